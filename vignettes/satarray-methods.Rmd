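---
title: "satarray: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{satarray: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and procedures, the tunable parameters with their defaults and
the reasons behind them, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis problem

Satellite DNA (satDNA) is organized as tandem arrays of a repeating monomer,
here 150–200 bp. A genome typically carries a library of related and
unrelated monomer families; in complex arrays, monomers of several families
plus uncharacterized spacer segments combine into a higher-order repeat
(HOR) that is itself tandemly repeated, in long and short variants that
differ by the presence of particular monomers. Two short boxes complicate
and illuminate the picture: a ~17-bp segment conserved across all families —
including pairs that share barely a third of their overall sequence — with
clear similarity to the human CENP-B box, and a ~20-bp T/C/A-tract segment
found at the terminus of one group's monomers. Junctions between unlike
monomers fall inside these boxes, and two structural signatures of sequence
exchange appear at them: a *cut-and-paste replacement*, in which a complete
donor monomer replaces a Box-1-delimited segment spanning a junction and
leaves truncated flanks, and *recombination junctions* inside the terminal
box. A third signature, the *overlap junction*, is a boundary where the
same stretch of the clone is simultaneously the tail of one monomer and the
head of the next family's consensus.

The package takes cloned array sequences (FASTA) plus a family consensus
library and reconstructs all of this; a seeded simulator generates data with
exactly this structure and known ground truth, which is how the pipeline is
validated.

## Alignment and identity

All pairwise comparisons use global (end-to-end) affine-gap alignment with a
single scoring scheme (`align_params()`): match +2, mismatch −1, gap opening
−10, gap extension −4, where a gap of length *g* costs
`gap_open + g*gap_extend`. Percent identity is `100 × matches / columns`
over alignment columns in which neither row is a gap.

Two numerical choices deserve explanation:

* **Stiff gap penalties.** Satellite monomers are collinear and their
  divergence is substitution-dominated. With lax gap costs the aligner
  harvests spuriously shifted matches between *unrelated* sequences and
  reports ~40% "identity" for random 169-mers, which would blur exactly the
  distinction the analysis cares about (unrelated families at ~32–40%
  versus moderately related ones at 50–65%). At −10/−4 the unrelated
  baseline sits near the ungapped expectation (~32%), so the bottom of the
  observed identity range remains interpretable. The parameters are
  configurable everywhere.
* **Canonical pair order.** Co-optimal global alignments can differ in
  match count, so identity is computed with the two sequences in
  lexicographic order; this makes `pairwise_identity(a, b)` exactly
  symmetric, as an identity measure must be.

Register normalization (`normalize_register()`) evaluates all cyclic
rotations of a monomer and keeps the rotation whose alignment *score* is
maximal (ties: higher identity, then smaller offset). Identity alone is the
wrong criterion here: end gaps never enter the identity denominator, so a
rotation off by a few bases can tie at 100% identity on a truncated
alignment while its score is clearly worse.

The multiple alignment behind consensus calling and variability profiling is
a deterministic center-star procedure: the sequence with the highest summed
pairwise identity is the center, all others are aligned to it pairwise, and
gap patterns merge under "once a gap, always a gap". This is adequate for
near-collinear monomer sets (length spread below ~30%) and keeps the whole
pipeline free of external alignment dependencies; it is not a general MSA.

## Family statistics and trees

`group_identity_matrix()` reports, per group pair, the mean and *population*
SD of all cross-pair identities (within-group pairs on the diagonal);
monomers with more than 10% ambiguous bases are excluded. The report layout
(`make_identity_table()`) is the familiar lower-triangular "mean (sd)" table
with a per-group *n* column.

Trees are built by neighbor joining on p-distances (proportion of differing
sites, pairwise deletion of gap columns, no multiple-hit correction — the
distances here are large enough that any correction choice would be
model-speculation, so the uncorrected distance is used and recorded).
Negative NJ branch lengths are clamped to zero. Bootstrap support resamples
alignment columns with replacement; each replicate tree and the full-data
tree have zero-length internal edges collapsed before bipartitions are
compared, so alignments without signal yield no supported edges (a set of
identical sequences gives a star). Supports are the percentage of
replicates containing each bipartition, reproducible under a seed.

## Variability profiles and conserved domains

The per-site statistic is the percent occurrence of the most frequent
non-gap base per alignment column (columns under 50% non-gap coverage are
excluded and reported). Sliding windows of `w = 15` sites at step `s = 2`
give `floor((L−w)/s)+1` values — 78 windows for a 169-column alignment.

Conserved domains are windows whose conservation exceeds the mean plus two
SDs, with at least two consecutive windows required (single-window peaks are
noise at typical row counts) and overlapping windows merged into site
intervals. The threshold is computed from the *window* values, not the
per-site values: per-site percentages carry binomial sampling noise of
several points per site and the planted/real conserved domain itself
inflates the site-level SD, so a site-level 2-SD band is too conservative to
call the very domains the plot shows. The profile object still carries the
site-level mean and SD, which is what a variability plot draws.

## Box discovery and CENP-B scoring

`find_shared_boxes()` slides windows of 15–25 bp from every consensus in
turn and finds each window's best ungapped placement on every other
consensus (computed via per-shift match prefix sums). A window counts as
shared by a family at ≥85% ungapped identity; candidates need at least three
families, the longest qualifying window wins per anchor position, and
duplicates found from different anchors are merged keeping the
representation with the greatest breadth, then length, then identity. Boxes
are named Box1, Box2, … by breadth. Two facts about the output are worth
knowing: the reported box can overhang a planted/real motif by a few bases
(flanking positions that are conserved by ancestry extend the window while
the identity criterion still holds), and families that are strongly
correlated by descent legitimately produce additional conserved windows
beyond the planted boxes — consumers that care about a specific box should
select it by coordinates, as the acceptance script does.

CENP-B similarity compares a 17-bp box positionally against a configured
reference — default `CTTCGTTGGAAACGGGA` with essential positions
2,3,4,5,10,13,14,15,16, i.e. the `NTTCGNNNNANNCGGGN` binding consensus —
after optional reverse complementation, since satellite boxes are routinely
deposited in the opposite orientation. A 16-bp variant (one deleted
nucleotide) must be padded with `-`, which can never match, so deletions
strictly reduce both counts.

## Tiling annotation

`tile_annotate()` computes an optimal, non-overlapping labeled-monomer
tiling in three stages:

1. every family consensus is scanned across the clone at stride 1 with a
   banded global alignment (band 15), producing complete-placement
   candidates with their raw alignment scores;
2. uncertain regions — unassigned stretches, placements under 90% identity
   (`reanalyze_below`), truncated placements — are re-decomposed greedily
   with free-rotation local fragments against a doubled consensus, which
   recovers truncated flanks, rotated donors, chimeric junction parts and
   array-end partials; a fragment's consensus span is capped at one period
   and the best-scoring sub-path within that cap is kept;
3. a single dynamic program over the pooled candidates picks the
   maximum-score tiling, with unassigned bases at −1.25 per base and a +1
   register-prior bonus on standard-register complete placements.

The scoring details are load-bearing. Candidates are scored by their *raw*
alignment score rather than identity×length: identity excludes gap columns,
so an identity-based score would let a misregistered placement absorb
stranded bases as free internal gaps. The unassigned penalty is set just
above the score gained by deleting one mismatch column (+1), so the optimal
tiling does not shave mutated boundary columns into micro-gaps; and the
register prior resolves the genuine ambiguity created by boxes shared
between neighboring monomers — a whole chain of placements can slide through
an identical terminal box at no alignment cost, and the prior plus the
stranded-base accounting makes the anchored chain win deterministically.

A residual, irreducible ambiguity remains at rearrangement breakpoints: a
cut inside a perfectly shared motif is only defined up to that motif, so
event coordinates are reported and validated at box resolution (the
extruded-segment length of a replacement is slide-invariant and is checked
tightly). The package reports observed in-box fractions and a permutation
p-value (`box_colocation_test()`, junction positions redrawn uniformly
within the flanking monomer, `p = (1 + #{perm ≥ obs})/(1 + n_perm)`) rather
than asserting that junctions always fall in boxes.

HOR units are the smallest period *p* such that the observed label sequence
is a prefix of the infinite repetition of its first *p* labels (a partial
final unit is accepted; a sequence whose minimal period equals its length is
non-periodic). On short label strings an inserted monomer can coincidentally
admit a longer period, so classification of event-carrying arrays is
interpreted together with the event detections. The long/short variant
rule looks for the `1b`-type labels: both present = long, one = short.

## The simulator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with exact ground truth:

* **Families.** An ancestral monomer evolves along a neighbor-joining guide
  tree fitted to the target identity matrix (Jukes–Cantor-corrected branch
  lengths), then a seeded greedy site-wise search refines the library until
  the realized pairwise identities — measured with the package's own
  aligner — sit on target: a fast Hamming-proxy descent alternates with a
  direct descent on aligned identities, because gapped alignment decouples
  from site agreement at high divergence. Configured targets are
  interpreted as *copy-level* identities (what an identity table over
  sequenced monomers shows); the consensus-level targets are derived from
  them through the two-sided substitution algebra
  `copy_agreement = a·q + (1−a)·r` with `q = (1−μ)² + μ²/3` and
  `r = 2μ(1−μ)/3 + 2μ²/9`. At the default μ this matters: an 86%
  copy-level pair needs ~91% consensus identity.
* **Boxes.** Masters are implanted at fixed coordinates (Box 1 at an
  interior position in all families; Box 2 at the monomer terminus of the
  group-1 HOR families) with at most one substitution per family, the first
  family keeping the exact master so the instance majority consensus equals
  it. Families *outside* a box's breadth are actively kept box-free: any
  window resembling a master at ≥80% is degraded below detection threshold,
  those sites are frozen, and the identity refinement never copies a frozen
  (box) site from one family into another — otherwise shared ancestry would
  smuggle Box 2 into closely related out-of-breadth families. The default
  Box 1 master is the reverse complement of a 17-mer matching the CENP-B
  reference at 11/17 positions (5/9 essential), the similarity level
  characteristic of CENP-B-box-like satellite motifs; the default Box 2
  master is a 20-bp T/C/A tract.
* **Arrays and events.** Arrays concatenate per-copy mutated consensuses
  (each site substituted with probability μ = 0.03 by default, giving
  within-family pairwise identity `100((1−μ)² + μ²/3) ≈ 94.1%`).
  The cut-and-paste operator removes the Box-1-bounded segment spanning a
  junction and inserts a complete donor rotated into Box-1 register, so both
  new junctions fall exactly at Box 1 and the extruded segment has monomer
  length. The recombination operator joins a prefix of one array to a
  suffix of another at aligned points inside Box-2 instances, choosing
  partners such that the resulting junction is an observable family switch
  (the cut monomer's remnant beyond the box is a few bases and is absorbed
  by the shared motif). The overlap operator deletes the right monomer's
  head at a junction between families constructed to share a 50-bp
  tail/head region (6 substitutions by default). Substitution-only defaults
  (no indels) reflect that all the structural signals of interest are
  substitution-scale; indels can be introduced by stress-testing configs.
* **Scale.** The default scenario uses two monomeric arrays of 10 copies,
  one dimeric array of 6 unit copies, and long/short HOR arrays of 6 units
  (7 and 6 monomers per unit, including a 170-bp independent spacer
  labeled U1) — a few dozen kilobases per dataset, so a full
  simulate-and-recover cycle takes seconds and the validation suite can
  afford ten independent datasets.

What passing these tests shows — and does not show — about real data: the
generator plants end-state structure under uniform substitution noise. It
does not emulate indel polymorphism, unequal crossover or gene-conversion
dynamics, ambiguity codes from sequencing, or spacer turnover, so perfect
recovery here demonstrates the correctness of the algorithms under the
stated model, not robustness to every artifact of real clone libraries
(the N-handling and indel-tolerant alignment paths are exercised by
separate unit tests).

## Validation metrics

The end-to-end tests measure: monomer boundary recovery (fraction of
non-truncated ground-truth monomers matched within ±2 bp — truncated event
flanks are validated separately through the event detections), family label
accuracy among recovered monomers, exact HOR unit and variant recovery,
event detection with box-resolution coordinates and tight extruded-length
agreement, and recovery of both planted boxes with their exact family
breadths. Identity-matrix recovery is validated at copy level against the
configured targets and against the closed-form within-family identity.
Tree building is validated by exact topology recovery on random additive
matrices and by separating-edge bootstrap support on two-cluster data.
`scripts/acceptance.R` recomputes all of these quantities from scratch on
freshly simulated data (three datasets for the structure-recovery block)
and writes them to JSON.

## Known limitations

* Breakpoints inside shared motifs are reported at motif resolution — no
  algorithm can do better, since the alternatives are literally
  score-equivalent.
* The center-star MSA degrades for length spreads beyond ~30% and is not a
  substitute for a progressive aligner on distant sequences.
* Box discovery on strongly correlated families reports additional
  ancestrally conserved windows beyond any planted/biological boxes;
  downstream consumers should select boxes by coordinates or breadth.
* The identity refinement in the simulator solves a constrained
  combinatorial problem heuristically; for extreme target matrices it stops
  with an error naming the unreachable pair rather than silently missing
  the target.
* `infer_hor_unit()`'s minimal-period rule can assign a coincidental period
  to short, event-carrying label strings; interpret classifications of
  rearranged arrays together with the event tables.
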