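# Synthetic satellite-DNA generator: family libraries evolved to a target
# identity matrix, conserved-box implantation, array construction under a
# per-site substitution rate, and rearrangement operators (Box-1 cut-and-paste
# insertion, Box-2 recombination, overlap junctions), all with exact ground
# truth and full seed determinism.

#' Default CENP-B-box-like master sequence for a planted Box 1
#'
#' The reverse complement of a 17-mer matching the human CENP-B box at 11 of
#' 17 positions (5 of the 9 essential positions), i.e. the degree of
#' similarity typical of CENP-B-box-like satellite motifs. Box 1 is planted
#' in forward orientation; scoring against the CENP-B box therefore uses the
#' reverse complement, as is conventional for such motifs.
#'
#' @return A 17-bp DNA string.
#' @export
default_box1_master <- function() {
  # revcomp("ATTCGTTGGAAATATCG"): 11/17 vs CTTCGTTGGAAACGGGA, 5/9 essential
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATTCGTTGGAAATATCG")))
}

#' Simulation configuration
#'
#' Bundles everything the simulator needs: family labels, lengths and group
#' tags, the target between-family identity matrix, the within-family
#' per-site substitution probability `mu`, box specifications, array plans
#' and rearrangement directives.
#'
#' @param seed Integer master seed.
#' @param labels Character vector of family labels.
#' @param lengths Integer vector of family monomer lengths (150-200 bp).
#' @param groups Integer/character group tags (same length as `labels`).
#' @param divergence_targets Symmetric matrix of target between-family percent
#'   identities, diagonal 100.
#' @param mu Within-family per-site substitution probability in `[0, 0.3]`.
#' @param boxes List of box specs: each a list with `name`, `length`,
#'   `position` (0-based integer, or `"terminus"`), `breadth` (`"all"` or a
#'   label vector), `degeneracy` (max substitutions per planted instance) and
#'   optional `master` sequence.
#' @param array_plans Named list of plans: each a list with `type`
#'   (`monomeric`, `dimeric`, `HOR`, `complex`), `unit` (label vector) and
#'   `copies`.
#' @param events List of event directives (see [simulate_dataset()]).
#' @param spacer Optional spacer spec `list(label, length)` for an
#'   uncharacterized segment generated independently of the families
#'   (`NULL` for none).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, labels, lengths, groups = NULL,
                       divergence_targets, mu = 0.03, boxes = list(),
                       array_plans = list(), events = list(), spacer = NULL) {
  stopifnot(length(labels) == length(lengths))
  if (mu < 0 || mu > 0.3) stop("mu must be in [0, 0.3]")
  if (any(lengths < 150 | lengths > 200))
    stop("family lengths must be in [150, 200]")
  divergence_targets <- as.matrix(divergence_targets)
  dimnames(divergence_targets) <- list(labels, labels)
  if (!isSymmetric(unname(divergence_targets)))
    stop("divergence_targets must be symmetric")
  if (any(abs(diag(divergence_targets) - 100) > 1e-9))
    stop("divergence_targets diagonal must be 100")
  for (b in boxes) {
    if (is.numeric(b$position) && any(b$position + b$length > lengths))
      stop("box ", b$name, " does not fit inside every family")
  }
  structure(list(seed = as.integer(seed), labels = labels,
                 lengths = setNames(as.integer(lengths), labels),
                 groups = if (is.null(groups)) rep(1L, length(labels)) else
                   setNames(groups, labels),
                 divergence_targets = divergence_targets, mu = mu,
                 boxes = boxes, array_plans = array_plans, events = events,
                 spacer = spacer),
            class = "sim_config")
}

#' Default simulation scenario
#'
#' Eight monomer families (169-180 bp) whose target identity matrix mirrors
#' the three observed similarity strata of satellite libraries - high
#' (81-86%) between closely related variants, moderate (51-66%) within a
#' group, negligible (32-46%) between groups; within-family substitution rate
#' `mu = 0.03` (pairwise within-family identity about 94%). A 17-bp Box 1 is
#' planted at an interior coordinate of all families and a 20-bp T/C/A-tract
#' Box 2 at the monomer terminus of the group-1 HOR families. Array plans:
#' two homogeneous monomeric arrays, one dimeric array (alternating 1c/1d),
#' and long/short HOR arrays of 6 units (unit 1d-2a-1c-U1-1a-1b-1b', the
#' short variant lacking 1b). Events: one Box-1 cut-and-paste insertion of a
#' complete 2a monomer at a 1d|1c junction of the dimeric array, and one
#' Box-2 recombination chimera of the two HOR arrays.
#'
#' @param seed Integer master seed. Default 1.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 1) {
  labels <- c("1aH", "1aM", "1bH", "1b'H", "1dMH", "1cMH", "2aMH", "2bM")
  lengths <- c(170, 169, 170, 169, 169, 169, 180, 179)
  groups <- c(1, 1, 1, 1, 1, 1, 2, 2)
  tg <- matrix(100, 8, 8)
  low <- list(
    c(2, 1, 81), c(3, 1, 63), c(3, 2, 64), c(4, 1, 64), c(4, 2, 66),
    c(4, 3, 86), c(5, 1, 64), c(5, 2, 63), c(5, 3, 57), c(5, 4, 56),
    c(6, 1, 56), c(6, 2, 53), c(6, 3, 52), c(6, 4, 51), c(6, 5, 62),
    c(7, 1, 39), c(7, 2, 40), c(7, 3, 46), c(7, 4, 42), c(7, 5, 36),
    c(7, 6, 32), c(8, 1, 40), c(8, 2, 40), c(8, 3, 51), c(8, 4, 46),
    c(8, 5, 37), c(8, 6, 35), c(8, 7, 60))
  for (e in low) { tg[e[1], e[2]] <- e[3]; tg[e[2], e[1]] <- e[3] }
  group1_hor <- c("1aH", "1bH", "1b'H", "1dMH", "1cMH")
  boxes <- list(
    list(name = "Box1", length = 17L, position = 120L, breadth = "all",
         degeneracy = 1L, master = default_box1_master()),
    list(name = "Box2", length = 20L, position = "terminus",
         breadth = group1_hor, degeneracy = 1L,
         master = "TTCTTTCAAACTTCCTTTCA"))
  unit_long <- c("1dMH", "2aMH", "1cMH", "U1", "1aH", "1bH", "1b'H")
  unit_short <- c("1dMH", "2aMH", "1cMH", "U1", "1aH", "1b'H")
  plans <- list(
    mono_1aM = list(type = "monomeric", unit = "1aM", copies = 10L),
    mono_2bM = list(type = "monomeric", unit = "2bM", copies = 10L),
    dimer = list(type = "dimeric", unit = c("1cMH", "1dMH"), copies = 6L),
    hor_long = list(type = "HOR", unit = unit_long, copies = 6L),
    hor_short = list(type = "HOR", unit = unit_short, copies = 6L))
  events <- list(
    list(type = "insertion_at_box1", array = "dimer", junction = 6L,
         donor = "2aMH"),
    list(type = "recombination_at_box2", a = "hor_long", b = "hor_short"))
  sim_config(seed = seed, labels = labels, lengths = lengths, groups = groups,
             divergence_targets = tg, mu = 0.03, boxes = boxes,
             array_plans = plans, events = events,
             spacer = list(label = "U1", length = 170L))
}

# Greedy seeded site-wise local search bringing the realized pairwise
# identities of `seqs` to `targets` (percent). The inner loop edits sites
# against a cheap Hamming identity (computed on the shared core prefix of
# each pair); an outer calibration loop measures the realized identities with
# the same global aligner used by group_identity_matrix() and shifts the
# Hamming targets by the observed per-pair offset (gapped alignment reads a
# few points higher than Hamming, most visibly on divergent pairs), so the
# final library is on target in alignment space. `frozen` lists per-family
# site indices (1-based) that must never be edited (planted boxes). Errors,
# naming the worst pair, when the targets cannot be approached within
# `fail_tol` points.
refine_to_targets <- function(seqs, targets, frozen = list(),
                              params = align_params(), tol = 1.5,
                              fail_tol = 5, max_iter = 10000,
                              tries_per_iter = 10, max_rounds = 8) {
  params <- as_align_params(params)
  labels <- names(seqs)
  n <- length(seqs)
  chars <- lapply(seqs, seq_chars)
  frozen_idx <- lapply(labels, function(l) frozen[[l]] %||% integer())
  ham_identity <- function(e, o) {
    core <- seq_len(min(length(chars[[e]]), length(chars[[o]])))
    100 * mean(chars[[e]][core] == chars[[o]][core])
  }
  ham_row <- function(e) vapply(seq_len(n), function(o)
    if (o == e) 100 else ham_identity(e, o), numeric(1))
  dp_matrix <- function() {
    r <- cpp_identity_matrix(vapply(chars, paste, "", collapse = ""),
                             params$match, params$mismatch, params$gap_open,
                             params$gap_extend)
    dimnames(r) <- list(labels, labels)
    r
  }
  off <- upper.tri(targets)
  ham <- matrix(100, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    ham[i, j] <- ham[j, i] <- ham_identity(i, j)
  ham_targets <- targets
  iter_budget <- max_iter
  for (round in seq_len(max_rounds)) {
    realized <- dp_matrix()
    dev <- realized - targets; diag(dev) <- 0
    if (max(abs(dev)) <= tol) break
    # recalibrate: aim Hamming at target minus the current DP-over-Hamming
    # offset
    ham_targets <- pmax(targets - (realized - ham), 2)
    diag(ham_targets) <- 100
    cur_loss <- sum((ham[off] - ham_targets[off])^2)
    blocked <- matrix(FALSE, n, n)
    it <- 0L
    while (it < iter_budget) {
      it <- it + 1L
      hdev <- ham - ham_targets; diag(hdev) <- 0
      hdev[blocked] <- 0
      worst <- which(abs(hdev) == max(abs(hdev)), arr.ind = TRUE)[1, ]
      if (abs(hdev[worst[1], worst[2]]) <= 0.5) break
      i <- worst[1]; j <- worst[2]
      e <- if (sum(abs(hdev[i, ])) >= sum(abs(hdev[j, ]))) i else j
      o <- if (e == i) j else i
      too_similar <- hdev[i, j] > 0
      improved <- FALSE
      for (fam_try in list(c(e, o), c(o, e))) {
        ee <- fam_try[1L]; oo <- fam_try[2L]
        core <- seq_len(min(length(chars[[ee]]), length(chars[[oo]])))
        sites <- if (too_similar)
          setdiff(core[chars[[ee]][core] == chars[[oo]][core]], frozen_idx[[ee]])
        else
          # never copy out of a frozen (planted-box) site of the partner:
          # that would propagate a box into a family outside its breadth
          setdiff(core[chars[[ee]][core] != chars[[oo]][core]],
                  c(frozen_idx[[ee]], frozen_idx[[oo]]))
        if (length(sites) == 0L) next
        for (t in seq_len(min(tries_per_iter, length(sites)))) {
          s <- sites[[sample.int(length(sites), 1L)]]
          old <- chars[[ee]][s]
          chars[[ee]][s] <- if (too_similar)
            sample(setdiff(DNA_BASES, c(old, chars[[oo]][s])), 1L)
          else chars[[oo]][s]
          new_row <- ham_row(ee)
          new_ham <- ham
          new_ham[ee, ] <- new_row; new_ham[, ee] <- new_row
          new_loss <- sum((new_ham[off] - ham_targets[off])^2)
          if (new_loss < cur_loss - 1e-12) {
            ham <- new_ham; cur_loss <- new_loss
            improved <- TRUE
            break
          } else chars[[ee]][s] <- old
        }
        if (improved) break
      }
      if (!improved)
        blocked[worst[1], worst[2]] <- blocked[worst[2], worst[1]] <- TRUE
    }
    # polishing phase: the Hamming proxy decouples from the gapped aligner at
    # high divergence, so residual deviations are descended directly against
    # the aligner: every candidate move is scored by the full set of aligned
    # identities of the edited family and accepted only when the global squared
    # deviation from the targets falls
    realized <- dp_matrix()
    seq_of <- function(k) paste(chars[[k]], collapse = "")
    dp_loss <- function(r) sum((r[off] - targets[off])^2)
    cur_loss <- dp_loss(realized)
    budget <- 4000L
    blocked <- matrix(FALSE, n, n)
    while (budget > 0L) {
      dev <- realized - targets; diag(dev) <- 0
      dev[blocked] <- 0
      worst <- which(abs(dev) == max(abs(dev)), arr.ind = TRUE)[1, ]
      if (abs(dev[worst[1], worst[2]]) <= tol) break
      i <- worst[1]; j <- worst[2]
      too_similar <- (realized - targets)[i, j] > 0
      moved <- FALSE
      for (fam_try in list(c(i, j), c(j, i))) {
        ee <- fam_try[1L]; oo <- fam_try[2L]
        core <- seq_len(min(length(chars[[ee]]), length(chars[[oo]])))
        sites <- if (too_similar)
          setdiff(core[chars[[ee]][core] == chars[[oo]][core]], frozen_idx[[ee]])
        else
          setdiff(core[chars[[ee]][core] != chars[[oo]][core]],
                  c(frozen_idx[[ee]], frozen_idx[[oo]]))
        if (length(sites) == 0L) next
        for (t in seq_len(min(tries_per_iter, length(sites)))) {
          budget <- budget - 1L
          s <- sites[[sample.int(length(sites), 1L)]]
          old <- chars[[ee]][s]
          chars[[ee]][s] <- if (too_similar)
            sample(setdiff(DNA_BASES, c(old, chars[[oo]][s])), 1L)
          else chars[[oo]][s]
          ids <- cpp_identity_vector(seq_of(ee),
                                     vapply(seq_len(n)[-ee], seq_of, ""),
                                     params$match, params$mismatch,
                                     params$gap_open, params$gap_extend)
          new_real <- realized
          new_real[ee, -ee] <- ids; new_real[-ee, ee] <- ids
          new_loss <- dp_loss(new_real)
          if (new_loss <= cur_loss + 1e-9) {
            # plateau moves are accepted: the aligned identity often reroutes
            # around a single substitution, and progress resumes a few sites on
            strict <- new_loss < cur_loss - 1e-12
            realized <- new_real; cur_loss <- new_loss
            if (strict) blocked[] <- FALSE
            moved <- TRUE
            break
          } else chars[[ee]][s] <- old
          if (budget <= 0L) break
        }
        if (moved || budget <= 0L) break
      }
      if (!moved) {
        blocked[worst[1], worst[2]] <- blocked[worst[2], worst[1]] <- TRUE
        if (all(blocked[abs(realized - targets) > tol & upper.tri(targets)])) break
      }
    }
  }
  seqs <- setNames(vapply(chars, paste, "", collapse = ""), labels)
  realized <- dp_matrix()
  dev <- realized - targets; diag(dev) <- 0
  if (max(abs(dev)) > fail_tol) {
    w <- which(abs(dev) == max(abs(dev)), arr.ind = TRUE)[1, ]
    stop(sprintf("could not reach target identity for pair %s / %s (off by %.1f)",
                 labels[w[1]], labels[w[2]], abs(dev[w[1], w[2]])))
  }
  list(seqs = seqs, realized = realized)
}

# Simulate sequences down an NJ guide tree fitted to the target identity
# matrix. Branch lengths (p-distance units) are Jukes-Cantor corrected into
# substitution rates before mutating.
sim_along_tree <- function(ancestor, targets, labels) {
  d <- 1 - targets / 100
  dimnames(d) <- list(labels, labels)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- stats::reorder(tr, "cladewise")  # parents before children
  nt <- length(tr$tip.label)
  root <- nt + 1L
  nseq <- vector("list", nt + tr$Nnode)
  nseq[[root]] <- seq_chars(ancestor)
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
    p <- min(tr$edge.length[k], 0.70)
    rate <- -3 / 4 * log(1 - 4 * p / 3)
    v <- nseq[[par]]
    sub_p <- 3 / 4 * (1 - exp(-4 * rate / 3))
    hit <- which(stats::runif(length(v)) < sub_p)
    for (s in hit) v[s] <- sample(setdiff(DNA_BASES, v[s]), 1L)
    nseq[[child]] <- v
  }
  out <- setNames(vapply(seq_len(nt), function(i)
    paste(nseq[[i]], collapse = ""), character(1)), tr$tip.label)
  out[labels]
}

#' Evolve a satellite family library to a target identity matrix
#'
#' Generates a random ancestral monomer and derives each family along a star
#' phylogeny with per-family divergences solved (least squares in log
#' agreement space) from the target matrix; families are then extended to
#' their target lengths, boxes from the config are implanted, and a seeded
#' greedy site-wise refinement (box sites frozen) adjusts the library until
#' every realized pairwise identity - measured with the same global aligner
#' used by [group_identity_matrix()] - is on target. Deterministic given the
#' config seed; errors naming the offending pair when a target cannot be
#' approached within 5 points.
#'
#' @param config A [sim_config()].
#' @param params [align_params()].
#' @return List with `consensuses` (named character), `boxes` (per family,
#'   named list of `c(start, end)` 0-based intervals) and `realized` (the
#'   achieved identity matrix).
#' @export
evolve_family_set <- function(config, params = align_params(),
                              copy_level = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "evolve_family_set"))
  labels <- config$labels
  n <- length(labels)
  tg <- config$divergence_targets
  tg_cons <- tg
  if (copy_level && config$mu > 0) {
    # the configured targets describe identities between sequenced monomer
    # copies (as an identity table over monomers reports them); solve for the
    # consensus-level agreement that yields them after within-family
    # mutation at rate mu on both sides:
    #   copy_agreement = a*q + (1-a)*r
    # with q = P(agree | consensuses agree), r = P(agree | they differ)
    mu <- config$mu
    q <- (1 - mu)^2 + mu^2 / 3
    r <- 2 * mu * (1 - mu) / 3 + 2 * mu^2 / 9
    tg_cons <- (tg / 100 - r) / (q - r)
    tg_cons[] <- pmin(1, pmax(0, tg_cons))
    tg_cons <- 100 * tg_cons
    diag(tg_cons) <- 100
  }
  tg <- tg_cons
  Lcore <- min(config$lengths)
  anc <- random_dna(Lcore)
  # guide-tree initialization: neighbor-joining on the target p-distances,
  # then substitutions simulated down the tree with Jukes-Cantor-corrected
  # branch lengths, so correlated family structure (subfamily pairs, groups)
  # is respected from the start
  seqs <- if (n >= 4) {
    sim_along_tree(anc, tg, labels)
  } else {
    m <- (100 - tg[1, ]) / 130
    setNames(vapply(seq_len(n), function(i) {
      v <- seq_chars(anc)
      hit <- which(stats::runif(Lcore) < m[i])
      for (s in hit) v[s] <- sample(setdiff(DNA_BASES, v[s]), 1L)
      paste(v, collapse = "")
    }, character(1)), labels)
  }
  for (i in seq_len(n)) {
    extra <- config$lengths[i] - Lcore
    if (extra > 0) seqs[[i]] <- paste0(seqs[[i]], random_dna(extra))
  }
  frozen <- list()
  if (length(config$boxes)) {
    imp <- implant_boxes(seqs, config$boxes, seed = NULL)
    seqs <- imp$consensuses
    frozen <- lapply(imp$boxes, function(bx)
      unlist(lapply(bx, function(iv) (iv[1] + 1L):iv[2])))
    boxes <- imp$boxes
    # keep out-of-breadth families genuinely box-free: degrade any window
    # resembling a master box below the detection threshold
    excl <- enforce_box_exclusivity(seqs, config$boxes, boxes)
    seqs <- excl$consensuses
    for (f in names(excl$touched))
      frozen[[f]] <- sort(unique(c(frozen[[f]], excl$touched[[f]])))
  } else boxes <- setNames(rep(list(list()), n), labels)
  ref <- refine_to_targets(seqs, tg, frozen, params)
  list(consensuses = ref$seqs, boxes = boxes, realized = ref$realized,
       targets_consensus = tg_cons)
}

#' Implant conserved boxes into family consensuses
#'
#' Overwrites the box interval of every in-breadth family with the master box
#' sequence, optionally degenerated by at most `degeneracy` substitutions per
#' family (the first in-breadth family always receives the exact master, so
#' the majority consensus of the instances equals the master). Lengths are
#' preserved; overlapping boxes within one family are an error.
#'
#' @param consensuses Named character vector of family consensuses.
#' @param box_specs List of box specs (see [sim_config()]).
#' @param seed Optional integer seed (uses the current RNG state when `NULL`).
#' @return List with `consensuses` (modified) and `boxes` (per family, named
#'   list of `c(start, end)`).
#' @export
implant_boxes <- function(consensuses, box_specs, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  labels <- names(consensuses)
  boxes <- setNames(rep(list(list()), length(labels)), labels)
  for (spec in box_specs) {
    master <- spec$master %||% random_dna(spec$length)
    if (nchar(master) != spec$length) stop("master length mismatch for ", spec$name)
    breadth <- if (identical(spec$breadth, "all")) labels else spec$breadth
    deg <- spec$degeneracy %||% 0L
    for (k in seq_along(breadth)) {
      f <- breadth[k]
      L <- nchar(consensuses[[f]])
      pos <- if (identical(spec$position, "terminus")) L - spec$length
             else as.integer(spec$position)
      if (pos < 0 || pos + spec$length > L)
        stop("box ", spec$name, " does not fit in family ", f)
      iv <- c(pos, pos + spec$length)
      for (existing in boxes[[f]]) {
        if (iv[1] < existing[2] && existing[1] < iv[2])
          stop("overlapping boxes in family ", f)
      }
      inst <- master
      if (deg > 0 && k > 1L) {
        ch <- seq_chars(inst)
        at <- sample.int(spec$length, deg)
        for (s in at) ch[s] <- sample(setdiff(DNA_BASES, ch[s]), 1L)
        inst <- paste(ch, collapse = "")
      }
      consensuses[[f]] <- paste0(substr(consensuses[[f]], 1, pos), inst,
                                 substr(consensuses[[f]], pos + spec$length + 1L, L))
      boxes[[f]][[spec$name]] <- iv
    }
  }
  list(consensuses = consensuses, boxes = boxes)
}

# Families outside a box's breadth must not carry look-alikes of the master
# (families related to an in-breadth family can inherit one through shared
# ancestry). Any ungapped window matching a master at >= `max_identity` is
# degraded to <= `target_identity` by substituting matched sites (never
# touching the family's own planted boxes). Returns the modified consensuses
# and the per-family sites touched (1-based), to be frozen downstream.
enforce_box_exclusivity <- function(consensuses, box_specs, boxes,
                                    max_identity = 80, target_identity = 72) {
  labels <- names(consensuses)
  touched <- setNames(rep(list(integer()), length(labels)), labels)
  for (spec in box_specs) {
    if (is.null(spec$master)) next
    mch <- seq_chars(spec$master)
    Lb <- length(mch)
    breadth <- if (identical(spec$breadth, "all")) labels else spec$breadth
    for (f in setdiff(labels, breadth)) {
      ch <- seq_chars(consensuses[[f]])
      own <- unlist(lapply(boxes[[f]], function(iv) (iv[1] + 1L):iv[2]))
      for (o in 0:(length(ch) - Lb)) {
        idx <- (o + 1L):(o + Lb)
        mhit <- which(ch[idx] == mch)
        if (100 * length(mhit) / Lb < max_identity) next
        while (100 * length(mhit) / Lb > target_identity) {
          editable <- setdiff(idx[mhit], own)
          if (length(editable) == 0L) break
          s <- editable[[sample.int(length(editable), 1L)]]
          ch[s] <- sample(setdiff(DNA_BASES, c(ch[s], mch[s - o])), 1L)
          touched[[f]] <- c(touched[[f]], s)
          mhit <- which(ch[idx] == mch)
        }
      }
      consensuses[[f]] <- paste(ch, collapse = "")
    }
  }
  list(consensuses = consensuses, touched = touched)
}

expand_plan <- function(plan) {
  switch(plan$type,
         monomeric = rep(plan$unit[1], plan$copies),
         dimeric = rep(plan$unit[1:2], plan$copies),
         HOR = rep(plan$unit, plan$copies),
         complex = plan$unit,
         stop("unknown plan type: ", plan$type))
}

#' Generate one satellite array with ground truth
#'
#' Concatenates per-copy mutated consensuses (each site substituted with
#' probability `mu`, uniformly over the three alternative bases) according to
#' an array plan, and records the exact monomer intervals and labels.
#'
#' @param plan A plan list (`type`, `unit`, `copies`), see [sim_config()].
#' @param consensuses Named character vector of family (and spacer)
#'   consensuses.
#' @param mu Per-site substitution probability.
#' @param seed Optional integer seed.
#' @param seq_id Identifier of the emitted sequence.
#' @return List with `seq_id`, `seq`, `truth` (a [monomer_annotations()]
#'   table) and `events` (empty list, filled by the rearrangement operators).
#' @export
generate_array <- function(plan, consensuses, mu = 0.03, seed = NULL,
                           seq_id = "array") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  labels <- expand_plan(plan)
  if (!all(labels %in% names(consensuses)))
    stop("plan references unknown labels: ",
         paste(setdiff(labels, names(consensuses)), collapse = ", "))
  parts <- character(length(labels))
  starts <- integer(length(labels)); ends <- integer(length(labels))
  pos <- 0L
  for (i in seq_along(labels)) {
    s <- mutate_seq(consensuses[[labels[i]]], mu)
    parts[i] <- s
    starts[i] <- pos; pos <- pos + nchar(s); ends[i] <- pos
  }
  truth <- monomer_annotations(
    seq_id = seq_id, start = starts, end = ends, family = labels,
    identity = NA, register_offset = 0L, partial = "none",
    cons_end = nchar(consensuses[labels]))
  list(seq_id = seq_id, seq = paste(parts, collapse = ""), truth = truth,
       events = list())
}

#' Apply a Box-1-bounded cut-and-paste insertion
#'
#' Removes the Box-1-bounded segment spanning the chosen junction (the left
#' monomer's tail from its Box 1 plus the right monomer's head up to its
#' Box 1) and inserts one complete donor monomer rotated into Box-1 register,
#' so that both new junctions fall exactly at Box 1 and the extruded segment
#' has monomer length. Ground truth records the donor, both truncation
#' points and the extruded length.
#'
#' @param array An array record from [generate_array()].
#' @param donor_family Donor family label.
#' @param junction_index Boundary index `k` (between truth rows `k` and
#'   `k + 1`).
#' @param consensuses Named character vector of consensuses.
#' @param boxes Per-family box intervals (as from [evolve_family_set()]).
#' @param mu Substitution rate applied to the inserted donor copy. Default 0.
#' @param box Name of the bounding box. Default `"Box1"`.
#' @param seed Optional integer seed.
#' @return The modified array record (updated `seq`, `truth`, `events`).
#' @export
apply_insertion_at_box1 <- function(array, donor_family, junction_index,
                                    consensuses, boxes, mu = 0, box = "Box1",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- array$truth
  k <- as.integer(junction_index)
  if (k < 1L || k >= nrow(tr)) stop("invalid junction index ", junction_index)
  X <- tr$family[k]; Y <- tr$family[k + 1L]
  bX <- boxes[[X]][[box]]; bY <- boxes[[Y]][[box]]; bD <- boxes[[donor_family]][[box]]
  if (is.null(bX) || is.null(bY)) stop("flanking families lack ", box)
  if (is.null(bD)) stop("donor family lacks ", box)
  LX <- nchar(consensuses[[X]])
  cut_left <- tr$start[k] + bX[1]
  cut_right <- tr$start[k + 1L] + bY[1]
  donor <- mutate_seq(rotate_seq(consensuses[[donor_family]], bD[1]), mu)
  LD <- nchar(donor)
  N <- nchar(array$seq)
  array$seq <- paste0(substr(array$seq, 1, cut_left), donor,
                      substr(array$seq, cut_right + 1L, N))
  delta <- LD - (cut_right - cut_left)
  tr_new <- as.data.frame(tr)
  tr_new$end[k] <- cut_left
  tr_new$cons_end[k] <- bX[1]
  tr_new$partial[k] <- "tail"
  donor_row <- data.frame(
    seq_id = array$seq_id, start = cut_left, end = cut_left + LD,
    family = donor_family, identity = NA_real_,
    register_offset = as.integer(bD[1]),
    cons_end = as.integer(bD[1] + nchar(consensuses[[donor_family]])),
    partial = "none", stringsAsFactors = FALSE)
  later <- tr_new[(k + 1L):nrow(tr_new), , drop = FALSE]
  later$start <- later$start + delta
  later$end <- later$end + delta
  later$start[1L] <- cut_left + LD
  later$register_offset[1L] <- as.integer(bY[1])
  later$partial[1L] <- "head"
  tr_new <- rbind(tr_new[seq_len(k), , drop = FALSE], donor_row, later)
  array$truth <- monomer_annotations(tr_new$seq_id, tr_new$start, tr_new$end,
                                     tr_new$family, tr_new$identity,
                                     tr_new$register_offset, tr_new$partial,
                                     tr_new$cons_end)
  array$events <- c(array$events, list(list(
    type = "insertion_at_box1", seq_id = array$seq_id,
    donor_family = donor_family, left_family = X, right_family = Y,
    left_truncation = cut_left, left_truncation_cons = bX[1],
    right_resume = cut_left + LD, right_resume_cons = bY[1],
    donor_start = cut_left, donor_end = cut_left + LD,
    extruded_length = (LX - bX[1]) + bY[1])))
  array
}

#' Apply a Box-2-mediated recombination between two arrays
#'
#' Builds a chimera from the prefix of array A up to a point inside a Box-2
#' instance and the suffix of array B from the aligned point of one of its
#' Box-2 instances; ground truth records the junction coordinate. Because
#' the cut lies inside a motif shared by both parents, the junction position
#' is only defined up to the remaining box length - downstream detection is
#' therefore assessed as in-box co-location.
#'
#' @param array_a,array_b Array records from [generate_array()].
#' @param boxes Per-family box intervals.
#' @param box Name of the mediating box. Default `"Box2"`.
#' @param cut_offset Offset of the cut inside the box. Default 10.
#' @param seed Optional integer seed (selects which monomers recombine).
#' @return A new array record for the chimera.
#' @export
apply_recombination_at_box2 <- function(array_a, array_b, boxes, box = "Box2",
                                        cut_offset = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pick <- function(arr, not_followed_by = NULL) {
    tr <- as.data.frame(arr$truth)
    ok <- which(tr$partial == "none" &
                  vapply(tr$family, function(f) !is.null(boxes[[f]][[box]]),
                         logical(1)))
    if (!is.null(not_followed_by)) {
      # the cut monomer's remnant beyond the box is tiny; the observable
      # junction is against the NEXT monomer, which must switch families
      ok <- ok[ok < nrow(tr) & tr$family[pmin(ok + 1L, nrow(tr))] != not_followed_by]
    }
    if (length(ok) == 0L) stop("no ", box, "-carrying monomer in ", arr$seq_id)
    ok[sample.int(length(ok), 1L)]
  }
  ia <- pick(array_a)
  fa_cut <- as.data.frame(array_a$truth)$family[ia]
  ib <- pick(array_b, not_followed_by = fa_cut)
  ta <- as.data.frame(array_a$truth); tb <- as.data.frame(array_b$truth)
  fa <- ta$family[ia]; fb <- tb$family[ib]
  ba <- boxes[[fa]][[box]]; bb <- boxes[[fb]][[box]]
  cut_a <- ta$start[ia] + ba[1] + cut_offset
  cut_b <- tb$start[ib] + bb[1] + cut_offset
  seq_id <- paste0(array_a$seq_id, "_x_", array_b$seq_id)
  chim <- paste0(substr(array_a$seq, 1, cut_a),
                 substr(array_b$seq, cut_b + 1L, nchar(array_b$seq)))
  keep_a <- ta[ta$end <= cut_a | seq_len(nrow(ta)) == ia, , drop = FALSE]
  keep_a <- keep_a[keep_a$start < cut_a, , drop = FALSE]
  keep_a$end[nrow(keep_a)] <- cut_a
  keep_a$cons_end[nrow(keep_a)] <- ba[1] + cut_offset
  keep_a$partial[nrow(keep_a)] <- "tail"
  shift <- cut_a - cut_b
  keep_b <- tb[tb$end > cut_b, , drop = FALSE]
  keep_b$start <- pmax(keep_b$start + shift, cut_a)
  keep_b$end <- keep_b$end + shift
  keep_b$register_offset[1L] <- as.integer(bb[1] + cut_offset)
  keep_b$partial[1L] <- "head"
  keep_a$seq_id <- seq_id; keep_b$seq_id <- seq_id
  tr <- rbind(keep_a, keep_b)
  truth <- monomer_annotations(tr$seq_id, tr$start, tr$end, tr$family,
                               tr$identity, tr$register_offset, tr$partial,
                               tr$cons_end)
  list(seq_id = seq_id, seq = chim, truth = truth,
       events = list(list(type = "recombination_at_box2", seq_id = seq_id,
                          left_family = fa, right_family = fb,
                          junction = cut_a, junction_cons = ba[1] + cut_offset,
                          box = box,
                          ambiguity = (ba[2] - (ba[1] + cut_offset)))))
}

#' Families sharing a terminal/initial overlap region
#'
#' Builds a two-family library in which the last `overlap_len` bases of the
#' first family equal the first `overlap_len` bases of the second up to
#' `n_subs` substitutions - the precondition for an overlap junction, where
#' one monomer "extends into" the next.
#'
#' @param seed Integer seed.
#' @param L Monomer length. Default 169.
#' @param overlap_len Shared region length. Default 50.
#' @param n_subs Substitutions distinguishing the two copies of the shared
#'   region. Default 6.
#' @param labels Labels of the two families.
#' @return Named character vector of the two consensuses.
#' @export
make_overlap_families <- function(seed = 1, L = 169, overlap_len = 50,
                                  n_subs = 6, labels = c("famA", "famB")) {
  set.seed(as.integer(seed))
  a <- random_dna(L)
  b <- seq_chars(random_dna(L))
  head <- seq_chars(substr(a, L - overlap_len + 1L, L))
  at <- sample.int(overlap_len, n_subs)
  for (s in at) head[s] <- sample(setdiff(DNA_BASES, head[s]), 1L)
  b[seq_len(overlap_len)] <- head
  setNames(c(a, paste(b, collapse = "")), labels)
}

#' Apply an overlap junction at a boundary
#'
#' Deletes the first `overlap_len` bases of the right-hand monomer at the
#' chosen junction, so that the clone segment before the boundary is shared
#' by the left monomer's tail and the right family's consensus head (which
#' must have been constructed to overlap, see [make_overlap_families()]).
#'
#' @param array An array record.
#' @param junction_index Boundary index between truth rows `k` and `k + 1`.
#' @param overlap_len Overlap length in bp. Default 50.
#' @return The modified array record.
#' @export
apply_overlap_junction <- function(array, junction_index, overlap_len = 50) {
  tr <- as.data.frame(array$truth)
  k <- as.integer(junction_index)
  if (k < 1L || k >= nrow(tr)) stop("invalid junction index ", junction_index)
  cut <- tr$start[k + 1L]
  array$seq <- paste0(substr(array$seq, 1, cut),
                      substr(array$seq, cut + overlap_len + 1L, nchar(array$seq)))
  tr$start[(k + 1L):nrow(tr)] <- tr$start[(k + 1L):nrow(tr)] - overlap_len
  tr$end[(k + 1L):nrow(tr)] <- tr$end[(k + 1L):nrow(tr)] - overlap_len
  tr$start[k + 1L] <- cut
  tr$register_offset[k + 1L] <- as.integer(overlap_len)
  tr$partial[k + 1L] <- "head"
  array$truth <- monomer_annotations(tr$seq_id, tr$start, tr$end, tr$family,
                                     tr$identity, tr$register_offset,
                                     tr$partial, tr$cons_end)
  array$events <- c(array$events, list(list(
    type = "overlap_junction", seq_id = array$seq_id, position = cut,
    left_family = tr$family[k], right_family = tr$family[k + 1L],
    overlap_length = overlap_len)))
  array
}

#' Simulate a complete satellite dataset
#'
#' Runs the whole generator: family library (with boxes), spacer, all planned
#' arrays, and all rearrangement directives; optionally writes the arrays as
#' FASTA, the family library as FASTA and the full ground truth as JSON.
#' Byte-identical output for identical config (the master seed fans out into
#' deterministic per-stage child seeds).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (`NULL` for no files).
#' @return List with `families` (consensuses incl. spacer), `boxes`,
#'   `realized` identity matrix, `arrays` (list of records), `events`,
#'   `truth` (combined annotation table) and `paths` (when written).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fam <- evolve_family_set(config)
  consensuses <- fam$consensuses
  if (!is.null(config$spacer)) {
    set.seed(derive_seed(config$seed, "spacer"))
    consensuses[[config$spacer$label]] <- random_dna(config$spacer$length)
  }
  arrays <- list()
  for (nm in names(config$array_plans)) {
    arrays[[nm]] <- generate_array(config$array_plans[[nm]], consensuses,
                                   mu = config$mu,
                                   seed = derive_seed(config$seed, paste0("array_", nm)),
                                   seq_id = nm)
  }
  events <- list()
  for (ev in config$events) {
    if (ev$type == "insertion_at_box1") {
      arrays[[ev$array]] <- apply_insertion_at_box1(
        arrays[[ev$array]], ev$donor, ev$junction, consensuses, fam$boxes,
        mu = config$mu, seed = derive_seed(config$seed, "insertion"))
      events <- c(events, tail(arrays[[ev$array]]$events, 1L))
    } else if (ev$type == "recombination_at_box2") {
      chim <- apply_recombination_at_box2(
        arrays[[ev$a]], arrays[[ev$b]], fam$boxes,
        seed = derive_seed(config$seed, "recombination"))
      arrays[[chim$seq_id]] <- chim
      events <- c(events, chim$events)
    } else stop("unknown event type: ", ev$type)
  }
  truth <- do.call(rbind, lapply(arrays, function(a) as.data.frame(a$truth)))
  rownames(truth) <- NULL
  out <- list(families = consensuses, boxes = fam$boxes,
              realized = fam$realized, arrays = arrays, events = events,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- setNames(vapply(arrays, `[[`, "", "seq"),
                   vapply(arrays, `[[`, "", "seq_id"))
    paths <- list(arrays_fasta = file.path(dir, "arrays.fa"),
                  families_fasta = file.path(dir, "families.fa"),
                  truth_json = file.path(dir, "truth.json"))
    write_fasta(fa, paths$arrays_fasta)
    write_fasta(consensuses, paths$families_fasta)
    jsonlite::write_json(
      list(schema = "satarray-truth-1",
           seed = config$seed,
           mu = config$mu,
           families = lapply(names(consensuses), function(f)
             list(label = f, consensus = consensuses[[f]],
                  length = nchar(consensuses[[f]]))),
           boxes = fam$boxes,
           annotations = truth,
           events = events),
      paths$truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
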