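# Array annotation and higher-order structure: optimal tiling of a clone with
# labeled monomers, HOR-unit inference, array classification, and junction /
# rearrangement detection (box co-location, Box-1-bounded cut-and-paste
# replacements, overlap junctions).

# The tiling DP and the greedy re-decomposition both score placements by the
# raw affine alignment score (match/mismatch/gap costs), so internal gaps are
# paid for; identity gates admission but does not set the score (an
# identity-based score would let a misregistered placement absorb stranded
# bases as free gap columns).

partial_flag <- function(u, v, L, edge_tol = 5L) {
  span <- v - u
  if (span >= L - edge_tol) return("none")
  head_missing <- u %% L
  tail_missing <- L - (u %% L + span)
  if (head_missing > edge_tol && head_missing >= tail_missing) "head"
  else if (tail_missing > edge_tol) "tail"
  else "none"
}

#' Tile an array sequence with labeled monomers
#'
#' Dynamic-programming segmentation of a clone into non-overlapping monomer
#' placements. Stage one scans every family consensus across the clone at
#' stride 1 with a banded global alignment and solves the optimal tiling over
#' complete placements (score proportional to identity times length, admitted
#' at `min_identity` or better; unassigned bases carry `unassigned_penalty`).
#' Stage two revisits every unassigned or low-confidence region together with
#' its flanking monomers and greedily re-decomposes it with free-rotation
#' local fragments (truncated and rotated monomers), which recovers
#' replacement flanks, rotated donors, chimeric junction parts and array-end
#' partials; the re-decomposition is kept only when it scores better.
#'
#' @param seq The array/clone sequence (one DNA string).
#' @param models A [family_model_set()] (or named character vector of family
#'   consensuses).
#' @param min_identity Minimum percent identity for a placement. Default 70.
#' @param unassigned_penalty Score per unassigned base (raw alignment-score
#'   units). Default -1.25: dearer than deleting one mismatch column (+1), so
#'   the optimal tiling does not shave mismatched boundary columns into
#'   micro-gaps, yet far cheaper than forcing a bad placement.
#' @param params [align_params()].
#' @param band Alignment band half-width for the stage-one scan. Default 15.
#' @param min_fragment Minimum length of a stage-two fragment. Default 25
#'   (shorter truncated flanks carry too little signal to place a box).
#' @param reanalyze_below Stage-one placements with identity below this are
#'   treated as uncertain and their neighbourhood is re-decomposed in stage
#'   two (rearranged regions often admit a mediocre full-monomer placement
#'   that outscores leaving them unassigned). Default 90; lower it for
#'   within-family divergence well above ~5%.
#' @param seq_id Sequence id recorded in the annotations.
#' @return A [monomer_annotations()] table covering the clone exactly
#'   (assigned monomers plus unassigned segments).
#' @export
tile_annotate <- function(seq, models, min_identity = 70,
                          unassigned_penalty = -1.25, params = align_params(),
                          band = 15, min_fragment = 25, reanalyze_below = 90,
                          seq_id = "seq") {
  params <- as_align_params(params)
  if (!inherits(models, "family_model_set")) models <- family_model_set(models)
  seq <- as.character(seq)
  N <- nchar(seq)
  cons <- model_consensuses(models)
  if (N < min(nchar(cons)) / 2) {
    return(monomer_annotations(seq_id = seq_id, start = 0L, end = N,
                               family = NA, identity = NA, register_offset = 0L,
                               partial = "none", cons_end = NA))
  }

  # ---- stage 1: complete placements + DP tiling --------------------------
  cand <- list()
  for (f in names(cons)) {
    L <- nchar(cons[[f]])
    if (N < L - band) next
    sc <- cpp_scan_complete(seq, cons[[f]], params$match, params$mismatch,
                            params$gap_open, params$gap_extend, as.integer(band))
    ok <- which(sc$valid & sc$identity >= min_identity)
    if (length(ok) == 0L) next
    cand[[f]] <- data.frame(
      family = f, start = sc$start[ok], end = sc$end[ok],
      identity = sc$identity[ok], u = sc$u[ok], v = sc$v[ok],
      score = sc$score[ok],
      stringsAsFactors = FALSE)
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(family = character(), start = integer(), end = integer(),
               identity = numeric(), u = integer(), v = integer(),
               score = numeric())
  dp <- c(0, rep(-Inf, N))
  choice <- integer(N + 1L)  # 0 = unassigned step, >0 = candidate row index
  by_end <- split(seq_len(nrow(cand)), cand$end)
  for (j in seq_len(N)) {
    dp[j + 1L] <- dp[j] + unassigned_penalty
    choice[j + 1L] <- 0L
    for (ci in by_end[[as.character(j)]]) {
      v <- dp[cand$start[ci] + 1L] + cand$score[ci]
      if (v > dp[j + 1L]) { dp[j + 1L] <- v; choice[j + 1L] <- ci }
    }
  }
  picked <- list()
  j <- N
  while (j > 0L) {
    ci <- choice[j + 1L]
    if (ci == 0L) { j <- j - 1L } else {
      picked[[length(picked) + 1L]] <- cand[ci, ]
      j <- cand$start[ci]
    }
  }
  picked <- if (length(picked)) do.call(rbind, rev(picked)) else
    cand[integer(0), ]

  # ---- stage 2: greedy re-decomposition of uncertain regions -------------
  segs <- picked
  covered <- logical(N)
  if (nrow(segs)) for (i in seq_len(nrow(segs)))
    covered[(segs$start[i] + 1L):segs$end[i]] <- TRUE
  gaps <- runs_false(covered)
  # seed regions: unassigned runs plus weak or truncated placements
  seeds <- list()
  if (nrow(gaps)) for (g in seq_len(nrow(gaps)))
    seeds[[length(seeds) + 1L]] <- c(gaps$start[g], gaps$end[g])
  if (nrow(segs)) for (i in seq_len(nrow(segs))) {
    L <- nchar(cons[[segs$family[i]]])
    weak <- segs$identity[i] < reanalyze_below ||
      partial_flag(segs$u[i], segs$v[i], L) != "none"
    if (weak) seeds[[length(seeds) + 1L]] <- c(segs$start[i], segs$end[i])
  }
  regions <- list()
  for (se in seeds) {
    rs <- se[1L]; re <- se[2L]
    # extend over the immediate flanking placements
    li <- if (nrow(segs)) which(segs$end == rs) else integer(0)
    ri <- if (nrow(segs)) which(segs$start == re) else integer(0)
    if (length(li)) rs <- segs$start[li[1L]]
    if (length(ri)) re <- segs$end[ri[1L]]
    regions[[length(regions) + 1L]] <- c(rs, re)
  }
  regions <- if (length(regions))
    merge_intervals(data.frame(start = vapply(regions, `[`, 0, 1),
                               end = vapply(regions, `[`, 0, 2)))
  else data.frame(start = integer(), end = integer())

  # fragments found in the uncertain regions join the candidate pool
  frags <- list()
  if (nrow(regions)) {
    for (g in seq_len(nrow(regions))) {
      rs <- regions$start[g]; re <- regions$end[g]
      frag <- decompose_region(substr(seq, rs + 1L, re), cons, params,
                               min_identity, min_fragment)
      if (nrow(frag)) {
        frag$start <- frag$start + rs
        frag$end <- frag$end + rs
        frags[[length(frags) + 1L]] <- frag
      }
    }
  }

  # ---- stage 3: one global DP over the pooled candidates -----------------
  # Stage-one placements are all in standard register and receive a small
  # register-prior bonus: a chain slid through a shared terminal box has the
  # same match count but strands its displaced bases as unassigned, so the
  # anchored chain wins ties deterministically.
  anchor_bonus <- 1.0
  pool <- cand
  if (nrow(pool)) pool$score <- pool$score + anchor_bonus
  if (length(frags)) pool <- rbind(pool, do.call(rbind, frags))
  dp <- c(0, rep(-Inf, N))
  choice <- integer(N + 1L)
  by_end <- split(seq_len(nrow(pool)), pool$end)
  for (j in seq_len(N)) {
    dp[j + 1L] <- dp[j] + unassigned_penalty
    choice[j + 1L] <- 0L
    for (ci in by_end[[as.character(j)]]) {
      v <- dp[pool$start[ci] + 1L] + pool$score[ci]
      if (v > dp[j + 1L]) { dp[j + 1L] <- v; choice[j + 1L] <- ci }
    }
  }
  final <- list()
  j <- N
  while (j > 0L) {
    ci <- choice[j + 1L]
    if (ci == 0L) { j <- j - 1L } else {
      final[[length(final) + 1L]] <- pool[ci, ]
      j <- pool$start[ci]
    }
  }
  final <- if (length(final)) do.call(rbind, rev(final)) else pool[integer(0), ]

  # ---- assemble annotations (assigned + unassigned) ----------------------
  rows <- list()
  pos <- 0L
  add_unassigned <- function(a, b) {
    if (b > a) rows[[length(rows) + 1L]] <<- data.frame(
      seq_id = seq_id, start = a, end = b, family = NA_character_,
      identity = NA_real_, register_offset = 0L, cons_end = NA_integer_,
      partial = "none", stringsAsFactors = FALSE)
  }
  if (nrow(final)) for (i in seq_len(nrow(final))) {
    add_unassigned(pos, final$start[i])
    L <- nchar(cons[[final$family[i]]])
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = seq_id, start = final$start[i], end = final$end[i],
      family = final$family[i], identity = final$identity[i],
      register_offset = as.integer(final$u[i] %% L),
      cons_end = as.integer(final$u[i] %% L + (final$v[i] - final$u[i])),
      partial = partial_flag(final$u[i], final$v[i], L),
      stringsAsFactors = FALSE)
    pos <- final$end[i]
  }
  add_unassigned(pos, N)
  df <- do.call(rbind, rows)
  out <- monomer_annotations(df$seq_id, df$start, df$end, df$family,
                             df$identity, df$register_offset, df$partial,
                             df$cons_end)
  out
}

runs_false <- function(x) {
  if (!length(x)) return(data.frame(start = integer(), end = integer()))
  r <- rle(!x)
  e <- cumsum(r$lengths); s <- e - r$lengths
  data.frame(start = s[r$values], end = e[r$values])
}

# Greedy free-rotation fragment decomposition of one region.
decompose_region <- function(segment, cons, params, min_identity, min_fragment) {
  empty <- data.frame(family = character(), start = integer(), end = integer(),
                      identity = numeric(), u = integer(), v = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  n <- nchar(segment)
  if (n < min_fragment) return(empty)
  best <- NULL
  for (f in names(cons)) {
    L <- nchar(cons[[f]])
    r <- cpp_local_fragment(segment, paste0(cons[[f]], cons[[f]]), as.integer(L),
                            params$match, params$mismatch, params$gap_open,
                            params$gap_extend)
    if (!isTRUE(r$found)) next
    len <- r$seg_end - r$seg_start
    if (len < min_fragment || r$identity < min_identity) next
    if (is.null(best) || r$score > best$sc)
      best <- list(f = f, r = r, sc = r$score)
  }
  if (is.null(best)) return(empty)
  r <- best$r
  here <- data.frame(family = best$f, start = r$seg_start, end = r$seg_end,
                     identity = r$identity, u = r$u, v = r$v, score = best$sc,
                     stringsAsFactors = FALSE)
  left <- decompose_region(substr(segment, 1L, r$seg_start), cons, params,
                           min_identity, min_fragment)
  right <- decompose_region(substr(segment, r$seg_end + 1L, nchar(segment)),
                            cons, params, min_identity, min_fragment)
  if (nrow(right)) { right$start <- right$start + r$seg_end; right$end <- right$end + r$seg_end }
  rbind(left, here, right)
}

#' Infer the higher-order repeat unit from a label sequence
#'
#' Finds the smallest period `p` such that the observed label sequence is a
#' prefix of the infinite repetition of its first `p` labels (a partial final
#' unit is accepted). Arrays whose minimal period equals their full length
#' are flagged non-periodic. The long/short HOR variant is assigned from the
#' `1b`-type labels in the unit: both present = long, exactly one = short.
#'
#' @param labels Character vector of family labels in array order.
#' @param lengths Optional named vector of family monomer lengths, used to
#'   report the unit length in bp.
#' @param b_pattern Regular expression identifying the 1b-type labels.
#'   Default `"^1b"`.
#' @return An object of class `hor_unit`: `labels` (the unit), `period`,
#'   `unit_length`, `variant` (`"long"`, `"short"`, `"other"`),
#'   `non_periodic`.
#' @examples
#' infer_hor_unit(c("A", "B", "A", "B", "A", "B"))
#' @export
infer_hor_unit <- function(labels, lengths = NULL, b_pattern = "^1b") {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2L) stop("need >= 2 labels")
  p <- n
  for (cand in seq_len(n - 1L)) {
    if (all(labels[(cand + 1L):n] == labels[seq_len(n - cand)])) { p <- cand; break }
  }
  unit <- labels[seq_len(p)]
  b_labels <- unique(unit[grepl(b_pattern, unit)])
  variant <- if (length(b_labels) >= 2L) "long"
             else if (length(b_labels) == 1L) "short" else "other"
  unit_length <- if (!is.null(lengths) && all(unit %in% names(lengths)))
    sum(lengths[unit]) else NA_integer_
  structure(list(labels = unit, period = p, unit_length = unit_length,
                 variant = variant, non_periodic = (p == n)),
            class = "hor_unit")
}

#' @export
print.hor_unit <- function(x, ...) {
  cat(sprintf("HOR unit [%s] (period %d%s, variant %s)\n",
              paste(x$labels, collapse = "-"), x$period,
              if (x$non_periodic) ", non-periodic" else "", x$variant))
  invisible(x)
}

#' Classify array organization
#'
#' `monomeric` (period-1 unit), `dimeric` (two distinct alternating labels),
#' `HOR` (unit of three or more monomers) or `complex` (non-periodic label
#' sequence).
#'
#' @param annotations A [monomer_annotations()] table (one sequence), or a
#'   character vector of labels.
#' @return One of `"monomeric"`, `"dimeric"`, `"HOR"`, `"complex"`.
#' @export
classify_array <- function(annotations) {
  labels <- annotation_labels(annotations)
  if (length(labels) < 2L) stop("need >= 2 non-partial annotations")
  u <- infer_hor_unit(labels)
  if (u$non_periodic) return("complex")
  if (u$period == 1L) return("monomeric")
  if (u$period == 2L && length(unique(u$labels)) == 2L) return("dimeric")
  "HOR"
}

annotation_labels <- function(annotations) {
  if (is.character(annotations)) return(annotations)
  a <- as.data.frame(annotations)
  a <- a[!is.na(a$family) & a$partial == "none", , drop = FALSE]
  a$family
}

#' Extract junctions between unlike monomers
#'
#' One event per boundary between two immediately adjacent assigned
#' annotations with different family labels. The boundary coordinate belongs
#' to the right-hand annotation. Consensus-space coordinates of both sides
#' (`left_cons_end`, `right_cons_start`) are carried along for box
#' co-location.
#'
#' @param annotations A [monomer_annotations()] table.
#' @return data.frame of junctions (possibly empty).
#' @export
extract_junctions <- function(annotations) {
  a <- as.data.frame(annotations)
  a <- a[!is.na(a$family), , drop = FALSE]
  out <- list()
  for (sid in unique(a$seq_id)) {
    s <- a[a$seq_id == sid, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) {
      if (s$end[i] != s$start[i + 1L]) next
      if (s$family[i] == s$family[i + 1L]) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sid, position = s$start[i + 1L],
        left_family = s$family[i], right_family = s$family[i + 1L],
        left_cons_end = s$cons_end[i],
        right_cons_start = s$register_offset[i + 1L],
        left_partial = s$partial[i], right_partial = s$partial[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(), position = integer(),
                      left_family = character(), right_family = character(),
                      left_cons_end = integer(), right_cons_start = integer(),
                      left_partial = character(), right_partial = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# circular membership of a position in [start - tol, end + tol) on a ring of
# size L
in_box_circular <- function(pos, start, end, L, tol) {
  lo <- (start - tol) %% L
  width <- (end + tol) - (start - tol)
  ((pos - lo) %% L) < width
}

junction_in_box <- function(j, models, tol) {
  hit <- NA_character_
  lm <- models[[j$left_family]]
  if (!is.null(lm)) for (bn in names(lm$boxes)) {
    b <- lm$boxes[[bn]]
    if (in_box_circular(j$left_cons_end, b[1], b[2], lm$monomer_length, tol))
      return(bn)
  }
  rm_ <- models[[j$right_family]]
  if (!is.null(rm_)) for (bn in names(rm_$boxes)) {
    b <- rm_$boxes[[bn]]
    if (in_box_circular(j$right_cons_start, b[1], b[2], rm_$monomer_length, tol))
      return(bn)
  }
  hit
}

#' Box co-location test for monomer junctions
#'
#' Flags each junction as in-box when its boundary falls inside a conserved
#' box interval of either flanking family (mapped through the annotations'
#' register, circular, with `tol` bp slack) and tests the observed in-box
#' fraction against a permutation null in which each junction's position is
#' re-drawn uniformly within the flanking monomer. The p-value is
#' `(1 + #{permutations >= observed}) / (1 + n_perm)`.
#'
#' @param junctions A junction table from [extract_junctions()].
#' @param models A [family_model_set()] whose models carry box intervals.
#' @param tol Positional tolerance in bp. Default 3.
#' @param n_perm Number of permutations. Default 10000.
#' @param seed Integer seed (same seed, same p).
#' @return List with `junctions` (input plus `in_box` column),
#'   `observed_fraction`, `p_value`, `n_junctions`.
#' @export
box_colocation_test <- function(junctions, models, tol = 3, n_perm = 10000,
                                seed = 1) {
  if (!inherits(models, "family_model_set")) models <- family_model_set(models)
  if (nrow(junctions) < 1L) stop("need >= 1 junction")
  if (!any(vapply(models, function(m) length(m$boxes) > 0L, logical(1))))
    stop("no boxes defined in the family models")
  nj <- nrow(junctions)
  inbox <- character(nj)
  for (i in seq_len(nj)) inbox[i] <- junction_in_box(junctions[i, ], models, tol)
  observed <- sum(!is.na(inbox))
  # per-family indicator of in-box positions
  ind <- lapply(models, function(m) {
    v <- rep(FALSE, m$monomer_length)
    for (b in m$boxes) {
      pos <- 0:(m$monomer_length - 1L)
      v <- v | in_box_circular(pos, b[1], b[2], m$monomer_length, tol)
    }
    v
  })
  set.seed(as.integer(seed))
  perm <- matrix(FALSE, n_perm, nj)
  for (i in seq_len(nj)) {
    lf <- junctions$left_family[i]; rf <- junctions$right_family[i]
    il <- ind[[lf]]; ir <- ind[[rf]]
    hl <- if (!is.null(il)) il[sample.int(length(il), n_perm, replace = TRUE)] else rep(FALSE, n_perm)
    hr <- if (!is.null(ir)) ir[sample.int(length(ir), n_perm, replace = TRUE)] else rep(FALSE, n_perm)
    perm[, i] <- hl | hr
  }
  counts <- rowSums(perm)
  p <- (1 + sum(counts >= observed)) / (1 + n_perm)
  junctions$in_box <- inbox
  list(junctions = junctions, observed_fraction = observed / nj,
       p_value = p, n_junctions = nj)
}

#' Detect Box-1-bounded cut-and-paste replacements
#'
#' Searches for the structural signature of a donor monomer inserted between
#' a left flank truncated at its Box-1 coordinate and a right flank resuming
#' at its Box-1 coordinate: a complete monomer of a third family framed by
#' two same-side-truncated partials whose truncation points fall in the named
#' box (within `tol` bp). Reports donor family, both truncation points and
#' the inferred extruded-segment length (missing left tail plus missing right
#' head).
#'
#' @param annotations A [monomer_annotations()] table.
#' @param models A [family_model_set()] with box coordinates.
#' @param box Name of the bounding box. Default `"Box1"`.
#' @param tol Positional tolerance in bp. Default 3.
#' @param min_flank Minimum truncated-flank length in bp. Default 25.
#' @param max_gap Maximum unannotated slack between the three parts. Default 3.
#' @return data.frame of replacement events (possibly empty).
#' @export
detect_box1_replacement <- function(annotations, models, box = "Box1", tol = 3,
                                    min_flank = 25, max_gap = 3) {
  if (!inherits(models, "family_model_set")) models <- family_model_set(models)
  a <- as.data.frame(annotations)
  a <- a[!is.na(a$family), , drop = FALSE]
  out <- list()
  for (sid in unique(a$seq_id)) {
    s <- a[a$seq_id == sid, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 3L) next
    for (i in seq_len(nrow(s) - 2L)) {
      left <- s[i, ]; mid <- s[i + 1L, ]; right <- s[i + 2L, ]
      if (mid$start - left$end > max_gap || right$start - mid$end > max_gap) next
      if (mid$partial != "none") next
      if (mid$family == left$family || mid$family == right$family) next
      lm <- models[[left$family]]; rm_ <- models[[right$family]]
      if (is.null(lm) || is.null(rm_)) next
      lb <- lm$boxes[[box]]; rb <- rm_$boxes[[box]]
      if (is.null(lb) || is.null(rb)) next
      if (left$end - left$start < min_flank) next
      if (right$end - right$start < min_flank) next
      # left flank: tail truncated at its box
      cut_l <- left$cons_end
      if (cut_l >= lm$monomer_length - tol) next  # not truncated
      if (!(cut_l >= lb[1] - tol && cut_l <= lb[2] + tol)) next
      # right flank: head truncated, resuming at its box
      cut_r <- right$register_offset
      if (cut_r <= tol) next
      if (!(cut_r >= rb[1] - tol && cut_r <= rb[2] + tol)) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sid, donor_family = mid$family,
        left_family = left$family, right_family = right$family,
        left_truncation = left$end, left_truncation_cons = cut_l,
        right_resume = right$start, right_resume_cons = cut_r,
        donor_start = mid$start, donor_end = mid$end,
        extruded_length = (lm$monomer_length - cut_l) + cut_r,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(), donor_family = character(),
                      left_family = character(), right_family = character(),
                      left_truncation = integer(), left_truncation_cons = integer(),
                      right_resume = integer(), right_resume_cons = integer(),
                      donor_start = integer(), donor_end = integer(),
                      extruded_length = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect overlap junctions
#'
#' An overlap junction is one where the clone segment immediately left of the
#' boundary is simultaneously the tail of the left monomer and (up to a few
#' substitutions) the head of the right family's consensus - the right
#' monomer "extends into" the left one. Detected where the right annotation
#' is head-truncated by `ov` bases and the `ov` clone bases before the
#' boundary match both the left consensus suffix and the right consensus
#' prefix at `min_identity` or better.
#'
#' @param annotations A [monomer_annotations()] table.
#' @param models A [family_model_set()].
#' @param seqs Named character vector of the clone sequences.
#' @param min_len Minimum overlap length in bp. Default 30.
#' @param min_identity Minimum percent identity of the overlap segment against
#'   each consensus. Default 90.
#' @param params [align_params()].
#' @return data.frame of overlap events with `overlap_length`, `mismatches`
#'   (between the two consensus stretches over the overlap) and
#'   `clone_mismatches` (clone segment vs right-consensus prefix).
#' @export
detect_overlap_junction <- function(annotations, models, seqs, min_len = 30,
                                    min_identity = 90, params = align_params()) {
  params <- as_align_params(params)
  if (!inherits(models, "family_model_set")) models <- family_model_set(models)
  seqs <- as_named_chr(seqs)
  jn <- extract_junctions(annotations)
  out <- list()
  if (nrow(jn)) for (i in seq_len(nrow(jn))) {
    j <- jn[i, ]
    ov <- j$right_cons_start
    if (is.na(ov) || ov < min_len) next
    rm_ <- models[[j$right_family]]; lm <- models[[j$left_family]]
    if (is.null(rm_) || is.null(lm)) next
    clone <- seqs[[j$seq_id]]
    if (is.null(clone) || j$position - ov < 0L) next
    seg <- substr(clone, j$position - ov + 1L, j$position)
    rpref <- substr(rm_$consensus, 1L, ov)
    # effective left consensus end (annotation cons_end may exceed one period
    # for rotated placements)
    ve <- ((j$left_cons_end - 1L) %% lm$monomer_length) + 1L
    if (ve - ov < 0L) next
    lsuf <- substr(lm$consensus, ve - ov + 1L, ve)
    if (nchar(lsuf) < ov || nchar(seg) < ov) next
    id_r <- pairwise_identity(seg, rpref, params)
    id_l <- pairwise_identity(seg, lsuf, params)
    if (id_r < min_identity || id_l < min_identity) next
    ham <- function(x, y) sum(seq_chars(x) != seq_chars(y))
    out[[length(out) + 1L]] <- data.frame(
      seq_id = j$seq_id, position = j$position,
      left_family = j$left_family, right_family = j$right_family,
      overlap_length = ov,
      mismatches = ham(lsuf, rpref),
      clone_mismatches = ham(seg, rpref),
      identity_left = id_l, identity_right = id_r,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(seq_id = character(), position = integer(),
                      left_family = character(), right_family = character(),
                      overlap_length = integer(), mismatches = integer(),
                      clone_mismatches = integer(), identity_left = numeric(),
                      identity_right = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
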