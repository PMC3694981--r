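# Monomer family analysis: pairwise identity, center-star multiple alignment,
# 50%-majority consensus, group identity matrices, family assignment, and
# neighbor-joining trees with bootstrap support.

#' Global percent identity between two sequences
#'
#' End-to-end (global, affine-gap) alignment under `params`; identity is
#' `100 * matches / columns` counted over alignment columns where neither row
#' is a gap. Symmetric in its arguments.
#'
#' @param a,b DNA strings.
#' @param params [align_params()].
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACGTACGTAC", "ACGTACGTAC")
#' @export
pairwise_identity <- function(a, b, params = align_params()) {
  params <- as_align_params(params)
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  # canonical pair order: co-optimal alignments may differ in match count,
  # so a fixed orientation is needed for exact symmetry
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  cpp_align_global(a, b, params$match, params$mismatch, params$gap_open,
                   params$gap_extend, FALSE)$identity
}

#' Full global alignment of two sequences
#'
#' As [pairwise_identity()] but returning the aligned strings, score, match
#' count and paired-column count.
#'
#' @inheritParams pairwise_identity
#' @return A list with `score`, `matches`, `paircols`, `identity`,
#'   `aligned_a`, `aligned_b`.
#' @export
pairwise_align <- function(a, b, params = align_params()) {
  params <- as_align_params(params)
  cpp_align_global(as.character(a), as.character(b), params$match,
                   params$mismatch, params$gap_open, params$gap_extend, TRUE)
}

#' Center-star multiple sequence alignment
#'
#' The center sequence (maximizing summed pairwise identity to all others) is
#' aligned pairwise to every other sequence and the pairwise gap patterns are
#' merged under the "once a gap, always a gap" rule. A deliberately simple,
#' deterministic MSA: adequate for the near-collinear monomer sets this
#' package aligns (length spread below ~30%), not a general aligner.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of >= 1 sequences.
#' @param params [align_params()].
#' @return A character matrix (rows = sequences, columns = alignment columns)
#'   with rownames preserved.
#' @export
center_star_msa <- function(seqs, params = align_params()) {
  params <- as_align_params(params)
  seqs <- as_named_chr(seqs)
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 1L) {
    m <- matrix(seq_chars(seqs), nrow = 1, dimnames = list(names(seqs), NULL))
    return(m)
  }
  spread <- (max(nchar(seqs)) - min(nchar(seqs))) / max(nchar(seqs))
  if (spread > 0.3)
    warning("length spread exceeds 30%; center-star alignment may be poor")
  idm <- cpp_identity_matrix(seqs, params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
  center <- which.max(rowSums(idm))
  cseq <- seqs[[center]]
  Lc <- nchar(cseq)
  # per-pair alignments of center vs other; record gaps inserted into the
  # center before each center position (slots 0..Lc)
  alns <- vector("list", n)
  gap_need <- integer(Lc + 1L)  # max gaps required in each center slot
  for (i in seq_len(n)) {
    if (i == center) next
    al <- cpp_align_global(cseq, seqs[[i]], params$match, params$mismatch,
                           params$gap_open, params$gap_extend, TRUE)
    alns[[i]] <- al
    ca <- seq_chars(al$aligned_a)
    pos <- 0L; run <- 0L
    gaps_here <- integer(Lc + 1L)
    for (ch in ca) {
      if (ch == "-") run <- run + 1L
      else { gaps_here[pos + 1L] <- run; run <- 0L; pos <- pos + 1L }
    }
    gaps_here[Lc + 1L] <- run
    gap_need <- pmax(gap_need, gaps_here)
  }
  # master center row with merged gaps
  cc <- seq_chars(cseq)
  master <- character(0)
  for (p in 0:Lc) {
    master <- c(master, rep("-", gap_need[p + 1L]),
                if (p < Lc) cc[p + 1L] else character(0))
  }
  width <- length(master)
  out <- matrix("-", nrow = n, ncol = width, dimnames = list(names(seqs), NULL))
  out[center, ] <- master
  # column index (in the master) of each center residue and of each slot start
  res_col <- which(master != "-")
  slot_start <- c(1L, res_col + 1L)  # first column of slot p (p = 0..Lc)
  for (i in seq_len(n)) {
    if (i == center) next
    al <- alns[[i]]
    ca <- seq_chars(al$aligned_a); cb <- seq_chars(al$aligned_b)
    row <- rep("-", width)
    pos <- 0L         # center residues consumed
    pend <- 0L        # pending gap chars in current slot
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        # b-residue in a center gap slot: right-align gaps inside the slot so
        # merged columns stay consistent
        row[slot_start[pos + 1L] + pend] <- cb[k]
        pend <- pend + 1L
      } else {
        pos <- pos + 1L
        pend <- 0L
        if (cb[k] != "-") row[res_col[pos]] <- cb[k]
      }
    }
    out[i, ] <- row
  }
  out
}

#' Majority-rule consensus of an alignment
#'
#' Per column, emits the unique symbol with relative frequency at least
#' `threshold` and strictly maximal; ties among qualifying symbols give `N`,
#' as does a column where no symbol qualifies. Columns whose majority symbol
#' is the gap are omitted from the consensus.
#'
#' @param alignment Character matrix (as from [center_star_msa()]) or a
#'   character vector of equal-length gapped strings.
#' @param threshold Majority threshold, default 0.5 (the 50% majority rule).
#' @return The consensus string.
#' @export
consensus_majority <- function(alignment, threshold = 0.5) {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 2L) stop("need >= 2 aligned rows")
  cons <- character(0)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    frac <- tab / nrow(m)
    qual <- names(frac)[frac >= threshold]
    if (length(qual) == 0L) { cons <- c(cons, "N"); next }
    top <- max(frac)
    winners <- names(frac)[frac == top]
    if (length(winners) > 1L) {
      if ("-" %in% winners) next else { cons <- c(cons, "N"); next }
    }
    if (winners == "-") next
    cons <- c(cons, winners)
  }
  paste(cons, collapse = "")
}

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  alignment <- as.character(alignment)
  if (length(unique(nchar(alignment))) != 1L)
    stop("aligned rows must have equal length")
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  m
}

#' Group-wise identity matrix
#'
#' Mean and standard deviation of pairwise percent identity between (and
#' within) monomer groups. Entry (i, j) averages over all cross pairs; the
#' diagonal averages over all within-group pairs. The SD is the population SD
#' of the pair scores. Monomers with more than `max_n_frac` ambiguous (`N`)
#' positions are excluded from the statistics.
#'
#' @param groups Named list of character vectors (or `DNAStringSet`s) of
#'   monomer sequences, one element per group.
#' @param params [align_params()].
#' @param max_n_frac Maximum tolerated `N` fraction per monomer. Default 0.1.
#' @return An object of class `identity_matrix`: list with `labels`, `mean`,
#'   `sd`, `n` (per-group monomer counts, after exclusion). Groups with fewer
#'   than 2 members get an `NA` diagonal.
#' @export
group_identity_matrix <- function(groups, params = align_params(),
                                  max_n_frac = 0.1) {
  params <- as_align_params(params)
  stopifnot(length(groups) >= 2L, !is.null(names(groups)))
  groups <- lapply(groups, as.character)
  groups <- lapply(groups, function(g) g[n_fraction(g) <= max_n_frac])
  labels <- names(groups)
  k <- length(groups)
  sizes <- lengths(groups)
  all_seqs <- unlist(groups, use.names = FALSE)
  gidx <- rep(seq_len(k), sizes)
  idm <- cpp_identity_matrix(all_seqs, params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
  mu <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  sdev <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  for (i in seq_len(k)) {
    for (j in i:k) {
      block <- idm[gidx == i, gidx == j, drop = FALSE]
      vals <- if (i == j) {
        if (sizes[i] < 2L) numeric(0) else block[upper.tri(block)]
      } else as.vector(block)
      if (length(vals) == 0L) next
      mu[i, j] <- mu[j, i] <- mean(vals)
      sdev[i, j] <- sdev[j, i] <- pop_sd(vals)
    }
  }
  structure(list(labels = labels, mean = mu, sd = sdev,
                 n = setNames(as.integer(sizes), labels)),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, digits = 1, ...) {
  cat("group identity matrix (% identity, mean with population SD)\n")
  m <- x$mean
  out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- if (is.na(m[i, j])) "-" else
      sprintf("%.*f (%.*f)", digits, m[i, j], digits, x$sd[i, j])
  print(cbind(n = x$n, as.data.frame(out)))
  invisible(x)
}

#' Family model and family model sets
#'
#' A family model bundles a family label, its consensus sequence, modal
#' monomer length, member ids and any conserved box intervals (0-based
#' half-open, on the consensus).
#'
#' @param label Family label (e.g. `"1cMH"`).
#' @param consensus Consensus DNA string.
#' @param members Character vector of member monomer ids.
#' @param boxes Named list of `c(start, end)` integer pairs.
#' @return An object of class `family_model`.
#' @export
family_model <- function(label, consensus, members = character(), boxes = list()) {
  consensus <- as.character(consensus)
  stopifnot(nchar(consensus) > 0L)
  for (b in boxes) {
    if (b[1] < 0 || b[2] > nchar(consensus) || b[1] >= b[2])
      stop("box interval out of consensus bounds in family ", label)
  }
  structure(list(label = label, consensus = consensus,
                 monomer_length = nchar(consensus),
                 members = as.character(members), boxes = boxes),
            class = "family_model")
}

#' @rdname family_model
#' @param consensuses Named character vector (or `DNAStringSet`) of family
#'   consensuses.
#' @param box_table Optional named list: per family, a named list of box
#'   intervals.
#' @export
family_model_set <- function(consensuses, box_table = list()) {
  consensuses <- as_named_chr(consensuses)
  stopifnot(!is.null(names(consensuses)))
  models <- lapply(names(consensuses), function(lb)
    family_model(lb, consensuses[[lb]], boxes = box_table[[lb]] %||% list()))
  names(models) <- names(consensuses)
  structure(models, class = "family_model_set")
}

model_consensuses <- function(models) {
  vapply(models, function(m) m$consensus, character(1))
}

#' Assign a monomer to its best-matching family
#'
#' Register-normalizes the monomer against each family consensus (all cyclic
#' rotations) and reports the best family, or `unassigned` when the best
#' identity falls below `min_identity`.
#'
#' @param monomer DNA string.
#' @param models A [family_model_set()].
#' @param min_identity Assignment threshold (percent). Default 70.
#' @param params [align_params()].
#' @return List with `label` (`NA` if unassigned), `identity`, `offset`.
#' @export
assign_family <- function(monomer, models, min_identity = 70,
                          params = align_params()) {
  params <- as_align_params(params)
  best <- list(label = NA_character_, identity = -1, offset = 0L)
  for (m in models) {
    if (abs(nchar(monomer) - nchar(m$consensus)) > 10L) {
      ident <- pairwise_identity(monomer, m$consensus, params)
      r <- list(offset = 0L, identity = ident)
    } else {
      r <- cpp_best_rotation(as.character(monomer), m$consensus, params$match,
                             params$mismatch, params$gap_open, params$gap_extend)
    }
    if (r$identity > best$identity) {
      best <- list(label = m$label, identity = r$identity,
                   offset = as.integer(r$offset))
    }
  }
  if (best$identity < min_identity)
    return(list(label = NA_character_, identity = best$identity, offset = 0L))
  best
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration (via [ape::nj()]) with input
#' validation; negative branch lengths arising from noisy distances are
#' clamped to zero. Distances built from sequences elsewhere in the package
#' are p-distances (`1 - identity/100`) with no multiple-hit correction.
#'
#' @param d Symmetric, zero-diagonal distance matrix with >= 3 taxa (rownames
#'   used as tip labels).
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop("distance matrix must have a zero diagonal")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# p-distance matrix from a character alignment matrix (pairwise deletion of
# gap/N columns).
p_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  is_base <- m %in% DNA_BASES
  dim(is_base) <- dim(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- is_base[i, ] & is_base[j, ]
      nk <- sum(ok)
      d[i, j] <- d[j, i] <- if (nk == 0L) 0 else sum(m[i, ok] != m[j, ok]) / nk
    }
  }
  d
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the NJ tree from p-distances of the full alignment, then resamples
#' alignment columns with replacement `B` times; the support of each internal
#' edge is the percentage of replicate trees containing the same bipartition.
#' Zero-length internal edges are collapsed (in the main tree and in every
#' replicate) before bipartitions are compared, so alignments without signal
#' yield no supported edges.
#'
#' @param alignment Character matrix or equal-length gapped strings (rows =
#'   taxa).
#' @param B Number of bootstrap replicates (>= 1). Default 100.
#' @param seed Integer seed; same seed, same supports.
#' @return An [ape::phylo] tree whose `node.label` carries percent support for
#'   internal edges (`NA` on the root node and on collapsed nodes).
#' @export
bootstrap_support <- function(alignment, B = 100, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  m <- as_alignment_matrix(alignment)
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  main <- nj_tree(p_distance(m))
  main <- ape::di2multi(main, tol = 1e-9)
  set.seed(as.integer(seed))
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    tb <- nj_tree(p_distance(m[, cols, drop = FALSE]))
    reps[[b]] <- ape::di2multi(tb, tol = 1e-9)
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / B
  main$node.label <- as.character(round(support, 1))
  attr(main, "bootstrap") <- support
  main
}
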