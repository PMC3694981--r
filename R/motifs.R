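# Conserved-box discovery across divergent family consensuses, degenerate
# (IUPAC) box consensuses, and similarity scoring against the human CENP-B
# box (x/17 overall and x/9 over the positions essential for CENP-B binding).

IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M",
  "CGT" = "B", "AGT" = "D", "ACT" = "H", "ACG" = "V", "ACGT" = "N")

#' Minimal IUPAC consensus of equal-length motif instances
#'
#' Per column, the minimal IUPAC degeneracy code covering all observed bases.
#'
#' @param instances Character vector of >= 2 equal-length DNA strings.
#' @return The degenerate pattern string.
#' @examples
#' iupac_consensus(c("ACGT", "AGGT"))  # "ASGT"... per-column minimal codes
#' @export
iupac_consensus <- function(instances) {
  instances <- as.character(instances)
  if (length(instances) < 2L) stop("need >= 2 instances")
  if (length(unique(nchar(instances))) != 1L)
    stop("conflicting instance lengths: ",
         paste(unique(nchar(instances)), collapse = ", "))
  m <- do.call(rbind, strsplit(instances, ""))
  codes <- apply(m, 2, function(col) {
    bases <- sort(unique(col[col %in% DNA_BASES]))
    if (length(bases) == 0L) return("N")
    IUPAC_FROM_SET[[paste(bases, collapse = "")]]
  })
  paste(codes, collapse = "")
}

#' Human CENP-B box reference
#'
#' The 17-bp CENP-B box consensus of human alpha satellite and the set of 9
#' positions essential for CENP-B protein binding. Both are configuration
#' data: the shipped default is the widely used
#' `NTTCGNNNNANNCGGGN` binding consensus written out as
#' `CTTCGTTGGAAACGGGA`, with the nine defined (essential) positions
#' 2,3,4,5,10,13,14,15,16 (1-based).
#'
#' @param consensus 17-mer DNA string.
#' @param essential_positions Integer vector of 9 positions in `1:17`.
#' @return An object of class `cenpb_reference`.
#' @export
cenpb_reference <- function(consensus = "CTTCGTTGGAAACGGGA",
                            essential_positions = c(2, 3, 4, 5, 10, 13, 14, 15, 16)) {
  consensus <- toupper(as.character(consensus))
  if (nchar(consensus) != 17L) stop("CENP-B consensus must be 17 bp")
  essential_positions <- sort(as.integer(essential_positions))
  if (length(essential_positions) != 9L ||
      any(essential_positions < 1L | essential_positions > 17L))
    stop("essential_positions must be 9 positions in 1:17")
  structure(list(consensus = consensus,
                 essential_positions = essential_positions),
            class = "cenpb_reference")
}

#' Positional similarity of a box sequence to the CENP-B box
#'
#' Counts positionally identical bases between a 17-bp box sequence and the
#' CENP-B reference, overall (of 17) and over the 9 essential positions
#' (of 9). A 16-bp box variant (one deleted nucleotide) must be padded to 17
#' with a `-`, which can never match. The comparison is applied after
#' optionally reverse-complementing the box (satellite boxes are often
#' deposited in the opposite orientation to the CENP-B box).
#'
#' @param box_sequence 17-character string over `ACGTN-` (16-bp variants
#'   padded with one `-`).
#' @param ref A [cenpb_reference()].
#' @param orientation `"forward"` or `"revcomp"`.
#' @return Integer vector `c(matches_of_17, matches_of_9)`.
#' @examples
#' ref <- cenpb_reference()
#' cenpb_similarity(ref$consensus, ref)  # c(17, 9)
#' @export
cenpb_similarity <- function(box_sequence, ref = cenpb_reference(),
                             orientation = c("forward", "revcomp")) {
  orientation <- match.arg(orientation)
  box_sequence <- toupper(as.character(box_sequence))
  if (!nchar(box_sequence) %in% c(16L, 17L))
    stop("box sequence must be 16-17 characters (16-mers padded to 17)")
  if (nchar(box_sequence) == 16L)
    stop("pad 16-bp variants to 17 with a '-' at the deleted position")
  if (orientation == "revcomp") {
    comp <- chartr("ACGTN-", "TGCAN-", box_sequence)
    box_sequence <- paste(rev(seq_chars(comp)), collapse = "")
  }
  b <- seq_chars(box_sequence)
  r <- seq_chars(ref$consensus)
  eq <- b == r & b %in% DNA_BASES
  c(matches_of_17 = sum(eq),
    matches_of_9 = sum(eq[ref$essential_positions]))
}

#' Discover boxes conserved across divergent family consensuses
#'
#' Scans windows of each consensus (every consensus serves as anchor in turn)
#' of lengths `L_min` to `L_max` and finds, for every window, its best
#' ungapped placement on every other consensus. Windows matched at >=
#' `min_cross_identity` percent in at least `min_breadth - 1` other families
#' are box candidates; at each anchor position the longest qualifying window
#' wins, overlapping candidates are merged (best breadth, then identity,
#' kept), and boxes found from different anchors are deduplicated by instance
#' overlap. Boxes are ranked and named (`Box1`, `Box2`, ...) by breadth, then
#' mean identity.
#'
#' @param consensuses Named character vector (>= 3) of family consensuses.
#' @param L_min,L_max Window length range. Defaults 15 and 25, bracketing the
#'   17/20-bp boxes typical of satellite junction motifs.
#' @param min_cross_identity Minimum ungapped identity (percent) for a family
#'   to count as carrying the box. Default 85.
#' @param min_breadth Minimum number of families sharing a box. Default 3.
#' @return List of `box_motif` objects: `name`, `length`, `breadth`,
#'   `mean_identity`, `iupac`, and `instances` (data.frame with `family`,
#'   `start`, `end` on each family consensus, and `seq`).
#' @export
find_shared_boxes <- function(consensuses, L_min = 15, L_max = 25,
                              min_cross_identity = 85, min_breadth = 3) {
  consensuses <- as_named_chr(consensuses)
  stopifnot(length(consensuses) >= 3L, !is.null(names(consensuses)))
  fams <- names(consensuses)
  cand <- list()
  for (a in seq_along(consensuses)) {
    anchor <- consensuses[[a]]
    others <- consensuses[-a]
    per_pos <- list()  # best candidate per (start)
    Lhi <- min(L_max, nchar(anchor), min(nchar(others)))
    if (Lhi < L_min) next
    scans <- cpp_window_scan_range(anchor, unname(others), as.integer(L_min),
                                   as.integer(Lhi))
    for (sc in scans) {
      L <- sc$L
      ident <- sc$identity; offs <- sc$offset
      if (nrow(ident) == 0L) next
      hit <- ident >= min_cross_identity
      nhit <- rowSums(hit)
      ok <- which(nhit >= min_breadth - 1L)
      for (s in ok) {
        mean_id <- mean(ident[s, hit[s, ]])
        prev <- per_pos[[as.character(s)]]
        better <- is.null(prev) ||
          sum(hit[s, ]) > prev$nhit ||
          (sum(hit[s, ]) == prev$nhit && L > prev$L)
        if (better) {
          per_pos[[as.character(s)]] <- list(
            anchor = a, start = s - 1L, L = L, nhit = sum(hit[s, ]),
            mean_id = mean_id, hits = which(hit[s, ]),
            offsets = offs[s, ])
        }
      }
    }
    if (length(per_pos) == 0L) next
    # greedy selection of non-overlapping anchor windows, best first
    ord <- order(vapply(per_pos, function(p)
      -(p$nhit * 1e8 + p$L * 1e3 + p$mean_id), numeric(1)))
    taken <- list()
    for (p in per_pos[ord]) {
      clash <- any(vapply(taken, function(t)
        p$start < t$start + t$L && t$start < p$start + p$L, logical(1)))
      if (!clash) taken[[length(taken) + 1L]] <- p
    }
    cand <- c(cand, taken)
  }
  if (length(cand) == 0L) return(list())
  # materialize instances and deduplicate across anchors by instance overlap
  boxes <- list()
  for (p in cand) {
    anchor_fam <- fams[p$anchor]
    other_fams <- fams[-p$anchor]
    inst <- data.frame(
      family = c(anchor_fam, other_fams[p$hits]),
      start = c(p$start, unname(p$offsets[p$hits])),
      stringsAsFactors = FALSE)
    inst$end <- inst$start + p$L
    inst$seq <- substring(consensuses[inst$family], inst$start + 1L, inst$end)
    cand_box <- structure(
      list(name = NA_character_, length = p$L, breadth = nrow(inst),
           mean_identity = p$mean_id,
           iupac = iupac_consensus(inst$seq), instances = inst),
      class = "box_motif")
    rank_key <- function(b) c(b$breadth, b$length, b$mean_identity,
                              -min(b$instances$start))
    dup_at <- 0L
    for (bi_idx in seq_along(boxes)) {
      b <- boxes[[bi_idx]]
      shared <- intersect(inst$family, b$instances$family)
      if (length(shared) == 0L) next
      f <- shared[1L]
      bi <- b$instances[b$instances$family == f, ]
      ii <- inst[inst$family == f, ]
      if (ii$start < bi$end && bi$start < ii$end) { dup_at <- bi_idx; break }
    }
    if (dup_at > 0L) {
      # keep the better representation of the same box, independent of the
      # anchor scan order
      ka <- rank_key(cand_box); kb <- rank_key(boxes[[dup_at]])
      cmp <- ka - kb
      first <- cmp[cmp != 0][1]
      if (!is.na(first) && first > 0) boxes[[dup_at]] <- cand_box
    } else {
      boxes[[length(boxes) + 1L]] <- cand_box
    }
  }
  ord <- order(vapply(boxes, function(b) -(b$breadth * 1e6 + b$mean_identity),
                      numeric(1)))
  boxes <- boxes[ord]
  for (i in seq_along(boxes)) boxes[[i]]$name <- paste0("Box", i)
  boxes
}

#' @export
print.box_motif <- function(x, ...) {
  cat(sprintf("%s: %d bp, shared by %d families, mean cross identity %.1f%%\n  %s\n",
              x$name, x$length, x$breadth, x$mean_identity, x$iupac))
  invisible(x)
}

#' Score a discovered box against the CENP-B box
#'
#' For every family instance of a box, takes the best-scoring 17-bp window in
#' the best orientation (forward or reverse complement) and reports the
#' CENP-B similarity counts.
#'
#' @param box A `box_motif` from [find_shared_boxes()].
#' @param ref A [cenpb_reference()].
#' @return data.frame with `family`, `matches_of_17`, `matches_of_9`,
#'   `orientation`.
#' @export
score_box_cenpb <- function(box, ref = cenpb_reference()) {
  res <- lapply(seq_len(nrow(box$instances)), function(i) {
    s <- box$instances$seq[i]
    best <- c(-1L, -1L); bor <- "forward"
    n <- nchar(s)
    starts <- if (n >= 17L) seq_len(n - 17L + 1L) else integer(0)
    for (st in starts) {
      w <- substr(s, st, st + 16L)
      for (orient in c("forward", "revcomp")) {
        sc <- cenpb_similarity(w, ref, orient)
        if (sc[1L] > best[1L]) { best <- sc; bor <- orient }
      }
    }
    data.frame(family = box$instances$family[i],
               matches_of_17 = best[1L], matches_of_9 = best[2L],
               orientation = bor, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Serialize discovered boxes to JSON
#'
#' @param boxes List of `box_motif` objects.
#' @param path Output path.
#' @param cenpb Optional [cenpb_reference()]; when given, CENP-B scores are
#'   included.
#' @return `path`, invisibly.
#' @export
write_boxes_json <- function(boxes, path, cenpb = NULL) {
  out <- lapply(boxes, function(b) {
    x <- list(name = b$name, length = b$length, breadth = b$breadth,
              mean_identity = b$mean_identity, iupac = b$iupac,
              instances = b$instances)
    if (!is.null(cenpb)) x$cenpb <- score_box_cenpb(b, cenpb)
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
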