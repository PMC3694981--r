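# Key-String Algorithm: segmentation of multimeric arrays at every exact
# occurrence of a short "key" string, key selection, and circular register
# normalization of the extracted monomers.

#' Segment a sequence at every occurrence of a key string
#'
#' Cuts `seq` immediately before each exact, non-overlapping (left-greedy)
#' occurrence of `key`. The region before the first cut is flagged
#' `head_partial`; cut-to-cut segments are `complete`; the final segment
#' (last cut to the sequence end) is `complete` when its length equals the
#' modal cut-to-cut length and `tail_partial` otherwise. If the key does not
#' occur at all, the whole sequence is returned as a single segment flagged
#' `unsegmented`.
#'
#' @param seq A DNA string.
#' @param key The key string (length >= 2, alphabet `ACGT`; primer-scale
#'   keys of 10-16 bp are typical).
#' @return A list of class `key_segmentation` with elements `key`,
#'   `cut_offsets` (0-based) and `segments` (a data.frame with `start`, `end`,
#'   `seq`, `flag`).
#' @examples
#' segment_by_key("ACGTACGTACGT", "ACGT")
#' @export
segment_by_key <- function(seq, key) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(key) < 2L) stop("key length must be >= 2")
  if (grepl("[^ACGT]", key)) stop("key must be over {A,C,G,T}")
  L <- nchar(seq)
  m <- gregexpr(key, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) {
    segs <- data.frame(start = 0L, end = L, seq = seq, flag = "unsegmented",
                       stringsAsFactors = FALSE)
    return(structure(list(key = key, cut_offsets = integer(), segments = segs),
                     class = "key_segmentation"))
  }
  cuts <- as.integer(m) - 1L
  bounds <- c(cuts, L)
  starts <- c(if (cuts[1L] > 0L) 0L else integer(), cuts)
  ends <- c(if (cuts[1L] > 0L) cuts[1L] else integer(), bounds[-1L])
  flag <- rep("complete", length(starts))
  if (cuts[1L] > 0L) flag[1L] <- "head_partial"
  # classify the final segment against the modal cut-to-cut length
  inner_len <- diff(cuts)
  final_len <- L - cuts[length(cuts)]
  if (length(inner_len) == 0L) {
    flag[length(flag)] <- "tail_partial"
  } else {
    tab <- table(inner_len)
    modal <- as.integer(names(tab)[which.max(tab)])
    if (final_len != modal) flag[length(flag)] <- "tail_partial"
  }
  segs <- data.frame(start = starts, end = ends,
                     seq = substring(seq, starts + 1L, ends), flag = flag,
                     stringsAsFactors = FALSE)
  structure(list(key = key, cut_offsets = cuts, segments = segs),
            class = "key_segmentation")
}

#' @export
print.key_segmentation <- function(x, ...) {
  cat(sprintf("key '%s': %d cut(s), %d segment(s) (%d complete)\n", x$key,
              length(x$cut_offsets), nrow(x$segments),
              sum(x$segments$flag == "complete")))
  invisible(x)
}

#' Periodicity score of a key segmentation
#'
#' Fraction of complete segments whose length equals the modal
#' complete-segment length; 0 when fewer than two complete segments exist.
#' A score of 1 means the key cuts the array into a perfect ladder of
#' monomer-sized segments.
#'
#' @param segmentation A [segment_by_key()] result.
#' @return A score in `[0, 1]`.
#' @export
key_periodicity_score <- function(segmentation) {
  stopifnot(inherits(segmentation, "key_segmentation"))
  lens <- with(segmentation$segments, end[flag == "complete"] - start[flag == "complete"])
  if (length(lens) < 2L) return(0)
  tab <- table(lens)
  max(tab) / length(lens)
}

#' Select a key string by exhaustive periodicity scoring
#'
#' Scores every distinct k-mer of the first input sequence (k from `k_min` to
#' `k_max`) by segmenting all input sequences and pooling the complete
#' segments. The key maximizing (periodicity score, number of modal-length
#' segments) wins; ties are broken lexicographically. Returns `NULL` when no
#' key reaches `min_score` - e.g. on non-repetitive input.
#'
#' @param seqs Character vector (or `DNAStringSet`) of array sequences.
#' @param k_min,k_max Candidate key length range. Defaults 10 and 16
#'   (primer-scale keys).
#' @param min_score Minimum pooled periodicity score. Default 0.8.
#' @return A list with `key`, `score`, `modal_length`, `modal_count`, or
#'   `NULL`.
#' @export
select_key <- function(seqs, k_min = 10, k_max = 16, min_score = 0.8) {
  seqs <- as.character(seqs)
  stopifnot(length(seqs) >= 1L)
  first <- seqs[[1L]]
  best <- NULL
  for (k in k_min:k_max) {
    if (nchar(first) < k) next
    cand <- unique(substring(first, seq_len(nchar(first) - k + 1L),
                             seq_len(nchar(first) - k + 1L) + k - 1L))
    cand <- cand[!grepl("[^ACGT]", cand)]
    for (key in cand) {
      lens <- integer()
      for (s in seqs) {
        sg <- segment_by_key(s, key)
        lens <- c(lens, with(sg$segments, end[flag == "complete"] - start[flag == "complete"]))
      }
      if (length(lens) < 2L) next
      tab <- table(lens)
      score <- max(tab) / length(lens)
      if (score < min_score) next
      modal_count <- as.integer(max(tab))
      modal_length <- as.integer(names(tab)[which.max(tab)])
      if (is.null(best) ||
          score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 && modal_count > best$modal_count) ||
          (abs(score - best$score) <= 1e-12 && modal_count == best$modal_count &&
           key < best$key)) {
        best <- list(key = key, score = score, modal_length = modal_length,
                     modal_count = modal_count)
      }
    }
  }
  best
}

#' Rotate a monomer into the register of a reference
#'
#' Evaluates all cyclic rotations of `monomer` and returns the one whose
#' global alignment against `reference` scores best (ties: higher identity,
#' then the smallest offset; the raw score is used as the criterion because
#' end gaps do not enter the identity denominator and identity alone would
#' favour shifted partial alignments). Needed because the Key-String start
#' point is freely chosen, so monomers extracted with different keys live in
#' different registers.
#'
#' @param monomer,reference DNA strings with `|len(monomer) - len(reference)|
#'   <= 10`.
#' @param params [align_params()].
#' @return A list with `seq` (the rotated monomer), `offset` (rotation applied,
#'   in `[0, len)`) and `identity` (percent identity of the winning rotation).
#' @export
normalize_register <- function(monomer, reference, params = align_params()) {
  params <- as_align_params(params)
  monomer <- as.character(monomer); reference <- as.character(reference)
  if (abs(nchar(monomer) - nchar(reference)) > 10L)
    stop("length difference between monomer and reference exceeds 10")
  r <- cpp_best_rotation(monomer, reference, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
  list(seq = rotate_seq(monomer, r$offset), offset = r$offset,
       identity = r$identity)
}
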