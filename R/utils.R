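# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Alignment scoring parameters
#'
#' Scoring scheme for all pairwise global alignments in the package. A gap of
#' length `g` costs `gap_open + g * gap_extend` (the opening charge is applied
#' once, at the first gapped position). Percent identity is always
#' `100 * matches / columns` where neither row is a gap.
#'
#' Defaults (+2 / -1 / -10 / -4) keep gaps expensive, as is appropriate for
#' collinear satellite monomers whose divergence is substitution-dominated:
#' the identity of unrelated sequences then stays near the ungapped baseline
#' instead of being inflated by shifted spurious matches.
#'
#' @param match Match score (positive). Default 2.
#' @param mismatch Mismatch score. Default -1.
#' @param gap_open Gap opening score (<= gap_extend <= 0). Default -10.
#' @param gap_extend Per-position gap extension score. Default -4.
#' @return An object of class `align_params`.
#' @examples
#' align_params()
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = -10, gap_extend = -4) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap_open),
            is.numeric(gap_extend))
  if (!(gap_open <= gap_extend && gap_extend <= 0 && 0 <= match))
    stop("require gap_open <= gap_extend <= 0 <= match")
  if (!(mismatch < match)) stop("require mismatch < match")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

as_align_params <- function(params) {
  if (inherits(params, "align_params")) return(params)
  if (is.null(params)) return(align_params())
  do.call(align_params, as.list(params))
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf("alignment scores: match %+g, mismatch %+g, gap open %+g, gap extend %+g\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

# Deterministic per-stage child seed derived from one pipeline seed.
# Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 20000L) * 100003L + (h %% 100003L)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

rotate_seq <- function(seq, offset) {
  L <- nchar(seq)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0) return(seq)
  paste0(substr(seq, offset + 1L, L), substr(seq, 1L, offset))
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Substitute each site with probability mu, uniformly over the 3 other bases.
mutate_seq <- function(seq, mu) {
  if (mu <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < mu)
  for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
  paste(v, collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

# as.character() drops the names of a plain character vector; sequence sets
# are always name-keyed here, so coerce through this instead.
as_named_chr <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}
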