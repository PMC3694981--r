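# FASTA and GFF3 input/output and the coordinate conventions used everywhere.
#
# Internally all intervals are 0-based half-open on the forward strand of the
# sequence as deposited; the single conversion to 1-based inclusive happens at
# the GFF3/report boundary.

#' Read DNA sequences from a FASTA file
#'
#' Reads and validates a FASTA file. Sequences are uppercased and restricted
#' to the alphabet `A`, `C`, `G`, `T`, `N`; anything else is rejected with the
#' offending position. Record ids (the first whitespace-delimited token of the
#' header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with per-record
#'   `description` and `species` columns in its metadata
#'   (`S4Vectors::mcols()`). The species tag is parsed from a
#'   `[species=...]` token in the header when present.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">m1 first monomer", "ACGTACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as raw strings: the DNA reader silently drops invalid letters,
  # which must instead be reported with their position
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence: ", ids[nchar(seqs) == 0L][1L])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  desc <- sub("^\\S+\\s*", "", headers)
  species <- ifelse(grepl("\\[species=([^]]+)\\]", headers),
                    sub(".*\\[species=([^]]+)\\].*", "\\1", headers), NA_character_)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc, species = species)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    stopifnot(!is.null(names(seqs)))
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Construct a monomer annotation table
#'
#' The row-per-monomer annotation container used by the tiling annotator and
#' junction analyses. Intervals are 0-based half-open. `register_offset` is
#' the consensus coordinate aligned at the annotation start (`cons_end` the
#' one at its end), so a complete monomer in standard register has
#' `register_offset = 0` and `cons_end = monomer length`.
#'
#' @param seq_id,start,end,family,identity,register_offset,partial,cons_end
#'   Per-annotation vectors, recycled to a common length. `partial` is one of
#'   `"none"`, `"head"` (head of the monomer missing), `"tail"` (tail
#'   missing); `family` is `NA` for unassigned segments.
#' @return A `data.frame` of class `monomer_annotations`, sorted by
#'   `seq_id` and `start`.
#' @export
monomer_annotations <- function(seq_id = character(), start = integer(),
                                end = integer(), family = character(),
                                identity = numeric(), register_offset = integer(),
                                partial = character(), cons_end = integer()) {
  n <- max(length(seq_id), length(start), length(end))
  df <- data.frame(
    seq_id = rep_len(as.character(seq_id), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    family = rep_len(if (length(family)) as.character(family) else NA_character_, n),
    identity = rep_len(if (length(identity)) as.numeric(identity) else NA_real_, n),
    register_offset = rep_len(if (length(register_offset)) as.integer(register_offset) else 0L, n),
    cons_end = rep_len(if (length(cons_end)) as.integer(cons_end) else NA_integer_, n),
    partial = rep_len(if (length(partial)) as.character(partial) else "none", n),
    stringsAsFactors = FALSE)
  if (n > 0 && any(df$start >= df$end)) stop("intervals must satisfy start < end")
  df <- df[order(df$seq_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("monomer_annotations", "data.frame")
  df
}

#' Write monomer annotations as GFF3
#'
#' Internal 0-based half-open intervals are emitted as standard 1-based
#' inclusive GFF3 with feature type `satellite_monomer`; family label,
#' identity, register offset, consensus end coordinate and partial flag travel
#' as attributes. Unassigned segments are written with feature type
#' `unassigned_region`.
#'
#' @param annotations A [monomer_annotations()] table.
#' @param path Output path.
#' @param seqlens Named integer vector of sequence lengths, used for bounds
#'   checking (annotations beyond a known sequence end are an error).
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(annotations, path, seqlens = NULL) {
  ann <- as.data.frame(annotations)
  if (!is.null(seqlens)) {
    if (!all(ann$seq_id %in% names(seqlens)))
      stop("annotations reference unknown seq_id(s): ",
           paste(setdiff(unique(ann$seq_id), names(seqlens)), collapse = ", "))
    over <- ann$end > seqlens[ann$seq_id] | ann$start < 0L
    if (any(over))
      stop("annotation interval out of sequence bounds on ",
           ann$seq_id[which(over)[1L]])
  }
  if (nrow(ann) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ann$seq_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = "+")
  gr$source <- "satarray"
  gr$type <- ifelse(is.na(ann$family), "unassigned_region", "satellite_monomer")
  gr$family <- ifelse(is.na(ann$family), "NA", ann$family)
  gr$identity <- ifelse(is.na(ann$identity), "NA", sprintf("%.2f", ann$identity))
  gr$register_offset <- ann$register_offset
  gr$cons_end <- ifelse(is.na(ann$cons_end), "NA", as.character(ann$cons_end))
  gr$partial <- ann$partial
  if (!is.null(seqlens)) {
    GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read monomer annotations from GFF3
#'
#' Inverse of [write_annotations_gff3()]; 1-based inclusive GFF3 intervals are
#' converted back to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file written by [write_annotations_gff3()].
#' @return A [monomer_annotations()] table.
#' @export
read_annotations_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(monomer_annotations())
  fam <- as.character(gr$family)
  fam[fam == "NA"] <- NA_character_
  ident <- suppressWarnings(as.numeric(as.character(gr$identity)))
  ce <- suppressWarnings(as.integer(as.character(gr$cons_end)))
  monomer_annotations(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    family = fam,
    identity = ident,
    register_offset = as.integer(as.character(gr$register_offset)),
    partial = as.character(gr$partial),
    cons_end = ce)
}

# Fraction of N characters; monomers above `max_frac` are excluded from
# identity statistics (deposited records may carry ambiguity codes).
n_fraction <- function(seq) {
  lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE))) / nchar(seq)
}
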