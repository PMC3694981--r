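# FASTA and GFF3 I/O, validation, and the coordinate convention at the
# 0-based/1-based boundary.

write_tmp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}

test_that("read_fasta validates, normalizes case, preserves order", {
  tf <- write_tmp_fasta(c(">a first", "ACGT"))
  rec <- read_fasta(tf)
  expect_length(rec, 1L)
  expect_equal(unname(nchar(as.character(rec))), 4L)
  expect_equal(names(rec), "a")

  tf <- write_tmp_fasta(c(">a", "acgt"))
  expect_equal(unname(as.character(read_fasta(tf))), "ACGT")

  tf <- write_tmp_fasta(unlist(lapply(1:6, function(i) c(paste0(">s", i), "ACGTN"))))
  rec <- read_fasta(tf)
  expect_equal(names(rec), paste0("s", 1:6))

  tf <- write_tmp_fasta(c(">a", "ACGT", ">a", "TTTT"))
  expect_error(read_fasta(tf), "duplicate.*a")

  tf <- write_tmp_fasta(c(">a", "ACXGT"))
  expect_error(read_fasta(tf), "illegal character.*position 3")

  tf <- write_tmp_fasta(character(0))
  expect_error(read_fasta(tf))
})

test_that("FASTA write/read round trip is stable", {
  seqs <- setNames(c("ACGTACGT", "TTTTAACC"), c("x", "y"))
  tf <- tempfile(fileext = ".fa")
  write_fasta(seqs, tf)
  back <- read_fasta(tf)
  expect_equal(setNames(as.character(back), names(back)), seqs)
})

test_that("GFF3 export converts to 1-based inclusive and round trips", {
  ann <- monomer_annotations(seq_id = "clone1", start = 0L, end = 169L,
                             family = "1aM", identity = 97.5,
                             register_offset = 0L, partial = "none",
                             cons_end = 169L)
  tf <- tempfile(fileext = ".gff3")
  write_annotations_gff3(ann, tf, seqlens = c(clone1 = 200L))
  lines <- readLines(tf)
  row <- grep("satellite_monomer", lines, value = TRUE)[1]
  fields <- strsplit(row, "\t")[[1]]
  expect_equal(as.integer(fields[4]), 1L)    # 0-based 0 -> 1-based 1
  expect_equal(as.integer(fields[5]), 169L)  # half-open 169 -> inclusive 169

  back <- read_annotations_gff3(tf)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$family, ann$family)
  expect_equal(back$identity, ann$identity, tolerance = 1e-6)
  expect_equal(back$register_offset, ann$register_offset)
  expect_equal(back$partial, ann$partial)
})

test_that("GFF3 rejects out-of-bounds intervals and handles empty input", {
  ann <- monomer_annotations(seq_id = "c", start = 10L, end = 300L,
                             family = "f", identity = 90,
                             register_offset = 0L, partial = "none",
                             cons_end = 169L)
  expect_error(write_annotations_gff3(ann, tempfile(), seqlens = c(c = 200L)),
               "out of sequence bounds")
  expect_error(write_annotations_gff3(ann, tempfile(), seqlens = c(z = 400L)),
               "unknown seq_id")
  tf <- tempfile(fileext = ".gff3")
  write_annotations_gff3(monomer_annotations(), tf)
  expect_equal(readLines(tf)[1], "##gff-version 3")
})

test_that("GFF3 coordinate conversion is a bijection on random intervals", {
  set.seed(11)
  starts <- sort(sample(0:800, 12))
  ann <- monomer_annotations(seq_id = "c", start = starts,
                             end = starts + sample(50:150, 12, TRUE),
                             family = letters[1:12], identity = runif(12, 70, 100),
                             register_offset = sample(0:50, 12, TRUE),
                             partial = "none", cons_end = 169L)
  # keep non-overlap irrelevant: bijection is per-interval
  tf <- tempfile(fileext = ".gff3")
  write_annotations_gff3(ann, tf)
  back <- read_annotations_gff3(tf)
  ord <- order(back$start)
  expect_equal(back$start[ord], sort(ann$start))
  expect_equal(back$end[ord], ann$end[order(ann$start)])
})
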