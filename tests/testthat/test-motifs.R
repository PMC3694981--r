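# Conserved-box discovery, IUPAC consensus, and CENP-B similarity scoring.

make_divergent_set <- function(n_fam = 6, L = 169, seed = 61) {
  set.seed(seed)
  anc <- rand_dna(L)
  out <- vapply(seq_len(n_fam), function(i) satarray:::mutate_seq(anc, 0.45), "")
  setNames(out, paste0("fam", seq_len(n_fam)))
}

plant <- function(seqs, motif, at) {
  vapply(seqs, function(s)
    paste0(substr(s, 1, at), motif, substr(s, at + nchar(motif) + 1, nchar(s))), "")
}

test_that("iupac_consensus emits minimal degeneracy codes", {
  expect_equal(iupac_consensus(c("ACGT", "ACGT")), "ACGT")
  expect_equal(iupac_consensus(c("ACGT", "GCGT")), "RCGT")
  expect_equal(iupac_consensus(c("AAAA", "CCCC", "GGGG", "TTTT")), "NNNN")
  expect_error(iupac_consensus(c("ACG", "ACGT")), "conflicting")
  expect_error(iupac_consensus("ACGT"), ">= 2")
  # every instance matches its consensus pattern
  set.seed(67)
  for (i in 1:10) {
    inst <- vapply(1:4, function(j) rand_dna(10), "")
    pat <- iupac_consensus(inst)
    m <- do.call(rbind, strsplit(inst, ""))
    codes <- strsplit(pat, "")[[1]]
    iupac_sets <- Biostrings::IUPAC_CODE_MAP
    for (col in 1:10)
      expect_true(all(grepl(paste0("[", iupac_sets[codes[col]], "]"), m[, col])))
  }
})

test_that("a planted identical motif is found with full breadth", {
  seqs <- make_divergent_set()
  motif <- "ACGTTCCGGAATTCGAC"  # 17 bp
  seqs <- plant(seqs, motif, 100)
  boxes <- find_shared_boxes(seqs)
  expect_gte(length(boxes), 1L)
  b1 <- boxes[[1]]
  expect_equal(b1$breadth, 6L)
  expect_gte(b1$length, 17L)
  # the box covers the plant in every family
  for (i in seq_len(nrow(b1$instances))) {
    expect_lte(b1$instances$start[i], 100)
    expect_gte(b1$instances$end[i], 117)
  }
})

test_that("no boxes are reported for unrelated sequences", {
  set.seed(71)
  seqs <- setNames(vapply(1:6, function(i) rand_dna(169), ""), paste0("f", 1:6))
  expect_length(find_shared_boxes(seqs), 0L)
})

test_that("two planted motifs are separated with their own breadths", {
  seqs <- make_divergent_set(6, seed = 73)
  m1 <- "ACGTTCCGGAATTCGAC"         # all six families
  m2 <- "TTCTTTCAAACTTCCTTTCA"      # 20 bp, families 1-5 only
  seqs <- plant(seqs, m1, 60)
  seqs[1:5] <- plant(seqs[1:5], m2, 130)
  boxes <- find_shared_boxes(seqs)
  expect_gte(length(boxes), 2L)
  expect_equal(boxes[[1]]$breadth, 6L)
  expect_equal(boxes[[2]]$breadth, 5L)
  expect_setequal(boxes[[2]]$instances$family, paste0("fam", 1:5))
})

test_that("box discovery is invariant to family order", {
  seqs <- make_divergent_set(5, seed = 79)
  seqs <- plant(seqs, "ACGTTCCGGAATTCGAC", 90)
  b1 <- find_shared_boxes(seqs)
  b2 <- find_shared_boxes(rev(seqs))
  expect_equal(length(b1), length(b2))
  expect_equal(b1[[1]]$breadth, b2[[1]]$breadth)
  expect_true(all(abs(sort(b1[[1]]$instances$start) -
                      sort(b2[[1]]$instances$start)) <= 3))
})

test_that("cenpb_similarity counts positional matches with orientation", {
  ref <- cenpb_reference()
  expect_equal(unname(cenpb_similarity(ref$consensus, ref)), c(17L, 9L))
  # sequence differing exactly at the 9 essential positions -> (8, 0)
  v <- strsplit(ref$consensus, "")[[1]]
  for (p in ref$essential_positions)
    v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  expect_equal(unname(cenpb_similarity(paste(v, collapse = ""), ref)), c(8L, 0L))
  # reverse-complement orientation restores a flipped motif
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref$consensus)))
  expect_equal(unname(cenpb_similarity(rc, ref, "revcomp")), c(17L, 9L))
  # a single deleted base is padded with '-', which never matches
  padded <- paste0(substr(ref$consensus, 1, 8), "-", substr(ref$consensus, 10, 17))
  expect_equal(unname(cenpb_similarity(padded, ref))[1], 16L)
  expect_error(cenpb_similarity(substr(ref$consensus, 1, 16), ref), "pad")
  expect_error(cenpb_similarity("ACGT", ref), "16-17")
})

test_that("similarity plus Hamming distance is conserved at 17", {
  ref <- cenpb_reference()
  set.seed(83)
  for (i in 1:20) {
    x <- rand_dna(17)
    sim <- cenpb_similarity(x, ref)[1]
    ham <- sum(strsplit(x, "")[[1]] != strsplit(ref$consensus, "")[[1]])
    expect_equal(unname(sim) + ham, 17L)
  }
})

test_that("the default planted Box 1 scores in the reported CENP-B range", {
  master <- default_box1_master()
  sc <- cenpb_similarity(master, cenpb_reference(), orientation = "revcomp")
  expect_equal(unname(sc), c(11L, 5L))
})
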