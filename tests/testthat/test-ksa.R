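# Key-String Algorithm: cutting, periodicity scoring, key selection, and
# circular register normalization.

test_that("segment_by_key cuts at exact occurrences and tiles the input", {
  sg <- segment_by_key("ACGTACGTACGT", "ACGT")
  expect_equal(sg$cut_offsets, c(0L, 4L, 8L))
  expect_equal(nrow(sg$segments), 3L)
  expect_true(all(sg$segments$flag == "complete"))
  expect_equal(sg$segments$end - sg$segments$start, rep(4L, 3))
  # tiling property: concatenation reconstructs the input
  expect_equal(paste(sg$segments$seq, collapse = ""), "ACGTACGTACGT")

  sg <- segment_by_key("TTTT", "ACGT")
  expect_equal(sg$segments$flag, "unsegmented")
  expect_equal(sg$segments$seq, "TTTT")
})

test_that("self-overlapping keys follow the left-greedy rule (vs enumeration)", {
  expect_equal(segment_by_key("AAAA", "AA")$cut_offsets,
               oracle_occurrences("AAAA", "AA"))
  set.seed(5)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C"), 60, TRUE), collapse = "")
    key <- paste(sample(c("A", "C"), 4, TRUE), collapse = "")
    sg <- segment_by_key(s, key)
    expect_equal(sg$cut_offsets, oracle_occurrences(s, key), info = s)
    expect_equal(paste(sg$segments$seq, collapse = ""), s)
  }
})

test_that("key periodicity score counts modal complete segments", {
  set.seed(7)
  mono <- rand_dna(169)
  arr <- paste(rep(mono, 8), collapse = "")
  key <- substr(mono, 1, 12)
  expect_equal(key_periodicity_score(segment_by_key(arr, key)), 1)
  # equal numbers of monomer- and dimer-sized segments -> 0.5
  key12 <- "ACGTACCGGTTA"
  filler <- function(n) gsub("G", "C", rand_dna(n))  # cannot contain the key
  mixed <- paste(c(vapply(1:5, function(i) paste0(key12, filler(157)), ""),
                   vapply(1:6, function(i) paste0(key12, filler(326)), "")),
                 collapse = "")
  expect_equal(key_periodicity_score(segment_by_key(mixed, key12)), 0.5)
  # single complete segment -> 0
  expect_equal(key_periodicity_score(segment_by_key("TTTT", "ACGT")), 0)
})

test_that("select_key recovers monomer length on a clean tandem and rejects noise", {
  set.seed(13)
  mono <- rand_dna(169)
  arr <- paste(rep(mono, 8), collapse = "")
  k <- select_key(arr)
  expect_false(is.null(k))
  expect_equal(k$score, 1)
  expect_equal(k$modal_length, 169L)
  expect_equal(k$modal_count, 8L)
  # mutation-free tandem: cuts are congruent to the key position mod 169
  sg <- segment_by_key(arr, k$key)
  expect_true(all(diff(sg$cut_offsets) == 169L))

  expect_null(select_key(rand_dna(2000)))
})

test_that("select_key avoids an internally duplicated region", {
  set.seed(17)
  mono <- rand_dna(169)
  dup <- paste0(substr(mono, 1, 30), substr(mono, 1, 139))  # 30-bp head repeat
  arr <- paste(rep(dup, 8), collapse = "")
  k <- select_key(arr)
  expect_false(is.null(k))
  # a key inside the duplicated 30-mer would double-cut; the winner must cut
  # once per monomer, at a register outside the duplicated head
  expect_equal(k$modal_length, 169L)
  expect_equal(k$score, 1)
  sg <- segment_by_key(arr, k$key)
  expect_true(all(sg$cut_offsets %% 169L >= 30L))
})

test_that("normalize_register inverts cyclic rotations, also under noise", {
  set.seed(19)
  ref <- rand_dna(169)
  r <- normalize_register(ref, ref)
  expect_equal(r$offset, 0L)
  expect_equal(r$identity, 100)

  rot <- satarray:::rotate_seq(ref, 10)
  r <- normalize_register(rot, ref)
  expect_equal(r$offset, 169L - 10L)  # group inverse of the applied rotation
  expect_equal(r$identity, 100)
  expect_equal(r$seq, ref)

  for (k in c(13, 40, 100)) {
    noisy <- satarray:::mutate_seq(satarray:::rotate_seq(ref, k), 0.03)
    r <- normalize_register(noisy, ref)
    expect_equal(r$offset, (169L - k) %% 169L, info = paste("k =", k))
  }
  expect_error(normalize_register(rand_dna(100), rand_dna(169)), "length difference")
})
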