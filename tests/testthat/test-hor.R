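# Tiling annotation, HOR-unit inference, classification, junction extraction,
# box co-location, and rearrangement detection.

make_family_pair <- function(seed = 91) {
  set.seed(seed)
  A <- rand_dna(169)
  B <- satarray:::mutate_seq(A, 0.4)
  C <- satarray:::mutate_seq(A, 0.45)
  c(A = A, B = B, C = C)
}

test_that("tiling recovers exact copies and noisy HOR units", {
  fams <- make_family_pair()
  arr <- paste(rep(fams[["A"]], 5), collapse = "")
  ann <- as.data.frame(tile_annotate(arr, family_model_set(fams), seq_id = "x"))
  got <- ann[!is.na(ann$family), ]
  expect_equal(nrow(got), 5L)
  expect_equal(got$start, (0:4) * 169L)
  expect_equal(got$end, (1:5) * 169L)
  expect_true(all(got$identity == 100))
  expect_true(all(got$family == "A"))

  # 3 units of A-B-C with 3% noise: 9 monomers, labels right, bounds +-2
  set.seed(93)
  unit <- c("A", "B", "C")
  copies <- vapply(rep(unit, 3), function(f) satarray:::mutate_seq(fams[[f]], 0.03), "")
  arr <- paste(copies, collapse = "")
  ann <- as.data.frame(tile_annotate(arr, family_model_set(fams), seq_id = "x"))
  got <- ann[!is.na(ann$family), ]
  expect_equal(nrow(got), 9L)
  expect_equal(got$family, rep(unit, 3))
  expect_true(all(abs(got$start - (0:8) * 169L) <= 2))

  # a random spacer between monomer blocks stays unassigned
  arr <- paste0(paste(rep(fams[["A"]], 2), collapse = ""), rand_dna(170),
                paste(rep(fams[["B"]], 2), collapse = ""))
  ann <- as.data.frame(tile_annotate(arr, family_model_set(fams), seq_id = "x"))
  un <- ann[is.na(ann$family), ]
  expect_equal(nrow(un), 1L)
  expect_true(abs(un$start - 338) <= 2 && abs(un$end - 508) <= 2)

  # annotations tile the clone exactly
  expect_equal(ann$start[1], 0L)
  expect_equal(ann$end[nrow(ann)], nchar(arr))
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)]))

  # sequences shorter than half a monomer come back unassigned
  stub <- as.data.frame(tile_annotate(rand_dna(40), family_model_set(fams)))
  expect_true(is.na(stub$family))
})

test_that("infer_hor_unit finds the minimal period (vs brute force)", {
  u <- infer_hor_unit(c("A", "B", "A", "B", "A", "B"))
  expect_equal(u$labels, c("A", "B"))
  expect_equal(u$period, 2L)
  u <- infer_hor_unit(c("A", "B", "C", "A", "B", "C", "A", "B"))
  expect_equal(u$labels, c("A", "B", "C"))
  expect_false(u$non_periodic)

  set.seed(97)
  for (i in 1:100) {
    labs <- sample(letters[1:3], sample(2:12, 1), TRUE)
    expect_equal(infer_hor_unit(labs)$period, oracle_min_period(labs),
                 info = paste(labs, collapse = ""))
  }
  expect_true(infer_hor_unit(c("A", "B", "C"))$non_periodic)
})

test_that("HOR variants follow the 1b rule", {
  long_unit <- c("1dMH", "2aMH", "1cMH", "U1", "1aH", "1bH", "1b'H")
  expect_equal(infer_hor_unit(rep(long_unit, 2))$variant, "long")
  short_unit <- setdiff(long_unit, "1bH")
  expect_equal(infer_hor_unit(rep(short_unit, 2))$variant, "short")
  expect_equal(infer_hor_unit(c("A", "B", "A", "B"))$variant, "other")
})

test_that("classify_array distinguishes the four organizations", {
  expect_equal(classify_array(rep("1aM", 6)), "monomeric")
  expect_equal(classify_array(rep(c("1cMH", "1dMH"), 3)), "dimeric")
  expect_equal(classify_array(rep(c("1d", "2a", "1c", "U1", "1a"), 3)), "HOR")
  expect_equal(classify_array(c("a", "b", "c", "c", "a", "b", "b")), "complex")
  expect_error(classify_array("1aM"), ">= 2")
})

test_that("junction extraction reports boundaries between unlike monomers", {
  fams <- make_family_pair(101)
  mono <- monomer_annotations(seq_id = "m", start = (0:5) * 169L,
                              end = (1:6) * 169L, family = "A",
                              identity = 99, register_offset = 0L,
                              partial = "none", cons_end = 169L)
  expect_equal(nrow(extract_junctions(mono)), 0L)

  dimer <- monomer_annotations(seq_id = "d", start = (0:5) * 169L,
                               end = (1:6) * 169L,
                               family = rep(c("A", "B"), 3),
                               identity = 99, register_offset = 0L,
                               partial = "none", cons_end = 169L)
  j <- extract_junctions(dimer)
  expect_equal(nrow(j), 5L)
  expect_equal(j$position, (1:5) * 169L)
  expect_equal(j$left_family, rep(c("A", "B"), 3)[1:5])
})

test_that("box co-location separates box-bound from uniform junctions", {
  set.seed(103)
  fams <- make_family_pair(107)
  boxes <- list(A = list(Box1 = c(120, 137)), B = list(Box1 = c(120, 137)),
                C = list())
  models <- family_model_set(fams, boxes)
  # 12 junctions, all with the boundary at the box
  j_in <- data.frame(seq_id = "s", position = 1:12 * 100L,
                     left_family = "A", right_family = "B",
                     left_cons_end = 125L, right_cons_start = 128L,
                     left_partial = "tail", right_partial = "head",
                     stringsAsFactors = FALSE)
  r <- box_colocation_test(j_in, models, n_perm = 5000, seed = 5)
  expect_equal(r$observed_fraction, 1)
  expect_lt(r$p_value, 0.001)
  expect_true(all(r$junctions$in_box == "Box1"))
  # same seed, same p
  r2 <- box_colocation_test(j_in, models, n_perm = 5000, seed = 5)
  expect_identical(r$p_value, r2$p_value)

  # uniform junction positions: fraction near coverage, p not significant
  nsig <- 0L; fracs <- numeric()
  for (s in 1:20) {
    set.seed(s)
    pos <- sample(0:168, 12, TRUE)
    j_u <- j_in
    j_u$left_cons_end <- pos
    j_u$right_cons_start <- sample(0:168, 12, TRUE)
    r <- box_colocation_test(j_u, models, n_perm = 1000, seed = s)
    fracs <- c(fracs, r$observed_fraction)
    if (r$p_value < 0.05) nsig <- nsig + 1L
  }
  cover <- 1 - (1 - 23 / 169)^2   # box+tol on either side
  expect_lt(abs(mean(fracs) - cover), 0.12)
  expect_lte(nsig, 4L)
})

test_that("box co-location p-values are honest under the null", {
  fams <- make_family_pair(109)
  models <- family_model_set(fams, list(A = list(Box1 = c(120, 137)),
                                        B = list(Box1 = c(120, 137)),
                                        C = list()))
  set.seed(111)
  ps <- vapply(1:200, function(i) {
    j <- data.frame(seq_id = "s", position = 1:8 * 50L,
                    left_family = "A", right_family = "B",
                    left_cons_end = sample(0:168, 8, TRUE),
                    right_cons_start = sample(0:168, 8, TRUE),
                    left_partial = "none", right_partial = "none",
                    stringsAsFactors = FALSE)
    box_colocation_test(j, models, n_perm = 400, seed = i)$p_value
  }, numeric(1))
  # super-uniform: the rejection rate never exceeds the nominal level by much
  expect_lte(mean(ps <= 0.05), 0.09)
  expect_lte(mean(ps <= 0.2), 0.27)
})

test_that("Box-1 replacement and overlap junctions are detected from truth-like annotations", {
  set.seed(113)
  # families with a shared box in identical coordinates
  anc <- rand_dna(169)
  box <- "ACGTTCCGGAATTCGAC"
  mk <- function(div) {
    s <- satarray:::mutate_seq(anc, div)
    paste0(substr(s, 1, 120), box, substr(s, 138, 169))
  }
  fams <- c(X = mk(0), D = mk(0.4), Y = mk(0.45))
  boxes <- list(X = list(Box1 = c(120, 137)), D = list(Box1 = c(120, 137)),
                Y = list(Box1 = c(120, 137)))
  models <- family_model_set(fams, boxes)
  arr <- generate_array(list(type = "dimeric", unit = c("X", "Y"), copies = 3),
                        fams, mu = 0, seed = 1, seq_id = "arr")
  arr2 <- apply_insertion_at_box1(arr, "D", 2L, fams, boxes, mu = 0)
  # detection on the simulator's exact truth annotations
  ev <- detect_box1_replacement(arr2$truth, models)
  expect_equal(nrow(ev), 1L)
  tr_ev <- arr2$events[[1]]
  expect_equal(ev$donor_family, "D")
  expect_equal(ev$left_truncation, tr_ev$left_truncation)
  expect_equal(ev$right_resume, tr_ev$right_resume)
  expect_equal(ev$extruded_length, tr_ev$extruded_length)
  # and end-to-end through the tiler (box-width ambiguity allowed)
  ann <- tile_annotate(arr2$seq, models, seq_id = "arr")
  ev2 <- detect_box1_replacement(ann, models)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$donor_family, "D")
  expect_lte(abs(ev2$extruded_length - tr_ev$extruded_length), 3)
  # intact arrays yield no replacement events
  expect_equal(nrow(detect_box1_replacement(arr$truth, models)), 0L)

  # overlap junction: right monomer extends into the left one
  ofams <- make_overlap_families(seed = 117)
  oarr <- generate_array(list(type = "complex", unit = c("famA", "famA", "famB", "famB")),
                         ofams, mu = 0, seed = 2, seq_id = "ov")
  oarr <- apply_overlap_junction(oarr, 2L, 50L)
  omod <- family_model_set(ofams)
  ov <- detect_overlap_junction(oarr$truth, omod, setNames(oarr$seq, "ov"),
                                min_identity = 85)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlap_length, 50L)
  expect_equal(ov$mismatches, 6L)
  # clean junctions between unrelated families produce no overlap events
  fams2 <- make_family_pair(119)
  carr <- generate_array(list(type = "dimeric", unit = c("A", "B"), copies = 2),
                         fams2, mu = 0, seed = 3, seq_id = "cl")
  ovc <- detect_overlap_junction(carr$truth, family_model_set(fams2),
                                 setNames(carr$seq, "cl"))
  expect_equal(nrow(ovc), 0L)
})
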