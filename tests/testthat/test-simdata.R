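# The synthetic-data generator: family evolution to a target identity
# matrix, box implantation, array generation, rearrangement operators, and
# dataset-level determinism.

small_config <- function(seed = 1) {
  labels <- c("fA", "fB", "fC", "fD")
  tg <- matrix(100, 4, 4)
  tg[lower.tri(tg)] <- c(60, 45, 40, 50, 42, 55)
  tg[upper.tri(tg)] <- t(tg)[upper.tri(tg)]
  sim_config(seed = seed, labels = labels, lengths = rep(169L, 4),
             divergence_targets = tg, mu = 0.03,
             boxes = list(list(name = "Box1", length = 17L, position = 100L,
                               breadth = "all", degeneracy = 1L,
                               master = default_box1_master())),
             array_plans = list(arr = list(type = "monomeric", unit = "fA",
                                           copies = 6L)))
}

test_that("evolve_family_set hits its identity targets deterministically", {
  cfg <- small_config(3)
  fam <- evolve_family_set(cfg)
  # consensus-level identities land on the mu-adjusted consensus targets
  dev <- fam$realized - fam$targets_consensus
  diag(dev) <- 0
  expect_lt(max(abs(dev)), 5)
  # copy-level identities (what an identity table over monomers measures)
  # land on the configured targets
  set.seed(1)
  groups <- lapply(fam$consensuses, function(cs)
    vapply(1:12, function(i) satarray:::mutate_seq(cs, cfg$mu), ""))
  im <- group_identity_matrix(groups)
  dev2 <- im$mean - cfg$divergence_targets
  diag(dev2) <- 0
  expect_lt(max(abs(dev2)), 5)
  expect_true(all(nchar(fam$consensuses) == 169L))
  # identical targets of 100 give identical consensuses
  cfg2 <- sim_config(seed = 5, labels = c("a", "b"), lengths = c(169L, 169L),
                     divergence_targets = matrix(100, 2, 2), mu = 0)
  fam2 <- evolve_family_set(cfg2)
  expect_equal(fam2$consensuses[["a"]], fam2$consensuses[["b"]])
  # same seed, byte-identical output
  expect_identical(evolve_family_set(small_config(3))$consensuses,
                   fam$consensuses)
})

test_that("implant_boxes plants masters with bounded degeneracy", {
  set.seed(121)
  cons <- setNames(vapply(1:4, function(i) rand_dna(169), ""), paste0("f", 1:4))
  master <- "ACGTTCCGGAATTCGAC"
  imp <- implant_boxes(cons, list(list(name = "Box1", length = 17L,
                                       position = 120L, breadth = "all",
                                       degeneracy = 1L, master = master)),
                       seed = 9)
  expect_true(all(nchar(imp$consensuses) == 169L))
  inst <- vapply(imp$consensuses, function(s) substr(s, 121, 137), "")
  hd <- vapply(inst, function(x)
    sum(strsplit(x, "")[[1]] != strsplit(master, "")[[1]]), integer(1))
  expect_equal(unname(hd[1]), 0L)       # first family carries the exact master
  expect_true(all(hd <= 1L))            # degeneracy bound
  expect_equal(imp$boxes$f2$Box1, c(120L, 137L))
  # overlapping boxes are rejected
  expect_error(implant_boxes(cons, list(
    list(name = "A", length = 17L, position = 120L, breadth = "all", master = master),
    list(name = "B", length = 20L, position = 130L, breadth = "all",
         master = "TTCTTTCAAACTTCCTTTCA"))), "overlapping")
})

test_that("generate_array emits exact truth at mu = 0 and the right noise at mu > 0", {
  set.seed(127)
  cons <- c(X = rand_dna(169), Y = rand_dna(169))
  arr <- generate_array(list(type = "monomeric", unit = "X", copies = 10),
                        cons, mu = 0, seed = 4, seq_id = "m")
  expect_equal(arr$seq, strrep(cons[["X"]], 10))
  expect_equal(arr$truth$start, (0:9) * 169L)
  expect_equal(arr$truth$end, (1:10) * 169L)

  dimer <- generate_array(list(type = "dimeric", unit = c("X", "Y"), copies = 5),
                          cons, mu = 0, seed = 4)
  expect_equal(dimer$truth$family, rep(c("X", "Y"), 5))

  # copy-vs-copy identity concentrates at 100((1-mu)^2 + mu^2/3)
  arr <- generate_array(list(type = "monomeric", unit = "X", copies = 50),
                        cons, mu = 0.03, seed = 6)
  copies <- substring(arr$seq, arr$truth$start + 1L, arr$truth$end)
  im <- group_identity_matrix(list(g = copies, h = copies[1:2]))
  expected <- 100 * ((1 - 0.03)^2 + 0.03^2 / 3)
  expect_lt(abs(im$mean["g", "g"] - expected), 1.5)
})

test_that("rearrangement operators keep truth consistent with the sequence", {
  set.seed(131)
  anc <- rand_dna(169)
  box <- "ACGTTCCGGAATTCGAC"
  mk <- function(div) {
    s <- satarray:::mutate_seq(anc, div)
    paste0(substr(s, 1, 120), box, substr(s, 138, 169))
  }
  fams <- c(X = mk(0), D = mk(0.4), Y = mk(0.45))
  boxes <- list(X = list(Box1 = c(120, 137)), D = list(Box1 = c(120, 137)),
                Y = list(Box1 = c(120, 137)))
  arr <- generate_array(list(type = "dimeric", unit = c("X", "Y"), copies = 3),
                        fams, mu = 0, seed = 2, seq_id = "a")
  ins <- apply_insertion_at_box1(arr, "D", 3L, fams, boxes, mu = 0)
  # the full donor consensus (in Box-1 register) appears verbatim
  donor_rot <- satarray:::rotate_seq(fams[["D"]], 120)
  expect_true(grepl(donor_rot, ins$seq, fixed = TRUE))
  ev <- ins$events[[1]]
  expect_equal(substr(ins$seq, ev$donor_start + 1, ev$donor_end), donor_rot)
  expect_equal(ev$extruded_length, 169L)
  # truth re-extraction reproduces the emitted sequence exactly
  tr <- as.data.frame(ins$truth)
  expect_equal(tr$start[1], 0L)
  expect_equal(tr$end[nrow(tr)], nchar(ins$seq))
  expect_true(all(tr$start[-1] == tr$end[-nrow(tr)]))
  expect_error(apply_insertion_at_box1(arr, "D", 99L, fams, boxes), "invalid junction")
  nobox <- list(X = list(), D = list(Box1 = c(120, 137)), Y = list())
  expect_error(apply_insertion_at_box1(arr, "D", 3L, fams, nobox), "lack")

  # recombination at a terminal box
  boxes2 <- list(X = list(Box2 = c(149, 169)), Y = list(Box2 = c(149, 169)),
                 D = list())
  a1 <- generate_array(list(type = "monomeric", unit = "X", copies = 4), fams,
                       mu = 0, seed = 7, seq_id = "p")
  a2 <- generate_array(list(type = "monomeric", unit = "Y", copies = 4), fams,
                       mu = 0, seed = 8, seq_id = "q")
  ch <- apply_recombination_at_box2(a1, a2, boxes2, seed = 11)
  evr <- ch$events[[1]]
  # junction falls inside Box 2 of both parents
  expect_gte(evr$junction_cons, 149)
  expect_lt(evr$junction_cons, 169)
  tr <- as.data.frame(ch$truth)
  expect_equal(tr$end[nrow(tr)], nchar(ch$seq))
  # same seed gives an identical chimera
  ch2 <- apply_recombination_at_box2(a1, a2, boxes2, seed = 11)
  expect_identical(ch$seq, ch2$seq)
  expect_error(apply_recombination_at_box2(a1, a2, list(X = list(), Y = list()),
                                           seed = 1), "no Box2")
})

test_that("simulate_dataset is plan-complete and byte-deterministic", {
  cfg <- default_sim_config(seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_dataset(cfg, dir = d1)
  s2 <- simulate_dataset(default_sim_config(seed = 9), dir = d2)
  expect_equal(length(s1$arrays), 6L)  # 5 planned + 1 recombination chimera
  expect_equal(length(s1$events), 2L)
  expect_identical(readLines(file.path(d1, "arrays.fa")),
                   readLines(file.path(d2, "arrays.fa")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  # dimeric plan alternates labels strictly (before the insertion event)
  plain <- generate_array(cfg$array_plans$dimer, s1$families, mu = cfg$mu,
                          seed = 1)
  expect_equal(plain$truth$family, rep(c("1cMH", "1dMH"), 6))
  # spacer and family consensuses all present
  expect_setequal(names(s1$families), c(cfg$labels, "U1"))
})

test_that("overlap families share the constructed head/tail region", {
  fams <- make_overlap_families(seed = 137, overlap_len = 50, n_subs = 6)
  tailA <- substr(fams[[1]], 120, 169)
  headB <- substr(fams[[2]], 1, 50)
  d <- sum(strsplit(tailA, "")[[1]] != strsplit(headB, "")[[1]])
  expect_equal(d, 6L)
})
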