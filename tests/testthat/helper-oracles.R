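# Independent oracles used to cross-check the package's kernels. These are
# deliberately separate implementations: plain-R dynamic programming for
# global affine alignment, exhaustive enumeration for key occurrences and
# minimal periods.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Plain-R Gotoh global alignment. Same scoring convention as the package
# (gap of length g costs open + g*extend) and same deterministic preference
# (diagonal, then gap consuming `a`, then gap consuming `b`), but an
# independent matrix-based implementation.
oracle_global_align <- function(a, b, match = 2, mismatch = -1,
                                gap_open = -10, gap_extend = -4) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  tM <- matrix(0L, n + 1, m + 1); tX <- matrix(0L, n + 1, m + 1)
  tY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) { X[i + 1, 1] <- gap_open + i * gap_extend
                          tX[i + 1, 1] <- if (i == 1) 0L else 1L }
  for (j in seq_len(m)) { Y[1, j + 1] <- gap_open + j * gap_extend
                          tY[1, j + 1] <- if (j == 1) 0L else 2L }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (av[i] == bv[j]) match else mismatch
    cand <- c(M[i, j], X[i, j], Y[i, j])
    k <- which.max(cand)
    M[i + 1, j + 1] <- cand[k] + s; tM[i + 1, j + 1] <- k - 1L
    cand <- c(M[i, j + 1] + gap_open + gap_extend,
              X[i, j + 1] + gap_extend,
              Y[i, j + 1] + gap_open + gap_extend)
    k <- which.max(cand)
    X[i + 1, j + 1] <- cand[k]; tX[i + 1, j + 1] <- k - 1L
    cand <- c(M[i + 1, j] + gap_open + gap_extend,
              Y[i + 1, j] + gap_extend,
              X[i + 1, j] + gap_open + gap_extend)
    k <- which.max(cand)
    Y[i + 1, j + 1] <- cand[k]
    tY[i + 1, j + 1] <- c(0L, 1L, 2L)[k]
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin) - 1L
  score <- fin[state + 1L]
  i <- n; j <- m; matches <- 0L; paircols <- 0L
  while (i > 0 || j > 0) {
    if (state == 0L) {
      if (av[i] == bv[j]) matches <- matches + 1L
      paircols <- paircols + 1L
      state <- tM[i + 1, j + 1]; i <- i - 1L; j <- j - 1L
    } else if (state == 1L) {
      state <- tX[i + 1, j + 1]; i <- i - 1L
    } else {
      state <- tY[i + 1, j + 1]; j <- j - 1L
    }
  }
  list(score = score, matches = matches, paircols = paircols,
       identity = if (paircols > 0) 100 * matches / paircols else 0)
}

# Left-greedy non-overlapping occurrence enumeration by direct scanning.
oracle_occurrences <- function(seq, key) {
  out <- integer(); i <- 1L
  n <- nchar(seq); k <- nchar(key)
  while (i <= n - k + 1L) {
    if (substr(seq, i, i + k - 1L) == key) { out <- c(out, i - 1L); i <- i + k }
    else i <- i + 1L
  }
  out
}

# Brute-force minimal period: smallest p such that the label vector is a
# prefix of the infinite repetition of its first p elements.
oracle_min_period <- function(labels) {
  n <- length(labels)
  for (p in seq_len(n)) {
    ok <- TRUE
    for (i in seq_len(n)) {
      if (labels[i] != labels[((i - 1L) %% p) + 1L]) { ok <- FALSE; break }
    }
    if (ok) return(p)
  }
  n
}

# Additive distance matrix from a random binary tree with given tip count.
oracle_random_additive <- function(n_tips, min_bl = 0.05, max_bl = 0.3) {
  tr <- ape::rtree(n_tips, br = function(k) stats::runif(k, min_bl, max_bl))
  tr <- ape::unroot(tr)
  list(tree = tr, d = cophenetic(tr))
}
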