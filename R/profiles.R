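# Per-site variability profiling of aligned monomers: percent occurrence of
# the most frequent base per column, sliding-window smoothing, and calling of
# low-variability (conserved) domains.

#' Per-site majority-base profile of an alignment
#'
#' For each alignment column the percent occurrence of the most frequent
#' non-gap base, computed over the non-gap rows of that column. Columns with
#' less than 50% non-gap coverage are excluded from the profile and reported
#' in `excluded_sites`.
#'
#' @param alignment Character matrix or equal-length gapped strings (>= 2
#'   rows).
#' @return An object of class `variability_profile`: `site_values` (percent,
#'   one per retained column), `site_index` (original column indices, 1-based),
#'   `excluded_sites`, `overall_mean`, `overall_sd` (mean and SD of the site
#'   values, the statistics drawn on a variability plot), `n_rows`.
#' @export
site_majority_profile <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 2L) stop("need >= 2 aligned rows")
  L <- ncol(m)
  vals <- numeric(0); keep <- integer(0); excl <- integer(0)
  for (j in seq_len(L)) {
    col <- m[, j]
    bases <- col[col %in% DNA_BASES]
    if (length(bases) < nrow(m) / 2) {
      if (length(bases) == 0L)
        warning("all-gap column ", j, " excluded from profile")
      excl <- c(excl, j)
      next
    }
    vals <- c(vals, 100 * max(table(bases)) / length(bases))
    keep <- c(keep, j)
  }
  structure(list(site_values = vals, site_index = keep, excluded_sites = excl,
                 overall_mean = mean(vals), overall_sd = stats::sd(vals),
                 n_rows = nrow(m), window_length = NA_integer_,
                 step = NA_integer_, window_values = NULL,
                 window_starts = NULL),
            class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, ...) {
  cat(sprintf("variability profile: %d sites, mean P %.1f%% (SD %.1f)\n",
              length(x$site_values), x$overall_mean, x$overall_sd))
  if (!is.null(x$window_values))
    cat(sprintf("  %d windows (w = %d, step = %d)\n", length(x$window_values),
                x$window_length, x$step))
  invisible(x)
}

#' Sliding-window means of a site profile
#'
#' Window `i` (0-based) covers sites `[i*s, i*s + w)`; its value is the
#' arithmetic mean of the site values. The number of windows is
#' `floor((L - w)/s) + 1`.
#'
#' @param site_values Numeric vector of per-site values, or a
#'   `variability_profile` (whose windows are then filled in).
#' @param w Window length in sites. Default 15.
#' @param s Step size in sites. Default 2.
#' @return For numeric input, a numeric vector of window means with attribute
#'   `starts` (0-based window start sites); for a profile, the updated
#'   profile.
#' @examples
#' length(sliding_window(rep(100, 169), w = 15, s = 2))  # 78 windows
#' @export
sliding_window <- function(site_values, w = 15, s = 2) {
  if (inherits(site_values, "variability_profile")) {
    p <- site_values
    wv <- sliding_window(p$site_values, w = w, s = s)
    p$window_length <- as.integer(w); p$step <- as.integer(s)
    p$window_values <- as.numeric(wv)
    p$window_starts <- attr(wv, "starts")
    return(p)
  }
  x <- as.numeric(site_values)
  L <- length(x)
  if (L < w) stop("profile length (", L, ") shorter than window (", w, ")")
  nwin <- floor((L - w) / s) + 1L
  starts <- (seq_len(nwin) - 1L) * s
  vals <- vapply(starts, function(st) mean(x[(st + 1L):(st + w)]), numeric(1))
  attr(vals, "starts") <- as.integer(starts)
  vals
}

#' Call conserved (low-variability) domains from a windowed profile
#'
#' Flags windows whose conservation exceeds the window mean plus `k` window
#' standard deviations (the 2-SD band drawn on variability plots,
#' operationalized on the smoothed profile), requires at least `min_run`
#' consecutive flagged windows to suppress single-window noise, and merges
#' overlapping or adjacent flagged windows into site-coordinate intervals.
#'
#' @param profile A `variability_profile` with windows filled in (see
#'   [sliding_window()]), or a plain numeric vector of window values (then
#'   `w`/`s` must be supplied).
#' @param k SD multiplier. Default 2.
#' @param min_run Minimum number of consecutive flagged windows. Default 2.
#' @param w,s Window geometry when `profile` is a bare vector.
#' @return A data.frame with 0-based half-open site intervals (`start`,
#'   `end`), disjoint and sorted; empty when the window SD is zero.
#' @export
call_conserved_domains <- function(profile, k = 2, min_run = 2, w = NULL, s = NULL) {
  if (inherits(profile, "variability_profile")) {
    if (is.null(profile$window_values))
      stop("profile has no windows; run sliding_window() first")
    wv <- profile$window_values; w <- profile$window_length; s <- profile$step
    starts <- profile$window_starts
  } else {
    wv <- as.numeric(profile)
    if (is.null(w) || is.null(s)) stop("w and s required for bare window values")
    starts <- (seq_along(wv) - 1L) * s
  }
  if (length(wv) < 3L) stop("need >= 3 windows")
  mu <- mean(wv); sdev <- sqrt(mean((wv - mu)^2))
  empty <- data.frame(start = integer(), end = integer())
  if (sdev == 0) return(empty)
  flagged <- wv > mu + k * sdev
  if (!any(flagged)) return(empty)
  r <- rle(flagged)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0L) return(empty)
  iv <- data.frame(start = starts[run_start[keep]],
                   end = starts[run_end[keep]] + w)
  merge_intervals(iv)
}

# Merge overlapping or adjacent half-open intervals; idempotent, output
# disjoint and sorted.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out_s <- iv$start[1L]; out_e <- iv$end[1L]
  res <- list()
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv$start[i] <= out_e) out_e <- max(out_e, iv$end[i])
    else { res[[length(res) + 1L]] <- c(out_s, out_e); out_s <- iv$start[i]; out_e <- iv$end[i] }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  df <- as.data.frame(do.call(rbind, res))
  names(df) <- c("start", "end")
  rownames(df) <- NULL
  df
}
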