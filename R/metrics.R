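#' Compare two force signals sampled on the same depth grid
#'
#' Computes the root-mean-squared error, the maximum absolute error
#' ("MAE" in this package always denotes the maximum, not the mean, of
#' the absolute force differences) and the percentage of exactly
#' identical emitted forces. Signals must share their depth grid; no
#' resampling is applied silently.
#'
#' @param ref,test `force_signal` tibbles (or any data frames with
#'   `depth_mm` and `force_N`) with matching sample counts and depths.
#' @param tol Tolerance in N under which two forces count as identical
#'   (default: bit-level float noise only).
#' @return A one-row tibble with columns `rmse`, `mae`, `pct_identical`,
#'   `n_samples`.
#' @examples
#' a <- tibble::tibble(depth_mm = c(0, 1), force_N = c(0.7, 0.7))
#' b <- tibble::tibble(depth_mm = c(0, 1), force_N = c(0, 0.7))
#' compare_signals(a, b)  # rmse 0.7/sqrt(2), mae 0.7, 50% identical
#' @export
compare_signals <- function(ref, test, tol = 1e-9) {
  if (nrow(ref) != nrow(test)) {
    abort("signals have different sample counts; no resampling is applied")
  }
  if (nrow(ref) > 0 && max(abs(ref$depth_mm - test$depth_mm)) > 1e-9) {
    abort("signals are sampled on different depth grids; no resampling is applied")
  }
  diff <- ref$force_N - test$force_N
  tibble::tibble(
    rmse = sqrt(mean(diff^2)),
    mae = max(abs(diff)),
    pct_identical = 100 * mean(abs(diff) <= tol),
    n_samples = nrow(ref)
  )
}

#' Structure border crossings along a path
#'
#' For each structure hit by the needle, the depths at which the needle
#' enters it, in order. Re-entrant structures (e.g. two fascial layers)
#' yield one entry depth per crossing.
#'
#' @param x A `force_signal` (its `code` column is used), or a
#'   [trajectory()] together with `labels`.
#' @param labels A label [volume3d()] (when `x` is a trajectory).
#' @return A tibble with columns `code` and `depth_mm`, one row per entry
#'   crossing, in depth order.
#' @export
border_crossings <- function(x, labels = NULL) {
  if (inherits(x, "force_signal")) {
    codes <- x$code
    depths <- x$depth_mm
  } else if (inherits(x, "trajectory")) {
    if (is.null(labels)) abort("`labels` is required with a trajectory")
    s <- sample_labels_along(x, labels)
    codes <- s$label
    depths <- s$depth_mm
  } else {
    abort("`x` must be a force_signal or a trajectory")
  }
  if (length(codes) == 0L) {
    return(tibble::tibble(code = integer(), depth_mm = numeric()))
  }
  entry <- c(TRUE, codes[-1] != codes[-length(codes)])
  tibble::tibble(code = codes[entry], depth_mm = depths[entry])
}

#' Border-lag distances between two segmentations along a path
#'
#' Matches the i-th crossing of each structure in the reference with the
#' i-th crossing of the same structure in the test sequence and measures
#' the depth differences: `msd` is their mean absolute value (mean
#' surface distance) and `hsd` their maximum (Hausdorff distance), per
#' structure and pooled over the path. Crossings present under only one
#' segmentation cannot be paired; they are excluded from the distances
#' and reported as `n_unmatched`.
#'
#' @param ref_crossings,test_crossings Crossing tibbles from
#'   [border_crossings()].
#' @return A list with `per_structure` (tibble: `code`, `msd_mm`,
#'   `hsd_mm`, `n_matched`, `n_unmatched`) and `pooled` (one-row tibble:
#'   `msd_mm`, `hsd_mm`, `n_matched`, `n_unmatched`).
#' @export
msd_hsd <- function(ref_crossings, test_crossings) {
  codes <- union(ref_crossings$code, test_crossings$code)
  per <- purrr::map_dfr(codes, function(cd) {
    r <- ref_crossings$depth_mm[ref_crossings$code == cd]
    t <- test_crossings$depth_mm[test_crossings$code == cd]
    n <- min(length(r), length(t))
    d <- if (n > 0) abs(r[seq_len(n)] - t[seq_len(n)]) else numeric()
    tibble::tibble(
      code = cd,
      msd_mm = if (n > 0) mean(d) else NA_real_,
      hsd_mm = if (n > 0) max(d) else NA_real_,
      n_matched = n,
      n_unmatched = length(r) + length(t) - 2L * n
    )
  })
  matched <- per[per$n_matched > 0, ]
  all_d <- unlist(purrr::map2(
    matched$code, matched$n_matched,
    function(cd, n) {
      r <- ref_crossings$depth_mm[ref_crossings$code == cd]
      t <- test_crossings$depth_mm[test_crossings$code == cd]
      abs(r[seq_len(n)] - t[seq_len(n)])
    }
  ))
  pooled <- tibble::tibble(
    msd_mm = if (length(all_d)) mean(all_d) else NA_real_,
    hsd_mm = if (length(all_d)) max(all_d) else NA_real_,
    n_matched = sum(per$n_matched),
    n_unmatched = sum(per$n_unmatched)
  )
  list(per_structure = per, pooled = pooled)
}

#' Weber fraction and just-noticeable-difference threshold
#'
#' The Weber fraction expresses the smallest perceivable change of a
#' stimulus relative to its reference magnitude:
#' `JND% = 100 * ((S + dS) - S) / S`. `weber_jnd()` computes the
#' fraction from a stimulus change; `jnd_threshold()` is its exact
#' inverse and converts a published fraction back to an absolute
#' threshold `dS = S * fraction / 100`.
#'
#' @param S Reference stimulus magnitude (N or mm), > 0.
#' @param delta Stimulus change (same units as `S`).
#' @return `weber_jnd()`: the fraction in percent; `jnd_threshold()`:
#'   the absolute threshold in the units of `S`.
#' @examples
#' jnd_threshold(0.8, 18.1)  # hand-arm force JND at the 0.8 N counter force
#' weber_jnd(28, 3)          # 3 mm lag on a 28 mm reference distance
#' @export
weber_jnd <- function(S, delta) {
  if (any(S <= 0)) abort("reference stimulus `S` must be positive")
  100 * ((S + delta) - S) / S
}

#' @rdname weber_jnd
#' @param fraction Weber fraction in percent.
#' @export
jnd_threshold <- function(S, fraction) {
  if (any(S <= 0)) abort("reference stimulus `S` must be positive")
  S * fraction / 100
}

#' Top-outlier accounting
#'
#' Flags values exceeding `mean + factor * sd` (one-sided, above the
#' mean; `sd` is the sample standard deviation with `n - 1` denominator)
#' and reports their percentage.
#'
#' @param values Numeric vector (length >= 2).
#' @param factor Multiplier on the standard deviation.
#' @return A one-row tibble with `mean`, `sd`, `outlier_pct` and a
#'   list-column `outliers` of the flagged indices.
#' @export
outlier_stats <- function(values, factor = 2.7) {
  if (length(values) < 2L) abort("need at least 2 values")
  m <- mean(values)
  s <- sd(values)
  flagged <- which(values > m + factor * s)
  tibble::tibble(mean = m, sd = s,
                 outlier_pct = 100 * length(flagged) / length(values),
                 outliers = list(flagged))
}
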