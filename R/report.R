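#' Evaluate force rendering of two patient models over planned paths
#'
#' Renders the reference and test models along every path, compares the
#' two force signals ([compare_signals()]) and measures the border lag of
#' every structure hit ([border_crossings()], [msd_hsd()]). Top MAE
#' outliers are flagged across the cohort at `mean + outlier_factor * sd`.
#'
#' @param paths A `puncture_plan` from [plan_all()], or a list of
#'   [trajectory()] objects.
#' @param ref_model Reference [patient_model()] (e.g. the gold-standard
#'   full segmentation).
#' @param test_model Test [patient_model()] (e.g. transfer function plus
#'   partial segmentation).
#' @param cfg An [engine_config()].
#' @param tol Identical-force tolerance in N (defaults to
#'   `cfg$identical_tol`).
#' @param outlier_factor Sigma multiplier for MAE outlier flagging.
#' @return A tibble of class `path_error_report`: one row per path with
#'   `rmse`, `mae`, `pct_identical`, pooled `msd_mm`/`hsd_mm`,
#'   `n_unmatched` and `outlier`. The per-structure border-lag table is
#'   attached as attribute `per_structure` and returned by [tidy()].
#' @export
evaluate_paths <- function(paths, ref_model, test_model,
                           cfg = engine_config(), tol = NULL,
                           outlier_factor = 2.7) {
  tol <- tol %||% cfg$identical_tol
  trajs <- if (inherits(paths, "puncture_plan")) {
    plan_trajectories(paths, cfg$n_samples)
  } else {
    paths
  }
  if (length(trajs) == 0L) abort("no paths to evaluate")
  rows <- vector("list", length(trajs))
  per_structure <- vector("list", length(trajs))
  for (i in seq_along(trajs)) {
    ref_sig <- render_insertion(trajs[[i]], ref_model, cfg)
    test_sig <- render_insertion(trajs[[i]], test_model, cfg)
    cmp <- compare_signals(ref_sig, test_sig, tol)
    lag <- msd_hsd(border_crossings(ref_sig), border_crossings(test_sig))
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(path_id = i), cmp,
      lag$pooled[, c("msd_mm", "hsd_mm", "n_unmatched")]
    )
    per_structure[[i]] <- dplyr::mutate(lag$per_structure, path_id = i,
                                        .before = 1)
  }
  report <- dplyr::bind_rows(rows)
  os <- outlier_stats(report$mae, outlier_factor)
  report$outlier <- seq_len(nrow(report)) %in% os$outliers[[1]]
  structure(report,
            class = c("path_error_report", class(report)),
            per_structure = dplyr::bind_rows(per_structure),
            outlier_factor = outlier_factor,
            tol = tol)
}

#' @export
tidy.path_error_report <- function(x, ...) {
  ps <- attr(x, "per_structure")
  tbl <- default_tissue_table()
  ps$tissue <- tbl$tissue[match(ps$code, tbl$code)]
  tibble::as_tibble(ps)
}

#' @export
glance.path_error_report <- function(x, ...) {
  summarize_report(x)
}

#' Cohort summary of a path error report
#'
#' Mean and standard deviation of the per-path RMSE and maximum absolute
#' error, the pooled percent-identical forces (sample-weighted, so paths
#' with more samples count proportionally) and the MAE top-outlier
#' percentage.
#'
#' @param report A `path_error_report` from [evaluate_paths()].
#' @return A one-row tibble.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "path_error_report"))
  n <- nrow(report)
  pooled_pct <- sum(report$pct_identical * report$n_samples) /
    sum(report$n_samples)
  tibble::tibble(
    n_paths = n,
    rmse_mean = mean(report$rmse),
    rmse_sd = if (n > 1) sd(report$rmse) else NA_real_,
    mae_mean = mean(report$mae),
    mae_sd = if (n > 1) sd(report$mae) else NA_real_,
    pct_identical_pooled = pooled_pct,
    outlier_pct = 100 * mean(report$outlier),
    msd_mean_mm = mean(report$msd_mm, na.rm = TRUE),
    hsd_max_mm = if (all(is.na(report$hsd_mm))) NA_real_ else
      max(report$hsd_mm, na.rm = TRUE)
  )
}

#' Write a path error report (per-path CSV plus JSON summary)
#'
#' @param report A `path_error_report`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(report), file.path(dir, "paths.csv"))
  readr::write_csv(tidy(report), file.path(dir, "per_structure.csv"))
  jsonlite::write_json(as.list(summarize_report(report)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
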