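#' Experiment run configuration
#'
#' A fully serialisable description of one evaluation run: the phantom,
#' planner, engine and evaluation settings plus the seed. A run
#' re-executed from its saved configuration reproduces all outputs
#' bit-exactly.
#'
#' @param seed Seed governing every source of randomness in the run.
#' @param phantom Named list of [phantom_spec()] overrides.
#' @param planner Named list of [planner_config()] overrides.
#' @param engine Named list of [engine_config()] overrides.
#' @param max_paths Optional cap on the number of evaluated paths (the
#'   first `max_paths` of the deterministic plan ordering); `NULL`
#'   evaluates all accepted paths.
#' @param outlier_factor Sigma multiplier for MAE outlier accounting.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, phantom = list(), planner = list(),
                       engine = list(), max_paths = NULL,
                       outlier_factor = 2.7) {
  structure(list(seed = as.integer(seed), phantom = phantom,
                 planner = planner, engine = engine,
                 max_paths = max_paths, outlier_factor = outlier_factor),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(seed = raw$seed %||% 1L,
             phantom = raw$phantom %||% list(),
             planner = raw$planner %||% list(),
             engine = raw$engine %||% list(),
             max_paths = raw$max_paths,
             outlier_factor = raw$outlier_factor %||% 2.7)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(cfg)), path)
  invisible(path)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

resolve_run <- function(cfg) {
  ph_spec <- do.call(phantom_spec,
                     modifyList(list(seed = cfg$seed), cfg$phantom))
  list(
    phantom_spec = ph_spec,
    planner = do.call(planner_config, cfg$planner),
    engine = do.call(engine_config, cfg$engine)
  )
}

#' Run the full phantom evaluation pipeline
#'
#' Executes the three-step study design end to end on a synthetic
#' phantom: (1) plan target-hitting reference paths on the gold-standard
#' segmentation, (2) render the force signal along every path under both
#' the gold-standard (reference) and partially segmented (test) models,
#' (3) compare the signals and analyse border lags. Writes the phantom
#' volumes, the accepted plan, the per-path report and a cohort summary;
#' every output carries the configuration hash and seed.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (`NULL` = no files written).
#' @param quiet Suppress per-stage progress messages?
#' @return A list with `phantom`, `models`, `plan`, `report`, `summary`,
#'   `config_hash`.
#' @export
run_experiment <- function(cfg = run_config(), out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  res <- resolve_run(cfg)
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(force(code), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
    if (!quiet) {
      message(sprintf("[%s] done in %.1f s", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    out
  }
  ph <- stage("phantom", layered_phantom(res$phantom_spec))
  models <- phantom_models(ph)
  plan <- stage("plan", plan_all(models$ref, res$planner,
                                 n_samples = res$engine$n_samples))
  if (nrow(plan) == 0L) abort("stage 'plan' failed: no accepted paths")
  eval_plan <- plan
  if (!is.null(cfg$max_paths) && nrow(plan) > cfg$max_paths) {
    eval_plan <- dplyr::slice(plan, seq_len(cfg$max_paths))
    attr(eval_plan, "n_samples") <- attr(plan, "n_samples")
    attr(eval_plan, "cfg") <- attr(plan, "cfg")
    class(eval_plan) <- class(plan)
  }
  report <- stage("evaluate", evaluate_paths(
    eval_plan, models$ref, models$test, res$engine,
    outlier_factor = cfg$outlier_factor
  ))
  summary <- summarize_report(report)
  out <- list(phantom = ph, models = models, plan = plan, report = report,
              summary = summary, config_hash = hash)
  if (!is.null(out_dir)) {
    stage("write", write_run_outputs(out, cfg, out_dir))
  }
  out
}

write_run_outputs <- function(out, cfg, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_phantom(out$phantom, out_dir)
  stamp <- sprintf("# punctforce config_hash=%s seed=%d", out$config_hash,
                   cfg$seed)
  write_stamped_csv <- function(df, path) {
    cat(stamp, "\n", readr::format_csv(tibble::as_tibble(df)), sep = "",
        file = path)
    invisible(path)
  }
  write_stamped_csv(out$plan, file.path(out_dir, "paths.csv"))
  write_stamped_csv(out$report, file.path(out_dir, "report.csv"))
  write_stamped_csv(tidy(out$report), file.path(out_dir, "per_structure.csv"))
  jsonlite::write_json(
    c(list(config_hash = out$config_hash, seed = cfg$seed),
      as.list(out$summary)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
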