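#' @title End-to-end experiment runner
#'
#' @description Sweeps long-axis strategies and interaction levels over a
#' dataset (a phantom suite or a directory of NIfTI image/label pairs),
#' segments every lesion of every case with the simulated rater, scores the
#' per-patient union against ground truth, and emits per-case results plus
#' mean / sd / range summary tables by strategy, by interaction level and by
#' processing stage.
#' @name runner
NULL

#' Experiment configuration
#'
#' @param n_phantoms Number of phantoms to generate when no `dataset` is
#'   given.
#' @param base_spec Baseline [phantom_spec()] for generated suites.
#' @param difficulty_grid Per-case overrides (see [make_suite()]).
#' @param dataset Optional directory containing a `manifest.json` written by
#'   [make_suite()]; takes precedence over generation.
#' @param strategies Subset of `true_longest`, `medial`, `statistical`,
#'   `swept`.
#' @param levels Subset of [interaction_levels()].
#' @param engine_name Registered engine name.
#' @param engine_cfg [engine_config()].
#' @param params [axis_score_params()].
#' @param policy [drop_policy()].
#' @param thresholds [category_thresholds()].
#' @param seed Experiment seed (drives phantom generation).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(n_phantoms = 20L, base_spec = phantom_spec(),
                       difficulty_grid = NULL, dataset = NULL,
                       strategies = "true_longest",
                       levels = "LONG_AXIAL",
                       engine_name = "parzen_rg",
                       engine_cfg = engine_config(),
                       params = axis_score_params(),
                       policy = drop_policy(),
                       thresholds = category_thresholds(),
                       seed = 1L, out_dir = NULL) {
  strategies <- match.arg(strategies,
                          c("true_longest", "medial", "statistical", "swept"),
                          several.ok = TRUE)
  levels <- match.arg(levels, interaction_levels(), several.ok = TRUE)
  structure(list(n_phantoms = n_phantoms, base_spec = base_spec,
                 difficulty_grid = difficulty_grid, dataset = dataset,
                 strategies = strategies, levels = levels,
                 engine_name = engine_name, engine_cfg = engine_cfg,
                 params = params, policy = policy, thresholds = thresholds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields of [run_config()], [phantom_spec()] (under `base_spec`),
#' [engine_config()] (under `engine`), [axis_score_params()] (under
#' `axis_score`) and [drop_policy()] (under `drops`) can all be set.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config(
    n_phantoms = y$n_phantoms %||% 20L,
    base_spec = do.call(phantom_spec, y$base_spec %||% list()),
    dataset = y$dataset,
    strategies = y$strategies %||% "true_longest",
    levels = y$levels %||% "LONG_AXIAL",
    engine_name = y$engine %||% "parzen_rg",
    engine_cfg = do.call(engine_config, y$engine_config %||% list()),
    params = do.call(axis_score_params, y$axis_score %||% list()),
    policy = do.call(drop_policy, y$drops %||% list()),
    thresholds = do.call(category_thresholds, y$thresholds %||% list()),
    seed = y$seed %||% 1L,
    out_dir = y$out_dir)
  if (!is.null(y$difficulty_grid))
    cfg$difficulty_grid <- as.data.frame(y$difficulty_grid)
  cfg
}

experiment_cases <- function(config) {
  if (!is.null(config$dataset)) {
    mf <- jsonlite::read_json(file.path(config$dataset, "manifest.json"),
                              simplifyVector = FALSE)
    lapply(mf, function(cs) {
      cs$image <- file.path(config$dataset, basename(cs$image))
      cs$labels <- file.path(config$dataset, basename(cs$labels))
      if (!is.null(cs$separator))
        cs$separator <- file.path(config$dataset, basename(cs$separator))
      cs
    })
  } else {
    make_suite(config$n_phantoms, config$base_spec, config$difficulty_grid,
               seed = config$seed)$cases
  }
}

#' Run the full simulated-interaction experiment
#'
#' For every case x strategy x level: enumerate lesions (after applying any
#' separator mask), run [simulate_patient()], and score the union mask
#' against the whole-case ground truth. Per-case failures are recorded and
#' the run continues.
#'
#' @param config A [run_config()].
#' @return A `seg_experiment`: `results` (one row per case x strategy x
#'   level with `dsc` and stage Dice means), `by_level`, `by_strategy`,
#'   `stage_table` summaries, `failures`, `config`.
#' @export
run_experiment <- function(config = run_config()) {
  cases <- experiment_cases(config)
  engine <- make_engine(config$engine_name, config$engine_cfg)
  simcfg <- sim_config(config$params, config$policy)
  rows <- list(); failures <- list()
  for (cs in cases) {
    dat <- load_case(cs)
    gt <- dat$labels > 0L
    enum_mask <- if (!is.null(dat$separator))
      apply_separators(gt, dat$separator) else gt
    lesions <- enumerate_lesions(enum_mask)
    if (length(lesions) == 0L) {
      failures <- c(failures, list(list(case = cs$case_id,
                                        error = "no lesions found")))
      next
    }
    for (strategy in config$strategies) {
      for (level in config$levels) {
        res <- tryCatch(
          simulate_patient(dat$volume, lesions, level, strategy, engine,
                           simcfg, seed = config$seed),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures, list(list(case = cs$case_id,
                                            strategy = strategy, level = level,
                                            error = conditionMessage(res))))
          next
        }
        sd_ <- colMeans(res$stage_dsc, na.rm = TRUE)
        rows <- c(rows, list(data.frame(
          patient_id = cs$case_id, strategy = strategy, level = level,
          lesion_count = length(lesions),
          dsc = dsc(res$mask, gt),
          dsc_2d = sd_[["d2"]], dsc_scout = sd_[["scout"]],
          dsc_3d = sd_[["d3"]],
          n_failures = length(res$failures))))
      }
    }
  }
  if (length(rows) == 0L) stop("experiment produced no results", call. = FALSE)
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  out <- structure(list(results = results,
                        by_level = summarize_results(results, "level"),
                        by_strategy = summarize_results(results, "strategy"),
                        stage_table = stage_summary(results),
                        failures = failures, config = config),
                   class = "seg_experiment")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(by_level = out$by_level, by_strategy = out$by_strategy,
           stage_table = out$stage_table),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

## Mean Dice per processing stage (2D, 3-plane scout, 3D), per strategy x level.
stage_summary <- function(results) {
  key <- interaction(results$strategy, results$level, drop = TRUE, sep = " / ")
  rows <- lapply(levels(key), function(k) {
    sub <- results[key == k, ]
    data.frame(condition = k,
               stage_2d = mean(sub$dsc_2d), stage_scout = mean(sub$dsc_scout),
               stage_3d = mean(sub$dsc_3d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.seg_experiment <- function(x, ...) {
  cat(sprintf("<seg_experiment> %d cases x {%s} x {%s}\n",
              length(unique(x$results$patient_id)),
              paste(x$config$strategies, collapse = ", "),
              paste(x$config$levels, collapse = ", ")))
  report(x)
  invisible(x)
}

#' Render the report tables
#'
#' Human-readable mean / standard deviation / range tables by interaction
#' level and by long-axis strategy, plus the per-stage progression table
#' (2D, 3-plane scout, 3D).
#'
#' @param x A `seg_experiment` or a results directory containing
#'   `results.csv`.
#' @return The results data frame, invisibly.
#' @export
report <- function(x) {
  if (is.character(x)) {
    f <- file.path(x, "results.csv")
    if (!file.exists(f)) stop("no results.csv in ", x, call. = FALSE)
    results <- utils::read.csv(f)
    x <- list(results = results,
              by_level = summarize_results(results, "level"),
              by_strategy = summarize_results(results, "strategy"),
              stage_table = stage_summary(results))
  }
  fmt_block <- function(df, label) {
    cat(sprintf("\n== 3D Dice by %s ==\n", label))
    for (i in seq_len(nrow(df))) {
      cat(sprintf("%-24s mean %.3f  sd %.3f  range [%.3f-%.3f]  (n=%d)\n",
                  df[i, 1], df$mean[i], df$sd[i], df$min[i], df$max[i],
                  df$n[i]))
    }
  }
  fmt_block(x$by_level, "interaction level")
  fmt_block(x$by_strategy, "long-axis strategy")
  cat("\n== Progression through processing stages (mean Dice) ==\n")
  st <- x$stage_table
  for (i in seq_len(nrow(st)))
    cat(sprintf("%-36s 2D %.3f | scout %.3f | 3D %.3f\n", st$condition[i],
                st$stage_2d[i], st$stage_scout[i], st$stage_3d[i]))
  invisible(x$results)
}
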