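#' Pipeline configuration
#'
#' One configuration object drives the whole run: simulate, preprocess,
#' featurize, evolve, evaluate. Stage seeds are derived deterministically
#' from the master seed and the stage name, so any stage can be re-run in
#' isolation and two runs with the same config produce identical outputs.
#'
#' @param config A named list, or the path of a YAML file, with (all
#'   optional) sections:
#'   \describe{
#'     \item{`generator`}{arguments for [generator_config()], including
#'       `preset`.}
#'     \item{`preprocessing`}{`low_hz`, `high_hz`, `order`, `zero_phase` for
#'       [filter_spec()] plus `gap_s` for [to_intensity()].}
#'     \item{`features`}{arguments for [feature_config()].}
#'     \item{`ga`}{arguments for [ga_config()].}
#'     \item{`tasks`}{character vector of [build_task()] names; default all
#'       six.}
#'     \item{`out_dir`}{output directory.}
#'     \item{`seed`}{master seed (default 1).}
#'     \item{`n_permutations`}{permutation-test shuffles per task
#'       (default 0 = skip).}
#'     \item{`write_wavs`}{materialise recordings as WAV files?
#'       (default TRUE).}
#'   }
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML file path")
  defaults <- list(generator = list(), preprocessing = list(),
                   features = list(), ga = list(),
                   tasks = c("injury_vs_normal", "normal_ptx_htx",
                             "ptx_vs_normal", "ptx_volume_ladder",
                             "htx_vs_normal", "htx_vs_ptx"),
                   out_dir = tempfile("pleurasound_run_"),
                   seed = 1L, n_permutations = 0L, write_wavs = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown pipeline config sections:",
                    paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates the study, writes the WAV recordings and manifest, extracts
#' the feature matrix, evolves a detector per requested task and writes a
#' genome JSON, history CSV and evaluation report JSON for each. All
#' randomness descends from the master seed, so two runs with the same
#' config are byte-identical in every output.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @return Named list of [evaluation_report()] objects (one per task),
#'   invisibly; artifacts land under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  gen_args <- modifyList(config$generator,
                         list(seed = hash_seed(config$seed, "simulate")))
  gcfg <- do.call(generator_config, gen_args)
  t0 <- proc.time()[3]
  study <- generate_study(gcfg)
  message(sprintf("[simulate] %d recordings / %d data sources (seed %d, %.1fs)",
                  length(study$recordings), nrow(study$manifest), gcfg$seed,
                  proc.time()[3] - t0))
  if (isTRUE(config$write_wavs)) write_study(study, file.path(out, "recordings"))

  pp <- config$preprocessing
  spec <- filter_spec(low_hz = pp$low_hz %||% 60,
                      high_hz = pp$high_hz %||%
                        min(2000, 0.45 * gcfg$sample_rate_hz),
                      order = pp$order %||% 4,
                      zero_phase = pp$zero_phase %||% TRUE)
  fcfg <- do.call(feature_config, config$features)
  t0 <- proc.time()[3]
  fd <- featurize_study(study, spec, fcfg, gap_s = pp$gap_s %||% 5e-5)
  write_features(fd, file.path(out, "features.csv"))
  message(sprintf("[featurize] %d x %d feature matrix (%.1fs)",
                  nrow(fd$features), ncol(fd$features), proc.time()[3] - t0))

  reports <- list()
  for (task_name in config$tasks) {
    task <- build_task(task_name)
    retained <- sum(!is.na(apply_task(task, fd$labels)))
    ga <- do.call(ga_config, modifyList(
      config$ga, list(seed = hash_seed(config$seed, "evolve", task_name))))
    t0 <- proc.time()[3]
    res <- evolve(fd, task, ga)
    write_genome(res$best_genome,
                 file.path(out, sprintf("genome_%s.json", task_name)))
    write.csv(res$history,
              file.path(out, sprintf("history_%s.csv", task_name)),
              row.names = FALSE)
    cv <- loocv(fd, res$best_genome, task)
    correlation <- NULL
    if (!is.null(cv$volumes) && sd(cv$volumes$real) > 0 &&
        sd(cv$volumes$predicted) > 0)
      correlation <- volume_correlation(cv$volumes$real, cv$volumes$predicted)
    permutation <- NULL
    if (config$n_permutations > 0)
      permutation <- monte_carlo_permutation(
        fd, task, res$best_genome, n_permutations = config$n_permutations,
        seed = hash_seed(config$seed, "perm", task_name))
    report <- evaluation_report(
      task, cv, correlation = correlation, permutation = permutation,
      genome = res$best_genome, seed = config$seed,
      config = list(generator_seed = gcfg$seed, ga_seed = ga$seed,
                    retained = retained))
    write_report(report, file.path(out, sprintf("report_%s.json", task_name)))
    message(sprintf(
      "[%s] retained %d/%d; sens %.1f%% spec %.1f%% acc %.1f%% (%.1fs)",
      task_name, retained, nrow(fd$features), report$sensitivity,
      report$specificity, report$accuracy, proc.time()[3] - t0))
    reports[[task_name]] <- report
  }
  invisible(reports)
}
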