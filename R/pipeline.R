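#' Run the full decoding pipeline
#'
#' Orchestrates data generation (or loading) -> per-trial connectivity
#' adjacency -> min-max standardization -> stratified k-fold
#' cross-validation, and writes a machine-readable metrics artifact. One
#' seed governs every stochastic choice downstream (synthetic data and fold
#' assignment), so a rerun with the same config is bit-identical.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{synth}{named list of [synth_config()] arguments, or `NULL` when
#'       `epochs_file` is given.}
#'     \item{epochs_file}{path to an epoch-set container saved by
#'       [save_container()] (used when `synth` is absent).}
#'     \item{method}{`"mi"`, `"cc"` or `"coh"` (default `"mi"`).}
#'     \item{modality}{`"fusion"`, `"eeg"` or `"emg"` (default `"fusion"`).}
#'     \item{folds}{CV folds (default 10).}
#'     \item{seed}{integer seed (default 7).}
#'     \item{out_dir}{output directory; when `NULL` nothing is written.}
#'   }
#' @return The metrics list, invisibly a side effect of writing
#'   `metrics.json` and `run.log` into `out_dir` when set. Fields: schema
#'   version, config echo, per-fold accuracies, mean/sd accuracy, confusion
#'   matrix, per-class accuracy, chance level.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  method <- tolower(config$method %||% "mi")
  modality <- tolower(config$modality %||% "fusion")
  folds <- as.integer(config$folds %||% 10L)
  seed <- as.integer(config$seed %||% 7L)

  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  if (!is.null(config$synth)) {
    args <- config$synth
    args$seed <- args$seed %||% seed
    cfg <- do.call(synth_config, args)
    say("[synth] generating ", 3L * cfg$n_trials, " trials (seed ",
        cfg$seed, ")")
    epochs <- generate_epochs(cfg)
  } else if (!is.null(config$epochs_file)) {
    say("[load] reading epochs from ", config$epochs_file)
    epochs <- load_container(config$epochs_file)
    if (!inherits(epochs, "epoch_set"))
      stop("[load] ", config$epochs_file, " does not hold an epoch_set")
  } else stop("config needs either `synth` or `epochs_file`")

  say("[connect] method=", method, " modality=", modality)
  ccfg <- connectivity_config(method)
  conn <- connectivity_matrices(epochs, ccfg, modality)

  say("[decode] ", folds, "-fold stratified CV (seed ", seed, ")")
  cv <- cross_validate(conn$matrices, conn$labels, k = folds, seed = seed)
  say("[decode] mean accuracy ", sprintf("%.2f", cv$mean_accuracy),
      "% (chance ", sprintf("%.3f", cv$chance_level), "%)")

  metrics <- list(
    schema = "neurofuse-metrics-1",
    version = as.character(utils::packageVersion("neurofuse")),
    config = list(method = method, modality = modality, folds = folds,
                  seed = seed,
                  n_trials = length(conn$labels),
                  window = epochs$window),
    fold_accuracy = cv$fold_accuracy,
    mean_accuracy = cv$mean_accuracy,
    sd_accuracy = cv$sd_accuracy,
    per_class_accuracy = as.list(cv$per_class_accuracy),
    confusion = list(classes = rownames(cv$confusion),
                     counts = unname(apply(cv$confusion, 1L, as.integer,
                                           simplify = FALSE))),
    chance_level = cv$chance_level)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics,
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    say("[report] wrote ", file.path(config$out_dir, "metrics.json"))
  }
  invisible(metrics)
}

#' Tabulate several pipeline runs
#'
#' Reads metrics files written by [run_pipeline()] and aligns them into one
#' summary table of mean +/- sd accuracies with their config columns.
#'
#' @param paths character vector of `metrics.json` paths (>= 1).
#' @return A data.frame with columns `method`, `modality`, `folds`, `seed`,
#'   `n_trials`, `mean_accuracy`, `sd_accuracy`, `chance_level`.
#' @export
compare_runs <- function(paths) {
  if (!length(paths)) stop("no metrics files given")
  rows <- lapply(paths, function(p) {
    m <- jsonlite::read_json(p, simplifyVector = TRUE)
    if (is.null(m$schema) || !startsWith(m$schema, "neurofuse-metrics"))
      stop("incompatible metrics schema in ", p)
    data.frame(method = m$config$method, modality = m$config$modality,
               folds = m$config$folds, seed = m$config$seed,
               n_trials = m$config$n_trials,
               mean_accuracy = m$mean_accuracy,
               sd_accuracy = m$sd_accuracy,
               chance_level = m$chance_level)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
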