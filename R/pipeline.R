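# YAML run configuration and the end-to-end pipeline:
# simulate -> iterative training -> scan held-out chromosomes ->
# evaluate -> report.

RUN_CONFIG_SECTIONS <- c("simulate", "model", "train", "scan", "split",
                         "seed", "out_dir", "n_iterations")

#' Build a run configuration
#'
#' Every value has a default; unknown keys are rejected so typos cannot
#' silently fall back to defaults. The single global `seed` derives the
#' per-stage seeds by fixed offsets, so one knob reproduces a whole run.
#'
#' @param config named list (typically from [read_run_config()]) with any
#'   of the sections `simulate`, `model`, `train`, `scan`, `split`, and
#'   scalars `seed`, `out_dir`, `n_iterations`.
#' @return list of class `run_config` with all defaults filled in.
#' @export
run_config <- function(config = list()) {
  unknown <- setdiff(names(config), RUN_CONFIG_SECTIONS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  seed <- config$seed %||% 1L
  sim_defaults <- list(n_chroms = 2L, chrom_len = 100000L,
                       n_promoters = 20L, n_enhancers = 6L,
                       grammar = list())
  sim <- utils::modifyList(sim_defaults, config$simulate %||% list())
  unknown <- setdiff(names(sim), names(sim_defaults))
  if (length(unknown)) {
    stop("unknown simulate key(s): ", paste(unknown, collapse = ", "))
  }
  model <- do.call(model_config,
                   utils::modifyList(config$model %||% list(),
                                     list(seed = derive_seed(seed, 2L))))
  train <- do.call(train_config,
                   utils::modifyList(config$train %||% list(),
                                     list(seed = derive_seed(seed, 3L))))
  scan <- do.call(scan_config, config$scan %||% list())
  if (scan$window_len != model$window_len) {
    stop("scan window_len must match model window_len")
  }
  split_cfg <- config$split %||% list()
  structure(list(simulate = sim, model = model, train = train,
                 scan = scan, split = split_cfg, seed = seed,
                 out_dir = config$out_dir %||% tempfile("run_"),
                 n_iterations = config$n_iterations %||% 3L),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  run_config(yaml::read_yaml(path))
}

#' Run the end-to-end pipeline
#'
#' Simulates a genome with planted regulatory grammar, runs the iterative
#' hard-negative training loop with the first chromosome held out, scans
#' the held-out chromosome and writes predictions, the final negative
#' set, and a JSON report with one held-out evaluation per iteration.
#' Fully reproducible from (config, seed).
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return the output directory path, invisibly; the report is at
#'   `report.json` inside it.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  sim <- stage("simulate", {
    spec <- do.call(grammar_spec, config$simulate$grammar)
    generate_genome(spec, n_chroms = config$simulate$n_chroms,
                    chrom_len = config$simulate$chrom_len,
                    n_promoters = config$simulate$n_promoters,
                    n_enhancers = config$simulate$n_enhancers,
                    seed = derive_seed(config$seed, 1L))
  })
  write_fasta(sim$genome, file.path(config$out_dir, "genome.fa"))
  write_bed(sim$truth, file.path(config$out_dir, "truth.bed"))
  test_chroms <- config$split$test_chroms %||% names(sim$genome$chroms)[1]
  split <- split_spec(test_chroms,
                      train_fraction = config$split$train_fraction %||% 0.9,
                      seed = derive_seed(config$seed, 4L))
  run <- stage("train", {
    run_iterative_training(sim$genome, sim$truth,
                           n_iterations = config$n_iterations,
                           split = split, mconfig = config$model,
                           tconfig = config$train, sconfig = config$scan,
                           verbose = verbose)
  })
  stage("write-outputs", {
    preds <- run$reports[[length(run$reports)]]$heldout_predictions
    write_predictions_bed(preds, file.path(config$out_dir, "predictions.bed"))
    write_negatives_bed(run$negset, file.path(config$out_dir, "negatives.bed"))
    for (role in c("scan", "prediction", "strand")) {
      save_scorer(run$models[[role]],
                  file.path(config$out_dir, paste0(role, "_model.rds")))
    }
    report <- list(
      seed = config$seed,
      n_iterations = config$n_iterations,
      test_chroms = test_chroms,
      iterations = lapply(run$reports, function(r) {
        list(iteration = r$iteration,
             negatives_pool = r$negatives_pool,
             negatives_added = r$mining$negatives_added,
             eval = if (!is.null(r$eval)) unclass(r$eval) else NULL)
      }))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  })
  invisible(config$out_dir)
}
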