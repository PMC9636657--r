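# End-to-end orchestration: simulate -> summarize -> train (MLP + RBF) ->
# evaluate -> sensitivity -> optimize, with a manifest so a run is replayable
# from its configuration alone. Stage seeds are derived from one global seed
# by fixed offsets, so stages are individually rerunnable yet jointly
# reproducible.

#' Serialize a surrogate model to JSON
#'
#' Writes weights, centers, scalers and configuration of a `callus_mlp` or
#' `callus_rbf` model to a documented JSON file; [load_model()] restores it.
#'
#' @param model Trained surrogate.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  kind <- if (inherits(model, "callus_mlp")) "mlp" else if
    (inherits(model, "callus_rbf")) "rbf" else stop("not a surrogate model")
  obj <- unclass(model)
  obj$kind <- kind
  obj$cfg <- unclass(obj$cfg)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a surrogate model saved by [save_model()]
#'
#' @param path Path to the JSON file.
#' @return A `callus_mlp` or `callus_rbf` model.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind
  obj$kind <- NULL
  restore_mat <- function(m) if (is.list(m)) do.call(rbind, m) else as.matrix(m)
  if (kind == "mlp") {
    obj$w1 <- restore_mat(obj$w1)
    obj$w2 <- matrix(unlist(obj$w2), ncol = 1)
    obj$cfg <- structure(obj$cfg, class = "callus_mlp_config")
    structure(obj, class = "callus_mlp")
  } else {
    obj$centers <- restore_mat(obj$centers)
    obj$cfg <- structure(obj$cfg, class = "callus_rbf_config")
    structure(obj, class = "callus_rbf")
  }
}

#' Pipeline run configuration
#'
#' @param seed Global seed; stage seeds are derived from it by fixed offsets
#'   (generator `+0`, split `+1`, MLP `+2`, RBF `+3`, GA `+4`).
#' @param out_dir Output directory for artifacts (created if missing).
#' @param generator [generator_config()] overrides as a named list (the seed
#'   is always derived from the global seed).
#' @param mlp,rbf,ga Configuration objects for the model and optimizer
#'   stages; seeds are overridden by the derived stage seeds.
#' @param train_fraction Train fraction of the condition-summary split.
#' @param speed_mode Speed scale used for summaries fed to the speed
#'   surrogate: `"inverted"` (diameter/day desirability, default, maximized
#'   by the GA) or `"as_written"` (day/diameter).
#' @return A `callus_run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("callusopt_run_"),
                       generator = list(), mlp = mlp_config(),
                       rbf = rbf_config(), ga = ga_config(),
                       train_fraction = 0.9,
                       speed_mode = c("inverted", "as_written")) {
  speed_mode <- match.arg(speed_mode)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, generator = generator,
         mlp = mlp, rbf = rbf, ga = ga, train_fraction = train_fraction,
         speed_mode = speed_mode),
    class = "callus_run_config"
  )
}

#' Run the full surrogate-assisted optimization pipeline
#'
#' Simulates a factorial experiment, summarizes it per condition, fits MLP
#' and RBF surrogates for both outputs on a 90/10 split, reports train/test
#' RMSE and R-squared for each, runs the leave-one-variable-out sensitivity
#' ranking, and optimizes the MLP surrogates with the discrete GA in
#' percentage-only, speed-only and multi-objective modes. All artifacts (raw
#' CSV, summary CSV, model JSON files, metric/sensitivity/optimization
#' tables, manifest with MD5 hashes) are written under `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `callus_run` list with all stage results and artifact paths.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  if (!inherits(cfg, "callus_run_config")) stop("cfg must come from run_config()")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[callusopt] ", ...)
  t0 <- proc.time()[["elapsed"]]
  stage_time <- c()
  tick <- function(name) {
    stage_time[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }

  say("simulating factorial experiment")
  gen_args <- cfg$generator
  gen_args$seed <- cfg$seed
  gen <- do.call(generator_config, gen_args)
  records <- simulate_experiment(gen)
  raw_path <- file.path(cfg$out_dir, "replicates.csv")
  write_replicates(records, raw_path)
  tick("simulate")

  say("summarizing conditions")
  sum_pct <- condition_summaries(records, speed_mode = cfg$speed_mode)
  sum_path <- file.path(cfg$out_dir, "condition_summaries.csv")
  utils::write.csv(sum_pct, sum_path, row.names = FALSE, quote = FALSE)
  split <- split_train_test(sum_pct, cfg$train_fraction, seed = cfg$seed + 1L)
  tick("summarize")

  say("training surrogates")
  models <- list()
  metrics <- list()
  for (fam in c("mlp", "rbf")) {
    for (target in c("percentage", "speed")) {
      mcfg <- cfg[[fam]]
      mcfg$seed <- cfg$seed + if (fam == "mlp") 2L else 3L
      m <- if (fam == "mlp") {
        train_mlp(split$train, target, mcfg)
      } else {
        fit_rbf(split$train, target, mcfg)
      }
      models[[paste(fam, target, sep = "_")]] <- m
      path <- file.path(cfg$out_dir, paste0("model_", fam, "_", target, ".json"))
      save_model(m, path)
      rep <- metric_report(m, split$train, split$test)
      rep$model <- fam
      rep$target <- target
      metrics[[paste(fam, target, sep = "_")]] <- rep
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(cfg$out_dir, "model_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  tick("train")

  say("sensitivity analysis")
  sens_cfg <- cfg$mlp
  sens_cfg$seed <- cfg$seed + 2L
  sens <- sensitivity_analysis(sum_pct, target = "percentage",
                               model_family = "mlp", cfg = sens_cfg)
  utils::write.csv(sens, file.path(cfg$out_dir, "sensitivity.csv"),
                   row.names = FALSE, quote = FALSE)
  tick("sensitivity")

  say("genetic-algorithm optimization")
  ga_cfg <- cfg$ga
  opt <- list()
  for (obj in c("percentage", "speed", "both")) {
    ga_cfg$objectives <- obj
    ga_cfg$seed <- cfg$seed + 4L
    opt[[obj]] <- ga_optimize(models$mlp_percentage, models$mlp_speed, ga_cfg)
  }
  opt_summary <- lapply(opt, function(r) {
    list(selected = r$selected, front = r$front,
         selection_rule = r$selection_rule)
  })
  jsonlite::write_json(opt_summary, file.path(cfg$out_dir, "optimization.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  tick("optimize")

  artifacts <- list.files(cfg$out_dir, full.names = TRUE)
  artifacts <- artifacts[!grepl("manifest[.]json$", artifacts)]
  manifest <- list(
    seed = cfg$seed,
    stage_seeds = list(generator = cfg$seed, split = cfg$seed + 1L,
                       mlp = cfg$seed + 2L, rbf = cfg$seed + 3L,
                       ga = cfg$seed + 4L),
    train_fraction = cfg$train_fraction, speed_mode = cfg$speed_mode,
    stage_seconds = as.list(stage_time),
    artifacts = as.list(tools::md5sum(artifacts))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)

  structure(
    list(records = records, summaries = sum_pct, split = split,
         models = models, metrics = metrics, sensitivity = sens,
         optimization = opt, manifest = manifest, out_dir = cfg$out_dir),
    class = "callus_run"
  )
}
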