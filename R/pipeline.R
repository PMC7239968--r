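## End-to-end orchestration: simulate/read -> diagnose -> fit grid ->
## select -> isolate, with a reproducible report bundle.

#' Configure a pipeline run
#'
#' @param input A [simulation_config()] to simulate from, or a path to a
#'   sample CSV (see [read_samples()]).
#' @param overdispersion_filter Exclude experiments whose pooled counts
#'   fail the deviance/d.f. > 1 overdispersion check (default `TRUE`,
#'   mirroring the exclusion of the non-overdispersed experiment from
#'   model training in the study design).
#' @param split_fraction Training fraction of the train/validation split.
#' @param families,kernels Model grid to fit.
#' @param pi_mode Link orientation, see [zi_model_spec()].
#' @param thresholds CP thresholds in percent; each must exceed the
#'   structural plateau `100 * 0.5 / 384 = 0.1302`%.
#' @param n_boot Bootstrap replicates for the conservative isolation
#'   distance (0 skips the bootstrap).
#' @param n_starts Start points per model fit.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param out_dir Output directory for the report bundle (`NULL`: no
#'   files written).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = simulation_config(),
                            overdispersion_filter = TRUE,
                            split_fraction = 0.7,
                            families = c("ZIP", "ZINB"),
                            kernels = list_kernels()$name,
                            pi_mode = "reconciled",
                            thresholds = c(3, 1, 0.9),
                            n_boot = 500,
                            n_starts = 20,
                            seed = 1L,
                            out_dir = NULL) {
  plateau <- 100 * 0.5 / 384
  if (any(thresholds <= plateau))
    stop(sprintf(paste("threshold(s) %s are at or below the structural",
                       "plateau %.4f%% and have no finite isolation",
                       "distance"),
                 paste(thresholds[thresholds <= plateau], collapse = ", "),
                 plateau), call. = FALSE)
  kernels <- vapply(kernels, match_kernel, character(1), USE.NAMES = FALSE)
  structure(list(input = input,
                 overdispersion_filter = isTRUE(overdispersion_filter),
                 split_fraction = split_fraction,
                 families = families, kernels = kernels,
                 pi_mode = pi_mode, thresholds = thresholds,
                 n_boot = n_boot, n_starts = n_starts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic per-stage seeds derived from the master seed
.stage_seed <- function(master, stage) {
  offsets <- c(simulate = 11L, split = 23L, fit = 37L, boot = 53L)
  (master * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Observed-vs-predicted CP table by distance
#'
#' One row per sampling distance: the validation-set mean observed CP
#' rate and each final model's predicted CP rate.  Distances with no
#' validation samples carry `NA` in the observed column (missing, not
#' zero).
#'
#' @param fits A named list of converged `zi_fit` objects.
#' @param valid Validation samples.
#' @param distances Distances to tabulate (default the design grid).
#' @return A data.frame: `distance_m`, `observed_cp`, one predicted
#'   column per fit.
#' @export
make_table4 <- function(fits, valid, distances = design_distances()) {
  if (inherits(fits, "zi_fit")) fits <- list(fits)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f)
      paste0(f$spec$family, "-", f$spec$kernel), character(1))
  obs <- vapply(distances, function(d) {
    sel <- valid$distance_m == d
    if (any(sel)) mean(valid$cp_percent[sel]) else NA_real_
  }, numeric(1))
  out <- data.frame(distance_m = distances, observed_cp = obs)
  for (nm in names(fits))
    out[[paste0("predicted_cp_", nm)]] <- predicted_cp(fits[[nm]], distances)
  out
}

#' Run the full gene-flow analysis pipeline
#'
#' Stages: (1) simulate or read the sample table; (2) per-experiment
#' diagnostics, excluding experiments that fail the overdispersion check
#' when the filter is on; (3) seeded stratified train/validation split;
#' (4) fit the family-by-kernel grid; (5) rank models and pick candidates
#' and a final model; (6) observed-vs-predicted CP table; (7) isolation
#' distances at the configured thresholds (bootstrap conservative
#' estimate when `n_boot > 0`).  With `out_dir` set, writes
#' `samples.csv`, `diagnostics.json`, `metrics.csv`, `table4.csv`,
#' `isolation.csv`, `config.yaml`, `report.md` (all deterministic given
#' the master seed) and `run.log` (timings).
#'
#' @param config A [pipeline_config()].
#' @return A list with the per-stage results: `samples`, `diagnostics`,
#'   `excluded`, `split`, `grid`, `ranking`, `table4`, `isolation`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  stamp <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  t0 <- proc.time()[["elapsed"]]

  # stage 1: data
  samples <- if (inherits(config$input, "simulation_config")) {
    sim <- config$input
    sim$seed <- .stage_seed(config$seed, "simulate")
    simulate_dataset(sim)
  } else {
    read_samples(config$input)
  }
  stamp("data", sprintf("%d samples, %d experiments", nrow(samples),
                        length(unique(samples$experiment_id))))

  # stage 2: diagnostics + exclusion filter
  diagnostics <- diagnose_experiments(samples)
  per_exp <- diagnostics[diagnostics$experiment_id != "(pooled)", ]
  excluded <- if (config$overdispersion_filter)
    per_exp$experiment_id[!per_exp$overdispersed] else character(0)
  included <- samples[!(samples$experiment_id %in% excluded), , drop = FALSE]
  stamp("diagnose", sprintf("excluded: %s",
                            if (length(excluded)) paste(excluded, collapse = ", ")
                            else "(none)"))

  # stage 3: split
  split <- train_valid_split(included, fraction = config$split_fraction,
                             seed = .stage_seed(config$seed, "split"))
  stamp("split", sprintf("train %d / valid %d", nrow(split$train),
                         nrow(split$valid)))

  # stage 4: model grid
  grid <- fit_model_grid(split$train, split$valid,
                         families = config$families,
                         kernels = config$kernels,
                         pi_mode = config$pi_mode,
                         n_starts = config$n_starts,
                         seed = .stage_seed(config$seed, "fit"))
  stamp("fit", sprintf("%d models, %d converged", nrow(grid$metrics),
                       sum(grid$metrics$converged)))

  # stage 5: ranking
  ranking <- rank_models(grid$metrics)
  final_label <- ranking$final$model
  final_fit <- grid$fits[[final_label]]
  stamp("select", sprintf("final: %s", final_label))

  # stage 6: observed vs predicted by distance (final + runner-up candidate)
  cand_labels <- ranking$candidates$model
  shown <- unique(c(final_label, cand_labels))[
    seq_len(min(2, length(cand_labels)))]
  table4 <- make_table4(grid$fits[shown], split$valid,
                        distances = sort(unique(samples$distance_m)))

  # stage 7: isolation distances
  iso_rows <- lapply(config$thresholds, function(th) {
    point <- solve_isolation_distance(final_fit, th)
    cons <- NA_real_
    if (config$n_boot > 0) {
      b <- bootstrap_isolation(included, final_fit$spec, th,
                               n_boot = config$n_boot,
                               seed = .stage_seed(config$seed, "boot"),
                               n_starts = config$n_starts)
      cons <- b$conservative_distance
    }
    data.frame(threshold = th, model = final_label,
               point_distance_m = point, conservative_distance_m = cons,
               n_boot = config$n_boot, seed = config$seed)
  })
  isolation <- do.call(rbind, iso_rows)
  stamp("isolate", sprintf("%d thresholds", length(config$thresholds)))
  stamp("done", sprintf("elapsed %.1f s", proc.time()[["elapsed"]] - t0))

  result <- list(samples = samples, diagnostics = diagnostics,
                 excluded = excluded, split = split, grid = grid,
                 ranking = ranking, table4 = table4, isolation = isolation,
                 log = log_lines)

  if (!is.null(config$out_dir)) .write_bundle(result, config)
  result
}

.write_bundle <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  if (inherits(config$input, "simulation_config")) {
    write_simulated_dataset(result$samples, config$input, path("samples.csv"))
  } else {
    write_samples(result$samples, path("samples.csv"))
  }
  jsonlite::write_json(result$diagnostics, path("diagnostics.json"),
                       dataframe = "rows", digits = NA)
  write.csv(result$grid$metrics, path("metrics.csv"), row.names = FALSE)
  write.csv(result$table4, path("table4.csv"), row.names = FALSE)
  write.csv(result$isolation, path("isolation.csv"), row.names = FALSE)
  cfg <- config
  cfg$input <- if (inherits(cfg$input, "simulation_config"))
    cfg$input[setdiff(names(cfg$input),
                      c("mean_profile", "zero_inflation_profile",
                        "model_spec"))]
  else cfg$input
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "out_dir")],
                   path("config.yaml"))
  report <- c(
    "# Gene-flow pipeline report", "",
    sprintf("- samples: %d (%d experiments)", nrow(result$samples),
            length(unique(result$samples$experiment_id))),
    sprintf("- excluded experiments (no overdispersion): %s",
            if (length(result$excluded))
              paste(result$excluded, collapse = ", ") else "(none)"),
    sprintf("- models fitted: %d (%d converged)", nrow(result$grid$metrics),
            sum(result$grid$metrics$converged)),
    sprintf("- candidate models: %s",
            paste(result$ranking$candidates$model, collapse = ", ")),
    sprintf("- final model: %s", result$ranking$final$model), "",
    "## Isolation distances", "",
    sprintf("- %.2f%% threshold: %.3f m", result$isolation$threshold,
            result$isolation$point_distance_m))
  writeLines(report, path("report.md"))
  writeLines(result$log, path("run.log"))
  invisible(config$out_dir)
}
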