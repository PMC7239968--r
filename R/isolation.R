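## Isolation-distance recommendations: invert the fitted CP-rate curve at
## a regulatory threshold, with a bootstrap conservative estimate.

#' Structural plateau of a fitted model's CP curve
#'
#' Under the reconciled link the predicted CP rate cannot fall below
#' `100 * 0.5 / n_seeds` (0.1302% for 384-seed assays): as the kernel
#' vanishes, `mu -> 1` and `pi -> 0.5`.  Thresholds at or below the
#' plateau have no finite isolation distance.
#'
#' @param fit A `zi_fit`.
#' @return The plateau CP rate in percent.
#' @export
cp_plateau <- function(fit) 100 * 0.5 / fit$n_seeds

#' Solve the isolation distance at a CP threshold
#'
#' The smallest distance beyond which the model-predicted CP rate stays
#' at or below the threshold: the last downward crossing of the predicted
#' curve, located on a log-spaced scan of `[1e-3, upper]` m and refined
#' by bisection to 1e-3 m.  (For monotone kernels this is simply the
#' first crossing; for unimodal kernels such as a fitted Weibull with
#' shape > 1 -- whose CP curve rises from the plateau before decaying --
#' the last crossing is the distance that actually guarantees
#' compliance.)
#'
#' @param fit A converged [fit_zi_model()] result.
#' @param threshold CP threshold in percent; must exceed the structural
#'   plateau (see [cp_plateau()]).
#' @param upper Upper search bound in metres (default 50; the result is
#'   insensitive to this for thresholds above the plateau).
#' @return Distance in metres; 0 when the predicted CP rate never exceeds
#'   the threshold (no isolation needed).
#' @export
solve_isolation_distance <- function(fit, threshold, upper = 50) {
  if (!isTRUE(fit$converged))
    stop("cannot solve isolation distance from an unconverged fit",
         call. = FALSE)
  plateau <- cp_plateau(fit)
  if (threshold <= plateau)
    stop(sprintf(paste("threshold %.4g%% is at or below the structural",
                       "plateau %.4f%%; no finite isolation distance"),
                 threshold, plateau), call. = FALSE)
  lower <- 1e-3
  grid <- exp(seq(log(lower), log(upper), length.out = 1024))
  cp <- predicted_cp(fit, grid)
  above <- which(cp > threshold)
  if (length(above) == 0) return(0)        # always compliant
  i <- above[length(above)]                # last point above the threshold
  if (i == length(grid))
    stop(sprintf("predicted CP stays above %.4g%% out to %g m",
                 threshold, upper), call. = FALSE)
  lo <- grid[i]
  hi <- grid[i + 1L]
  while (hi - lo > 1e-3) {
    mid <- (hi + lo) / 2
    if (predicted_cp(fit, mid) <= threshold) hi <- mid else lo <- mid
  }
  (hi + lo) / 2
}

#' Bootstrap conservative isolation distance
#'
#' Resamples the data with replacement (stratified by sampling distance,
#' preserving the design's distance coverage in every replicate), refits
#' the model -- warm-started at the full-data estimates -- and solves the
#' isolation distance per replicate.  The conservative estimate is the
#' 95th-percentile order statistic of the replicate distances.
#'
#' @param samples The full sample table.
#' @param spec A [zi_model_spec()] naming family/kernel/link (parameters
#'   free).
#' @param threshold CP threshold in percent.
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param percentile Order-statistic level of the conservative estimate
#'   (default 0.95).
#' @param seed Integer seed; deterministic given the seed.
#' @param n_starts Start points for the full-data fit.
#' @return An object of class `isolation_result`: `threshold`, `model`,
#'   `point_distance`, `conservative_distance`, `n_boot`, `n_failed`,
#'   `percentile`, `replicate_distances`.
#' @export
bootstrap_isolation <- function(samples, spec, threshold, n_boot = 500,
                                percentile = 0.95, seed = 1, n_starts = 20) {
  samples <- validate_samples(samples)
  full_fit <- fit_zi_model(samples, family = spec$family,
                           kernel = spec$kernel, pi_mode = spec$pi_mode,
                           n_starts = n_starts, seed = seed)
  point <- solve_isolation_distance(full_fit, threshold)
  warm <- list(Q = full_fit$spec$Q, a = full_fit$spec$a,
               b = full_fit$spec$b, alpha = full_fit$spec$alpha)
  set.seed(seed + 1L)
  strata <- split(seq_len(nrow(samples)), samples$distance_m)
  reps <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    idx <- unlist(lapply(strata, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]),
      use.names = FALSE)
    boot <- samples[idx, , drop = FALSE]
    reps[i] <- tryCatch({
      fit <- fit_zi_model(boot, family = spec$family, kernel = spec$kernel,
                          pi_mode = spec$pi_mode, start = warm)
      solve_isolation_distance(fit, threshold)
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.2 * n_boot)
    stop(sprintf("unstable bootstrap: %d of %d replicates failed",
                 n_failed, n_boot), call. = FALSE)
  good <- reps[!is.na(reps)]
  conservative <- as.numeric(quantile(good, percentile, type = 1))
  structure(list(
    threshold = threshold,
    model = paste0(spec$family, "-", spec$kernel),
    point_distance = point,
    conservative_distance = conservative,
    n_boot = n_boot, n_failed = n_failed, percentile = percentile,
    replicate_distances = good,
    fit = full_fit
  ), class = "isolation_result")
}

#' @export
print.isolation_result <- function(x, ...) {
  cat(sprintf("Isolation distance at %.2f%% CP threshold (%s)\n",
              x$threshold, x$model))
  cat(sprintf("  point estimate: %.3f m\n", x$point_distance))
  cat(sprintf("  conservative (bootstrap %g%%ile, %d reps, %d failed): %.3f m\n",
              100 * x$percentile, x$n_boot, x$n_failed,
              x$conservative_distance))
  invisible(x)
}

#' Isolation-distance table over several thresholds
#'
#' @param fit A converged fit used for point estimates.
#' @param thresholds CP thresholds in percent (default the 3%, 1% and
#'   0.9% regulatory levels).
#' @return A data.frame: `threshold`, `model`, `point_distance_m`.
#' @export
isolation_table <- function(fit, thresholds = c(3, 1, 0.9)) {
  data.frame(
    threshold = thresholds,
    model = paste0(fit$spec$family, "-", fit$spec$kernel),
    point_distance_m = vapply(thresholds, function(t)
      solve_isolation_distance(fit, t), numeric(1)))
}
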