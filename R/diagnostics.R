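## Pre-model diagnostics: excess zeros, overdispersion, and wind effect.

#' Excess-zero check against the Poisson prediction
#'
#' Compares the observed fraction of zero counts with the zero probability
#' of a Poisson distribution at the sample mean, `exp(-lambda_hat)`.
#' More observed zeros than predicted indicates zero inflation.
#'
#' @param counts Non-negative integer counts.
#' @return A list: `observed_zero_fraction`, `expected_zero_fraction`,
#'   `lambda_hat`, and logical `excess`.
#' @export
zero_excess_check <- function(counts) {
  if (length(counts) == 0)
    stop("insufficient data: empty count vector", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lambda_hat <- mean(counts)
  observed <- mean(counts == 0)
  expected <- exp(-lambda_hat)
  list(observed_zero_fraction = observed,
       expected_zero_fraction = expected,
       lambda_hat = lambda_hat,
       excess = observed > expected)
}

#' Overdispersion check via the intercept-only Poisson deviance
#'
#' Computes the sample mean and variance and the deviance of an
#' intercept-only Poisson model (`lambda_hat` = mean):
#' `D = 2 sum(y log(y / lambda_hat) - (y - lambda_hat))` with
#' `0 log 0 = 0`.  Data with deviance / d.f. > 1 (d.f. = n - 1) are
#' flagged as overdispersed.
#'
#' @param counts Non-negative integer counts, length >= 2.
#' @return A list: `mean_count`, `var_count`, `deviance`, `dof`,
#'   `deviance_ratio`, logical `overdispersed`.
#' @export
overdispersion_check <- function(counts) {
  if (length(counts) < 2)
    stop("insufficient data: need at least 2 counts", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  m <- mean(counts)
  v <- var(counts)
  if (m == 0) {
    dev <- 0
  } else {
    term <- ifelse(counts == 0, 0, counts * log(counts / m))
    dev <- 2 * sum(term - (counts - m))
  }
  dof <- length(counts) - 1L
  ratio <- dev / dof
  list(mean_count = m, var_count = v, deviance = dev, dof = dof,
       deviance_ratio = ratio, overdispersed = ratio > 1)
}

#' Two-proportion z-test for the wind effect on CP events
#'
#' A CP event is a sampling point with at least one hybrid progeny.  The
#' upwind and downwind recipient plots are compared by the pooled
#' two-proportion z statistic on their event fractions.
#'
#' @param events_up,n_up Events and sampling points in the upwind plot.
#' @param events_down,n_down Same for the downwind plot.
#' @return A list: `z`, two-sided `p`, the two proportions, and logical
#'   `degenerate` (pooled proportion 0 or 1, where `z` is defined as 0).
#' @export
wind_event_ztest <- function(events_up, n_up, events_down, n_down) {
  stopifnot(n_up > 0, n_down > 0,
            events_up >= 0, events_up <= n_up,
            events_down >= 0, events_down <= n_down)
  p1 <- events_up / n_up
  p2 <- events_down / n_down
  pp <- (events_up + events_down) / (n_up + n_down)
  if (pp == 0 || pp == 1)
    return(list(z = 0, p = 1, prop_up = p1, prop_down = p2,
                degenerate = TRUE))
  se <- sqrt(pp * (1 - pp) * (1 / n_up + 1 / n_down))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)), prop_up = p1, prop_down = p2,
       degenerate = FALSE)
}

#' One-way ANOVA of CP rate on plot side
#'
#' Tests whether the recipient-plot side (upwind/downwind or east/west)
#' explains variation in the CP rate.
#'
#' @param samples A validated sample table with >= 2 plot sides, each with
#'   >= 2 samples.
#' @return A list: `F`, `p`, and the degrees of freedom.
#' @export
wind_anova <- function(samples) {
  samples <- validate_samples(samples)
  tab <- table(samples$plot_side)
  if (length(tab) < 2 || any(tab < 2))
    stop("insufficient groups: need >= 2 plot sides with >= 2 samples each",
         call. = FALSE)
  fit <- aov(cp_percent ~ plot_side, data = samples)
  a <- anova(fit)
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       df_between = a$Df[1], df_within = a$Df[2])
}

#' Diagnostics report for one or more experiments
#'
#' Runs the excess-zero and overdispersion checks per experiment and
#' pooled; the pooled row carries `experiment_id = "(pooled)"`.
#'
#' @param samples A validated sample table.
#' @return A data.frame with one row per experiment plus the pooled row:
#'   zero fractions, `lambda_hat`, mean/variance, deviance ratio, and the
#'   `excess_zeros` / `overdispersed` flags.
#' @export
diagnose_experiments <- function(samples) {
  samples <- validate_samples(samples)
  groups <- split(samples, samples$experiment_id)
  groups[["(pooled)"]] <- samples
  rows <- lapply(names(groups), function(id) {
    y <- model_counts(groups[[id]])
    ze <- zero_excess_check(y)
    od <- overdispersion_check(y)
    data.frame(experiment_id = id, n = length(y),
               observed_zero_fraction = ze$observed_zero_fraction,
               expected_zero_fraction = ze$expected_zero_fraction,
               lambda_hat = ze$lambda_hat,
               excess_zeros = ze$excess,
               mean_count = od$mean_count, var_count = od$var_count,
               deviance = od$deviance, dof = od$dof,
               deviance_ratio = od$deviance_ratio,
               overdispersed = od$overdispersed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
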