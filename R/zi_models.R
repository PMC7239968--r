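## Zero-inflated Poisson / negative-binomial likelihoods with a
## dispersal-kernel mean structure, and their maximum-likelihood fitting.
##
## The mean model is log mu(d) = Q * r(d; a, b) with r a registered
## dispersal kernel, so mu = exp(Q r(d)) decays from exp(Q) toward 1 as
## the kernel vanishes.  The zero-inflation probability shares the same
## predictor through a logit link; see `pi_mode` below for the two
## orientations of that link.

# linear predictor clipped to +/- 50 to keep exp() finite
.eta_clip <- 50

#' Specify a zero-inflated dispersal model
#'
#' @param family `"ZIP"` (zero-inflated Poisson) or `"ZINB"`
#'   (zero-inflated negative binomial).
#' @param kernel Dispersal kernel name (see [list_kernels()]).
#' @param pi_mode Orientation of the shared logit link for the
#'   zero-inflation probability.  `"reconciled"` (default) sets
#'   `pi = 1/(1 + mu)`, so zero inflation fades where the mean is large and
#'   the far-distance expected CP plateaus at `100 * 0.5/384 = 0.1302`%.
#'   `"literal"` sets `pi = mu/(1 + mu)`, which caps the marginal mean
#'   below one count; it is retained for comparison (see the vignette).
#' @param Q Kernel coefficient (free if `NA`).
#' @param a,b Kernel scale/shape parameters (free if `NA`).
#' @param alpha ZINB dispersion parameter (> 0; larger is more
#'   overdispersed; the variance is `mu (1 + alpha mu)`).
#' @return An object of class `zi_model_spec`.
#' @export
zi_model_spec <- function(family = c("ZINB", "ZIP"), kernel,
                          pi_mode = c("reconciled", "literal"),
                          Q = NA_real_, a = NA_real_, b = NA_real_,
                          alpha = NA_real_) {
  family <- match.arg(family)
  pi_mode <- match.arg(pi_mode)
  kernel <- match_kernel(kernel)
  if (family == "ZIP" && !is.na(alpha))
    stop("alpha is a ZINB parameter; not allowed for ZIP", call. = FALSE)
  structure(list(family = family, kernel = kernel, pi_mode = pi_mode,
                 Q = Q, a = a, b = b, alpha = alpha),
            class = "zi_model_spec")
}

#' Kernel-driven mean structure of a zero-inflated model
#'
#' Evaluates `mu(d) = exp(Q r(d))` and the zero-inflation probability
#' `pi(d)` implied by the spec's link orientation.
#'
#' @param spec A [zi_model_spec()] with concrete parameter values.
#' @param d Distances in metres (> 0).
#' @return A list with numeric vectors `mu` (> 0) and `pi` (in (0, 1)).
#' @export
mean_structure <- function(spec, d) {
  r <- evaluate_kernel(spec$kernel, d, spec$a,
                       if (kernel_registry[[spec$kernel]]$n_params == 2L)
                         spec$b else NULL)
  eta <- pmin(pmax(spec$Q * r, -.eta_clip), .eta_clip)
  mu <- exp(eta)
  pi <- switch(spec$pi_mode,
               reconciled = 1 / (1 + mu),
               literal = mu / (1 + mu))
  # keep pi off the boundary: at eta = -50, 1/(1+mu) rounds to 1.0
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  list(mu = mu, pi = pi)
}

# log(a + b) from log a, log b, elementwise
.logspace_add <- function(la, lb) {
  m <- pmax(la, lb)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(la, lb) - m)))
}

#' Zero-inflated Poisson probability mass function
#'
#' `P(Y = 0) = pi + (1 - pi) exp(-mu)`;
#' `P(Y = y) = (1 - pi) mu^y exp(-mu) / y!` for `y > 0`.
#'
#' @param y Non-negative integer counts (vectorized).
#' @param mu Poisson mean (> 0).
#' @param pi Zero-inflation probability in `[0, 1)`.
#' @param log Return log probabilities?
#' @return Probabilities (or log probabilities), same length as `y`.
#' @export
zip_pmf <- function(y, mu, pi, log = FALSE) {
  stopifnot(all(y >= 0), all(mu > 0), all(pi >= 0), all(pi < 1))
  lpois <- y * base::log(mu) - mu - lgamma(y + 1)
  lp <- ifelse(y == 0,
               .logspace_add(base::log(pi), log1p(-pi) - mu),
               log1p(-pi) + lpois)
  if (log) lp else exp(lp)
}

# log NB pmf in the (mu, alpha) parameterization: size = 1/alpha
.lnb <- function(y, mu, alpha) {
  ia <- 1 / alpha
  # lgamma(y + ia) - lgamma(ia) cancels catastrophically for large ia;
  # use log[Gamma(y+ia)/Gamma(ia)] = sum_{k<y} log(ia + k) ~ y log(ia) +
  # y(y-1)/(2 ia) there (exact to O((y/ia)^2))
  lgr <- if (ia > 1e8)
    y * base::log(ia) + y * (y - 1) / (2 * ia)
  else
    lgamma(y + ia) - lgamma(ia)
  lgr - lgamma(y + 1) -
    ia * log1p(alpha * mu) +
    ifelse(y == 0, 0, y * (base::log(alpha * mu) - log1p(alpha * mu)))
}

#' Zero-inflated negative-binomial probability mass function
#'
#' The negative-binomial component `g(y)` uses the shape (dispersion)
#' parameterization with mean `mu` and variance `mu (1 + alpha mu)`:
#' `g(y) = Gamma(y + 1/alpha) / (Gamma(1/alpha) y!) *`
#' `(1/(1 + alpha mu))^(1/alpha) * (alpha mu / (1 + alpha mu))^y`, and
#' `P(Y = y) = pi 1(y = 0) + (1 - pi) g(y)`.  As `alpha -> 0` this
#' converges to [zip_pmf()].
#'
#' @inheritParams zip_pmf
#' @param alpha Dispersion (shape) parameter, > 0.
#' @return Probabilities (or log probabilities), same length as `y`.
#' @export
zinb_pmf <- function(y, mu, pi, alpha, log = FALSE) {
  stopifnot(all(y >= 0), all(mu > 0), all(pi >= 0), all(pi < 1),
            all(alpha > 0))
  lg <- .lnb(y, mu, alpha)
  lp <- ifelse(y == 0,
               .logspace_add(base::log(pi), log1p(-pi) + lg),
               log1p(-pi) + lg)
  if (log) lp else exp(lp)
}

# decode a flat optimizer vector into model parameters; kernel parameters
# and alpha live on the log scale for positivity
.decode_params <- function(params, family, kernel) {
  kp <- kernel_registry[[kernel]]$n_params
  need <- 1L + kp + (family == "ZINB")
  if (length(params) != need)
    stop(sprintf("expected %d parameters for %s-%s, got %d",
                 need, family, kernel, length(params)), call. = FALSE)
  out <- list(Q = params[1], a = exp(params[2]),
              b = if (kp == 2L) exp(params[3]) else NA_real_,
              alpha = if (family == "ZINB") exp(params[need]) else NA_real_)
  # keep the dispersion in a numerically safe range (flat beyond it)
  if (family == "ZINB") out$alpha <- min(max(out$alpha, 1e-10), 1e10)
  out
}

#' Negative log-likelihood of a zero-inflated dispersal model
#'
#' The objective minimised by [fit_zi_model()]: minus the sum of log
#' pmf values of the model-scale counts.  `params` is the flat optimizer
#' vector `(Q, log a[, log b][, log alpha])`.
#'
#' @param params Numeric vector as above.
#' @param family `"ZIP"` or `"ZINB"`.
#' @param kernel Kernel name.
#' @param samples A validated sample table (counts via [model_counts()]).
#' @param pi_mode Link orientation, see [zi_model_spec()].
#' @return A finite scalar, or `+Inf` for invalid parameter values.
#' @export
neg_loglik <- function(params, family, kernel, samples,
                       pi_mode = "reconciled") {
  kernel <- match_kernel(kernel)
  p <- try(.decode_params(params, family, kernel), silent = TRUE)
  if (inherits(p, "try-error") || any(!is.finite(unlist(params))))
    return(Inf)
  spec <- zi_model_spec(family, kernel, pi_mode, Q = p$Q, a = p$a, b = p$b,
                        alpha = if (family == "ZINB") p$alpha else NA_real_)
  y <- model_counts(samples)
  ms <- try(mean_structure(spec, samples$distance_m), silent = TRUE)
  if (inherits(ms, "try-error")) return(Inf)
  lp <- if (family == "ZIP")
    zip_pmf(y, ms$mu, ms$pi, log = TRUE)
  else
    zinb_pmf(y, ms$mu, ms$pi, p$alpha, log = TRUE)
  nll <- -sum(lp)
  if (!is.finite(nll)) Inf else nll
}

# seeded Latin-hypercube start points over the documented search box
.lhs_starts <- function(n_starts, family, kernel, seed) {
  kp <- kernel_registry[[kernel]]$n_params
  lo <- c(-5, -2, if (kp == 2L) -2, if (family == "ZINB") -3)
  hi <- c(5, 3, if (kp == 2L) 2, if (family == "ZINB") 3)
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, length(lo))
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

#' Fit a zero-inflated dispersal model by maximum likelihood
#'
#' Multi-start local optimization of [neg_loglik()]: `n_starts` seeded
#' Latin-hypercube start points (box `Q` in `[-5, 5]`, `log a` in
#' `[-2, 3]`, `log b` in `[-2, 2]`, `log alpha` in `[-3, 3]`), each run
#' through BFGS with a Nelder-Mead fallback, and the best point polished
#' by Nelder-Mead to a `1e-8` relative tolerance.  Deterministic given
#' `seed`.
#'
#' @param samples A validated sample table with at least 10 rows spanning
#'   at least 3 distinct distances.
#' @param family,kernel,pi_mode Model structure, see [zi_model_spec()].
#' @param n_starts Number of Latin-hypercube start points (default 20).
#' @param seed Integer seed for the start-point draw.
#' @param start Optional named list `(Q, a, b, alpha)` used as the single
#'   start point (warm start); `n_starts` is then ignored.
#' @return An object of class `zi_fit`: `spec` (with estimates), `loglik`,
#'   `n_obs`, `n_params`, `n_seeds` (assay scale of the data), `converged`,
#'   `start_points_tried`, `gradient_norm`.
#' @export
fit_zi_model <- function(samples, family = c("ZINB", "ZIP"), kernel,
                         pi_mode = c("reconciled", "literal"),
                         n_starts = 20, seed = 1, start = NULL) {
  family <- match.arg(family)
  pi_mode <- match.arg(pi_mode)
  kernel <- match_kernel(kernel)
  samples <- validate_samples(samples)
  if (nrow(samples) < 10 || length(unique(samples$distance_m)) < 3)
    stop("insufficient data: need >= 10 samples spanning >= 3 distances",
         call. = FALSE)
  kp <- kernel_registry[[kernel]]$n_params
  npar <- 1L + kp + (family == "ZINB")
  if (nrow(samples) <= npar)
    stop("fewer samples than parameters; fit is degenerate", call. = FALSE)

  obj <- function(th) neg_loglik(th, family, kernel, samples, pi_mode)

  starts <- if (is.null(start)) {
    .lhs_starts(n_starts, family, kernel, seed)
  } else {
    matrix(c(start$Q, log(start$a),
             if (kp == 2L) log(start$b),
             if (family == "ZINB") log(start$alpha)), nrow = 1)
  }

  best <- NULL
  tried <- 0L
  for (i in seq_len(nrow(starts))) {
    th0 <- starts[i, ]
    if (!is.finite(obj(th0))) next
    tried <- tried + 1L
    opt <- try(optim(th0, obj, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-8)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value))
      opt <- try(optim(th0, obj, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-8)),
                 silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    # a count likelihood is < 1, so its negative log is strictly positive;
    # a non-positive objective value can only be numerical breakdown
    if (opt$value <= 0) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("non-convergence: all ", nrow(starts), " start points failed for ",
         family, "-", kernel, call. = FALSE)

  polish <- try(optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10)),
                silent = TRUE)
  if (!inherits(polish, "try-error") && is.finite(polish$value) &&
      polish$value <= best$value) best <- polish

  # central-difference gradient norm at the optimum
  h <- 1e-5
  g <- vapply(seq_len(npar), function(j) {
    e <- rep(0, npar); e[j] <- h
    (obj(best$par + e) - obj(best$par - e)) / (2 * h)
  }, numeric(1))

  p <- .decode_params(best$par, family, kernel)
  spec <- zi_model_spec(family, kernel, pi_mode, Q = p$Q, a = p$a, b = p$b,
                        alpha = if (family == "ZINB") p$alpha else NA_real_)
  ns <- unique(samples$n_seeds)
  structure(list(
    spec = spec,
    loglik = -best$value,
    n_obs = nrow(samples),
    n_params = npar,
    n_seeds = if (length(ns) == 1) ns else 384L,
    converged = is.finite(best$value) && best$convergence == 0,
    start_points_tried = tried,
    gradient_norm = sqrt(sum(g^2))
  ), class = "zi_fit")
}

#' @export
print.zi_fit <- function(x, ...) {
  s <- x$spec
  cat(sprintf("%s-%s fit (%s link): loglik %.4f on %d samples\n",
              s$family, s$kernel, s$pi_mode, x$loglik, x$n_obs))
  cat(sprintf("  Q = %.4f, a = %.4f%s%s\n", s$Q, s$a,
              if (is.na(s$b)) "" else sprintf(", b = %.4f", s$b),
              if (is.na(s$alpha)) "" else sprintf(", alpha = %.4f", s$alpha)))
  cat(sprintf("  converged: %s (|grad| = %.2e, %d starts)\n",
              x$converged, x$gradient_norm, x$start_points_tried))
  invisible(x)
}

#' Model-predicted cross-pollination rate
#'
#' The expected count of the fitted zero-inflated model, expressed as a
#' percentage of the assay size: `100 (1 - pi(d)) mu(d) / n_seeds`.  Under
#' the reconciled link this decays to the structural plateau
#' `100 * 0.5 / n_seeds` (0.1302% for 384-seed assays) as the kernel
#' vanishes.
#'
#' @param fit A converged [fit_zi_model()] result.
#' @param d Distances in metres (> 0).
#' @return Predicted CP rates in percent.
#' @export
predicted_cp <- function(fit, d) {
  if (!inherits(fit, "zi_fit")) stop("fit must be a zi_fit", call. = FALSE)
  if (!isTRUE(fit$converged))
    stop("cannot predict from an unconverged fit", call. = FALSE)
  ms <- mean_structure(fit$spec, d)
  100 * (1 - ms$pi) * ms$mu / fit$n_seeds
}

#' Draw counts from a zero-inflated count law
#'
#' Exact draws from the ZIP/ZINB distributions used by the model-mode
#' simulator: with probability `pi` the count is a structural zero,
#' otherwise Poisson(`mu`) or NB(`mu`, `alpha`).
#'
#' @param n Number of draws.
#' @param mu Mean of the count component (scalar or length `n`).
#' @param pi Zero-inflation probability (scalar or length `n`).
#' @param family `"ZIP"` or `"ZINB"`.
#' @param alpha ZINB dispersion, required for `family = "ZINB"`.
#' @return Integer vector of counts.
#' @export
rzicount <- function(n, mu, pi, family = c("ZINB", "ZIP"), alpha = NULL) {
  family <- match.arg(family)
  base <- if (family == "ZIP") {
    rpois(n, lambda = mu)
  } else {
    if (is.null(alpha) || any(alpha <= 0))
      stop("ZINB draws need alpha > 0", call. = FALSE)
    rnbinom(n, size = 1 / alpha, mu = mu)
  }
  ifelse(runif(n) < pi, 0L, base)
}

#' Serialize a fit to JSON
#'
#' @param fit A `zi_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zi_fit <- function(fit, path) {
  jsonlite::write_json(list(
    family = fit$spec$family, kernel = fit$spec$kernel,
    pi_mode = fit$spec$pi_mode,
    estimates = list(Q = fit$spec$Q, a = fit$spec$a, b = fit$spec$b,
                     alpha = fit$spec$alpha),
    loglik = fit$loglik, n_obs = fit$n_obs, n_params = fit$n_params,
    converged = fit$converged, start_points_tried = fit$start_points_tried,
    gradient_norm = fit$gradient_norm
  ), path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
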