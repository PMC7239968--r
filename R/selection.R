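## Train/validation split, fit and prediction criteria, and ranking of the
## 2-family x 11-kernel model grid.

#' Stratified 70/30 train/validation split
#'
#' Randomly assigns samples to a training and a validation set,
#' stratified by sampling distance so both sets cover the full
#' 0.35-12.95 m range (an unstratified split can drop entire distance
#' classes at small n).  Deterministic given `seed`.
#'
#' @param samples A validated sample table (>= 10 rows).
#' @param fraction Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return A list with data.frames `train` and `valid`; disjoint and
#'   exhaustive.
#' @export
train_valid_split <- function(samples, fraction = 0.7, seed = 1) {
  samples <- validate_samples(samples)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  if (nrow(samples) < 10)
    stop("insufficient data: need >= 10 samples to split", call. = FALSE)
  set.seed(seed)
  idx <- seq_len(nrow(samples))
  strata <- split(idx, samples$distance_m)
  train_idx <- integer(0)
  for (s in strata) {
    n_tr <- round(fraction * length(s))
    train_idx <- c(train_idx, if (n_tr > 0) sample(s, n_tr) else integer(0))
  }
  # balance rounding drift toward the exact ceiling(fraction * n)
  target <- ceiling(fraction * nrow(samples))
  pool <- setdiff(idx, train_idx)
  if (length(train_idx) < target && length(pool) > 0)
    train_idx <- c(train_idx, sample(pool, target - length(train_idx)))
  if (length(train_idx) > target)
    train_idx <- sample(train_idx, target)
  train_idx <- sort(train_idx)
  list(train = samples[train_idx, , drop = FALSE],
       valid = samples[setdiff(idx, train_idx), , drop = FALSE])
}

#' Fit criteria of a zero-inflated model on its training data
#'
#' Residuals are on the proportion scale: observed CP proportion
#' (`cp_percent / 100`) minus predicted proportion
#' ([predicted_cp()] / 100).  `rmse = sqrt(SSE/n)`;
#' `adj_r2 = 1 - (SSE/(n-p-1)) / (SST/(n-1))`;
#' `aic = -2 loglik + 2p` and `bic = -2 loglik + p log n` use the
#' count-scale likelihood of the fit, with `p` the number of model
#' parameters.
#'
#' @param fit A converged [fit_zi_model()] result.
#' @param train The training samples the fit used.
#' @return A list: `model`, `rmse`, `adj_r2`, `aic`, `bic`, `n_train`,
#'   `n_params`.
#' @export
fit_metrics <- function(fit, train) {
  train <- validate_samples(train)
  n <- nrow(train)
  p <- fit$n_params
  if (n <= p + 1)
    stop("adjusted R-squared undefined: n <= p + 1", call. = FALSE)
  obs <- train$cp_percent / 100
  pred <- predicted_cp(fit, train$distance_m) / 100
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  list(model = paste0(fit$spec$family, "-", fit$spec$kernel),
       rmse = sqrt(sse / n),
       adj_r2 = 1 - (sse / (n - p - 1)) / (sst / (n - 1)),
       aic = -2 * fit$loglik + 2 * p,
       bic = -2 * fit$loglik + p * log(n),
       n_train = n, n_params = p)
}

#' Mean squared prediction error on held-out samples
#'
#' The mean over the validation set of the squared difference between the
#' observed and predicted CP proportions.  Evaluated on the training set
#' itself it equals `rmse^2`.
#'
#' @param fit A converged [fit_zi_model()] result.
#' @param valid Validation samples (non-empty).
#' @return A non-negative scalar.
#' @export
mspr <- function(fit, valid) {
  valid <- validate_samples(valid)
  if (nrow(valid) == 0)
    stop("empty validation set", call. = FALSE)
  obs <- valid$cp_percent / 100
  pred <- predicted_cp(fit, valid$distance_m) / 100
  mean((obs - pred)^2)
}

#' Rank fitted models and pick the final model
#'
#' Candidate models are the top three by adjusted R-squared (ties broken
#' by smaller AIC); the final pick is the candidate with the smallest
#' MSPR (ties broken by larger adjusted R-squared).  Ordering is stable,
#' so equal-metric models keep their input order.
#'
#' @param reports A data.frame with one row per model and columns
#'   `model`, `rmse`, `adj_r2`, `aic`, `bic`, `mspr` (rows with `NA`
#'   metrics -- unconverged fits -- are ranked last and never selected).
#' @return A list: `ordering` (full data.frame ordered by fit quality),
#'   `candidates` (top three), `final` (single-row data.frame).
#' @export
rank_models <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 2)
    stop("need at least 2 model reports to rank", call. = FALSE)
  ok <- !is.na(reports$adj_r2)
  key_r2 <- ifelse(ok, -reports$adj_r2, Inf)
  key_aic <- ifelse(is.na(reports$aic), Inf, reports$aic)
  ord <- order(key_r2, key_aic)
  ordering <- reports[ord, , drop = FALSE]
  candidates <- head(ordering[!is.na(ordering$adj_r2), , drop = FALSE], 3)
  key_mspr <- ifelse(is.na(candidates$mspr), Inf, candidates$mspr)
  pick <- order(key_mspr, -candidates$adj_r2)[1]
  list(ordering = ordering, candidates = candidates,
       final = candidates[pick, , drop = FALSE])
}

#' Fit the full family-by-kernel model grid
#'
#' Fits every requested family/kernel combination to the training set and
#' evaluates fit and prediction criteria.  Fits that fail or do not
#' converge appear as rows with `NA` metrics and `converged = FALSE`,
#' never as silent omissions.
#'
#' @param train,valid Training and validation sample tables.
#' @param families Subset of `c("ZIP", "ZINB")`.
#' @param kernels Kernel names (default: all 11).
#' @param pi_mode Link orientation, see [zi_model_spec()].
#' @param n_starts,seed Passed to [fit_zi_model()].
#' @return A list: `metrics` (data.frame, one row per model) and `fits`
#'   (named list of `zi_fit` objects, `NULL` where fitting failed).
#' @export
fit_model_grid <- function(train, valid, families = c("ZIP", "ZINB"),
                           kernels = list_kernels()$name,
                           pi_mode = "reconciled", n_starts = 20, seed = 1) {
  kernels <- vapply(kernels, match_kernel, character(1))
  grid <- expand.grid(family = families, kernel = kernels,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    label <- paste0(grid$family[i], "-", grid$kernel[i])
    fit <- tryCatch(
      fit_zi_model(train, family = grid$family[i], kernel = grid$kernel[i],
                   pi_mode = pi_mode, n_starts = n_starts, seed = seed),
      error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged)) {
      fm <- fit_metrics(fit, train)
      rows[[i]] <- data.frame(model = label, family = grid$family[i],
                              kernel = grid$kernel[i],
                              rmse = fm$rmse, adj_r2 = fm$adj_r2,
                              aic = fm$aic, bic = fm$bic,
                              mspr = mspr(fit, valid),
                              loglik = fit$loglik, converged = TRUE,
                              stringsAsFactors = FALSE)
      fits[[i]] <- fit
    } else {
      rows[[i]] <- data.frame(model = label, family = grid$family[i],
                              kernel = grid$kernel[i],
                              rmse = NA_real_, adj_r2 = NA_real_,
                              aic = NA_real_, bic = NA_real_,
                              mspr = NA_real_, loglik = NA_real_,
                              converged = FALSE, stringsAsFactors = FALSE)
    }
  }
  names(fits) <- paste0(grid$family, "-", grid$kernel)
  list(metrics = do.call(rbind, rows), fits = fits)
}
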