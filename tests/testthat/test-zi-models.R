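test_that("ZIP pmf matches its closed form and normalizes", {
  expect_equal(zip_pmf(0, 1, 0), exp(-1))
  expect_equal(round(zip_pmf(0, 1, 0), 5), 0.36788)
  expect_equal(zip_pmf(0, 1, 0.5), 0.5 + 0.5 * exp(-1))
  expect_equal(round(zip_pmf(0, 1, 0.5), 5), 0.68394)
  expect_equal(sum(zip_pmf(0:200, 3, 0.3)), 1, tolerance = 1e-10)
  # oracle: zero-inflated mixture of dpois
  set.seed(7)
  for (i in 1:20) {
    mu <- runif(1, 0.1, 15); pi <- runif(1, 0, 0.9); y <- rpois(1, 5)
    expect_equal(zip_pmf(y, mu, pi),
                 pi * (y == 0) + (1 - pi) * dpois(y, mu), tolerance = 1e-12)
  }
})

test_that("ZINB pmf matches its closed form, the NB oracle, and normalizes", {
  expect_equal(zinb_pmf(0, 1, 0, 1), 0.5)
  expect_equal(sum(zinb_pmf(0:2000, 3, 0.3, 2)), 1, tolerance = 1e-8)
  set.seed(8)
  for (i in 1:20) {
    mu <- runif(1, 0.1, 15); pi <- runif(1, 0, 0.9)
    alpha <- runif(1, 0.05, 3); y <- rpois(1, 5)
    expect_equal(zinb_pmf(y, mu, pi, alpha),
                 pi * (y == 0) + (1 - pi) * dnbinom(y, size = 1 / alpha, mu = mu),
                 tolerance = 1e-10)
  }
})

test_that("ZINB converges to ZIP as the dispersion vanishes", {
  grid <- expand.grid(y = c(0:10, 25, 50), mu = c(0.2, 1, 5, 20),
                      pi = c(0, 0.3, 0.7))
  diff <- abs(zinb_pmf(grid$y, grid$mu, grid$pi, alpha = 1e-6) -
              zip_pmf(grid$y, grid$mu, grid$pi))
  expect_lt(max(diff), 1e-6)
})

test_that("mean structure follows the kernel-driven links", {
  spec <- zi_model_spec("ZIP", "negative-exponential", Q = 0, a = 1)
  ms <- mean_structure(spec, c(0.35, 5, 50))
  expect_equal(ms$mu, rep(1, 3))
  expect_equal(ms$pi, rep(0.5, 3))
  # large-distance limit: r -> 0 so mu -> 1, pi -> 0.5 in both modes
  for (mode in c("reconciled", "literal")) {
    spec <- zi_model_spec("ZIP", "Gaussian", mode, Q = 3, a = 1)
    ms <- mean_structure(spec, 1e6)
    expect_equal(ms$mu, 1, tolerance = 1e-9)
    expect_equal(ms$pi, 0.5, tolerance = 1e-9)
  }
  # reconciled: mu = 12 -> pi = 1/13
  spec <- zi_model_spec("ZIP", "negative-exponential", Q = log(12) / exp(-1),
                        a = 1)
  ms <- mean_structure(spec, 1)
  expect_equal(ms$mu, 12, tolerance = 1e-9)
  expect_equal(ms$pi, 1 / 13, tolerance = 1e-9)
  expect_equal(round(ms$pi, 4), 0.0769)
})

test_that("negative log-likelihood matches a brute-force pmf product", {
  s1 <- toy_samples(0L, distances = 1)
  # Q = 0, reconciled ZIP: -log(0.5 + 0.5 exp(-1))
  val <- neg_loglik(c(0, 0), "ZIP", "negative-exponential", s1)
  expect_equal(round(val, 5), 0.37989)
  # additivity under dataset duplication
  s2 <- rbind(s1, s1)
  expect_equal(neg_loglik(c(0, 0), "ZIP", "negative-exponential", s2),
               2 * val)
  # brute force over 20 random samples
  set.seed(9)
  s <- toy_samples(as.integer(rpois(20, 2)),
                   distances = runif(20, 0.35, 12.95))
  theta <- c(1.7, log(1.3), log(0.8), log(0.6))
  spec <- zi_model_spec("ZINB", "exponential-power", Q = 1.7, a = 1.3,
                        b = 0.8, alpha = 0.6)
  ms <- mean_structure(spec, s$distance_m)
  brute <- -sum(log(zinb_pmf(model_counts(s), ms$mu, ms$pi, 0.6)))
  expect_equal(neg_loglik(theta, "ZINB", "exponential-power", s), brute,
               tolerance = 1e-9)
  # invalid parameters give the optimizer-safe sentinel
  expect_identical(neg_loglik(c(NA, 0), "ZIP", "negative-exponential", s1),
                   Inf)
})

test_that("maximum likelihood recovers known generator parameters", {
  spec <- zi_model_spec("ZINB", "negative-exponential", Q = 2.5, a = 1,
                        alpha = 1)
  cfg <- simulation_config(n_experiments = 10, mode = "model",
                           model_spec = spec, seed = 3)
  s <- simulate_dataset(cfg)  # 19 distances x 200 draws
  fit <- fit_zi_model(s, "ZINB", "negative-exponential", n_starts = 8,
                      seed = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$spec$Q - 2.5) / 2.5, 0.10)
  # the MLE cannot be beaten by the true parameters
  true_nll <- neg_loglik(c(2.5, 0, 0), "ZINB", "negative-exponential", s)
  expect_gte(fit$loglik, -true_nll - 1e-6)
})

test_that("refitting from the optimum is a fixed point", {
  s <- simulate_dataset(small_config(seed = 6))
  fit <- fit_zi_model(s, "ZINB", "negative-exponential", n_starts = 6,
                      seed = 5)
  refit <- fit_zi_model(s, "ZINB", "negative-exponential",
                        start = list(Q = fit$spec$Q, a = fit$spec$a,
                                     alpha = fit$spec$alpha))
  expect_lt(abs(refit$loglik - fit$loglik), 1e-6)
})

test_that("degenerate inputs are refused, never silently fitted", {
  s <- simulate_dataset(small_config(seed = 1))
  expect_error(fit_zi_model(s[1:5, ], "ZINB", "Weibull"), "insufficient")
  flat <- s[s$distance_m %in% c(0.35, 1.05), ]
  expect_error(fit_zi_model(flat, "ZINB", "Weibull"), "insufficient")
})

test_that("predicted CP follows the expected-count formula and plateau", {
  flat <- fake_fit(family = "ZIP", Q = 0, alpha = NA)
  expect_equal(round(predicted_cp(flat, c(0.35, 2, 50)), 4),
               rep(0.1302, 3))
  # reconciled mu(0.35) = 12 -> 100 * (12^2/13)/384
  f <- fake_fit(family = "ZIP", Q = log(12) / exp(-0.35), a = 1, alpha = NA)
  expect_equal(round(predicted_cp(f, 0.35), 4), 2.8846)
  # far-distance plateau for any converged fit
  expect_equal(round(predicted_cp(f, 1e5), 4), 0.1302)
  # monotone non-increasing for Q > 0 with a monotone kernel
  cp <- predicted_cp(fake_fit(Q = 3, a = 1.5), seq(0.35, 20, by = 0.05))
  expect_true(all(diff(cp) <= 1e-12))
  # literal mode can never exceed one count's worth of CP
  lit <- fake_fit(pi_mode = "literal", Q = 5, a = 2)
  cp <- predicted_cp(lit, seq(0.35, 20, by = 0.1))
  expect_true(all(cp < 100 / 384))
  # unconverged fits refuse to predict
  bad <- fake_fit(); bad$converged <- FALSE
  expect_error(predicted_cp(bad, 1), "unconverged")
})

test_that("fit serialization records the estimates and metadata", {
  f <- fake_fit(Q = 2.2, a = 0.9, alpha = 1.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_zi_fit(f, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$estimates$Q, 2.2)
  expect_identical(j$kernel, "negative-exponential")
  expect_true(j$converged)
})
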