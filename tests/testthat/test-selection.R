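# fit whose predictions are exact on purpose-built samples
perfect_samples <- function(fit, distances) {
  s <- toy_samples(rep(0L, length(distances)), distances = distances)
  s$cp_percent <- predicted_cp(fit, distances)
  s
}

test_that("train/validation split is a seeded stratified 70/30 partition", {
  s <- simulate_dataset(small_config(seed = 3))[1:100, ]
  sp <- train_valid_split(s, fraction = 0.7, seed = 11)
  expect_identical(nrow(sp$train), 70L)
  expect_identical(nrow(sp$valid), 30L)
  # partition: disjoint and exhaustive
  key <- function(df) sort(do.call(paste, df))
  expect_identical(sort(c(key(sp$train), key(sp$valid))), key(s))
  # determinism
  sp2 <- train_valid_split(s, fraction = 0.7, seed = 11)
  expect_identical(sp$train, sp2$train)
  # stratification: both sets cover every distance class at default sizes
  full <- simulate_dataset(small_config(seed = 3))
  spf <- train_valid_split(full, seed = 2)
  expect_setequal(unique(spf$train$distance_m), design_distances())
  expect_setequal(unique(spf$valid$distance_m), design_distances())
  expect_error(train_valid_split(s, fraction = 1.2), "fraction")
})

test_that("fit criteria match their formulas", {
  f <- fake_fit(Q = 3, a = 1.5, loglik = -100)
  f$n_params <- 3L
  d <- rep(design_distances(), each = 6)[1:100]
  s <- perfect_samples(f, d)
  m <- fit_metrics(f, s)
  expect_equal(m$rmse, 0)
  expect_equal(m$adj_r2, 1)
  expect_equal(m$aic, 206)
  expect_equal(m$bic, 200 + 3 * log(100))
  expect_equal(round(m$bic, 3), 213.816)

  # a constant predictor at the observed mean cannot beat adj R^2 = 0
  flat <- fake_fit(family = "ZIP", Q = 0, alpha = NA, loglik = -100)
  flat$n_params <- 2L
  s2 <- toy_samples(rep(0L, 40), distances = rep(c(1, 2), 20))
  plateau <- predicted_cp(flat, 1)
  s2$cp_percent <- plateau + rep(c(-0.05, 0.05), 20)  # mean = plateau
  m2 <- fit_metrics(flat, s2)
  expect_lte(m2$adj_r2, 0)

  expect_error(fit_metrics(f, s[1:4, ]), "undefined")
})

test_that("metrics are invariant to sample order", {
  f <- fake_fit(Q = 2, a = 1)
  set.seed(13)
  s <- toy_samples(as.integer(rpois(60, 1)),
                   distances = rep(design_distances(), length.out = 60))
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(fit_metrics(f, s)$rmse, fit_metrics(f, shuffled)$rmse)
  expect_equal(mspr(f, s), mspr(f, shuffled))
})

test_that("MSPR is the mean squared proportion error", {
  f <- fake_fit(Q = 3, a = 1.5)
  d <- design_distances()
  expect_equal(mspr(f, perfect_samples(f, d)), 0)
  # constant prediction c on observations {0, 2c} -> c^2
  flat <- fake_fit(family = "ZIP", Q = 0, alpha = NA)
  c_prop <- predicted_cp(flat, 1) / 100
  s <- toy_samples(rep(0L, 2), distances = c(1, 2))
  s$cp_percent <- c(0, 2 * c_prop * 100)
  expect_equal(mspr(flat, s), c_prop^2)
  # on the training set MSPR equals rmse^2
  set.seed(14)
  s3 <- toy_samples(as.integer(rpois(50, 1)),
                    distances = rep(design_distances(), length.out = 50))
  f$n_params <- 3L
  expect_equal(mspr(f, s3), fit_metrics(f, s3)$rmse^2)
})

test_that("model ranking reproduces the published criterion ordering", {
  # printed ZINB fit criteria (training) and MSPR (validation)
  zinb <- data.frame(
    model = c("log-sech", "exponential-power", "power-law", "logistic",
              "2Dt", "gamma", "WALD", "Weibull", "negative-exponential",
              "log-normal", "Gaussian"),
    rmse = c(0.00823, 0.00823, 0.00826, 0.00826, 0.00824, 0.00823,
             0.00825, 0.00823, 0.00828, 0.00824, 0.00826),
    adj_r2 = c(0.38911, 0.38925, 0.38495, 0.38517, 0.38769, 0.38884,
               0.38542, 0.38947, 0.38183, 0.38717, 0.38444),
    aic = c(-17859, -17859, -17846, -17847, -17855, -17858, -17848,
            -17860, -17838, -17853, -17846),
    bic = c(-17852, -17852, -17839, -17840, -17847, -17851, -17841,
            -17853, -17829, -17846, -17837),
    mspr = c(0.000068767, 0.000068742, 0.000069270, 0.0000689892,
             0.000068832, 0.000068764, 0.000069033, 0.000068764,
             0.000069723, 0.000068869, 0.000069163))
  r <- rank_models(zinb)
  expect_setequal(r$candidates$model,
                  c("Weibull", "exponential-power", "log-sech"))
  expect_identical(r$ordering$model[1], "Weibull")
  expect_identical(r$final$model, "exponential-power")  # smallest MSPR
})

test_that("ranking ties preserve input order and NA rows sink", {
  two <- data.frame(model = c("A", "B"), rmse = 1, adj_r2 = 0.5,
                    aic = 10, bic = 12, mspr = 0.1)
  r <- rank_models(two)
  expect_identical(r$ordering$model, c("A", "B"))
  expect_identical(r$final$model, "A")
  three <- rbind(two, data.frame(model = "C", rmse = NA, adj_r2 = NA,
                                 aic = NA, bic = NA, mspr = NA))
  r3 <- rank_models(three)
  expect_identical(r3$ordering$model[3], "C")
  expect_false("C" %in% r3$final$model)
})

test_that("the model grid reports every requested combination", {
  s <- simulate_dataset(small_config(seed = 8))
  sp <- train_valid_split(s, seed = 1)
  g <- fit_model_grid(sp$train, sp$valid, families = c("ZIP", "ZINB"),
                      kernels = c("negative-exponential", "Gaussian"),
                      n_starts = 5, seed = 2)
  expect_identical(nrow(g$metrics), 4L)
  expect_identical(length(g$fits), 4L)
  expect_true(all(c("ZIP-Gaussian", "ZINB-negative-exponential") %in%
                  g$metrics$model))
  # ZINB nests ZIP: its likelihood can only be higher on overdispersed data
  zip_ll <- g$metrics$loglik[g$metrics$model == "ZIP-negative-exponential"]
  zinb_ll <- g$metrics$loglik[g$metrics$model == "ZINB-negative-exponential"]
  expect_gte(zinb_ll, zip_ll - 1e-6)
})
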