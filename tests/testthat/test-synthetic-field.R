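test_that("pooled distance profile reproduces the published summaries", {
  prof <- default_mean_profile()
  expect_identical(nrow(prof), 19L)
  expect_equal(prof$distance_m, seq(0.35, 12.95, by = 0.7))
  expect_equal(round(prof$mean_cp[prof$distance_m == 0.35], 2), 2.78)
  expect_equal(round(prof$mean_cp[prof$distance_m == 12.95], 3), 0.028)
  # mean CP drops below 1% by 1.75 m and is non-increasing over 0.35-1.75 m
  near <- prof$mean_cp[prof$distance_m <= 1.75]
  expect_true(all(diff(near) < 0))
  expect_lt(near[3], 1)
})

test_that("per-experiment mean table has the printed extremes", {
  tab <- cp_field_means()
  expect_identical(dim(tab), c(19L, 13L))
  row035 <- as.numeric(tab[tab$distance_m == 0.35, -1])
  expect_equal(min(row035), 0.48)
  expect_equal(max(row035), 5.07)
})

test_that("field layouts follow the two-site design", {
  for (site in c("TARI", "AES")) {
    fl <- build_field_layout(site)
    expect_identical(fl$n_donor, 696L)
    expect_identical(fl$n_recipient, 1776L)
    expect_identical(fl$furrow_count, 12L)
    pts <- rbind(fl$donor_positions[c("x", "y")],
                 fl$recipient_positions[c("x", "y")])
    expect_true(all(pts$x >= 0 & pts$x <= fl$field_extent["length_m"]))
    expect_true(all(pts$y >= 0 & pts$y <= fl$field_extent["width_m"]))
    # recipient offsets reproduce the sampling grid
    expect_equal(sort(unique(fl$recipient_positions$offset_m)),
                 seq(0.35, 12.95, by = 0.35))
    # nearest-donor distance within the geometric bounds
    diag_m <- sqrt(sum(fl$field_extent^2))
    d1 <- plant_distance(as.matrix(fl$recipient_positions[1, c("x", "y")]),
                         as.matrix(fl$donor_positions[1, c("x", "y")]))
    expect_gte(d1, 0); expect_lte(d1, diag_m)
  }
  expect_setequal(unique(build_field_layout("TARI")$recipient_positions$plot_side),
                  c("up", "down"))
  expect_setequal(unique(build_field_layout("AES")$recipient_positions$plot_side),
                  c("east", "west"))
  expect_error(build_field_layout("XYZ"))
})

test_that("simulation is deterministic given the config seed", {
  cfg <- small_config(seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_simulated_dataset(a, cfg, p1)
  write_simulated_dataset(b, cfg, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed gives different counts
  expect_false(identical(a$n_hybrid,
                         simulate_dataset(small_config(seed = 100))$n_hybrid))
})

test_that("a zero mean profile yields all-zero counts", {
  prof <- data.frame(distance_m = design_distances(), mean_cp = 0)
  cfg <- small_config(seed = 1, mean_profile = prof)
  s <- simulate_dataset(cfg)
  expect_true(all(s$n_hybrid == 0L))
})

test_that("empirical mode is calibrated to the design conditions", {
  # zero fraction per experiment in the observed 70-90% band and
  # variance > mean, for several generator seeds
  for (seed in 1:3) {
    s <- simulate_dataset(simulation_config(seed = seed))
    for (id in unique(s$experiment_id)) {
      y <- model_counts(s[s$experiment_id == id, ])
      zf <- mean(y == 0)
      expect_gte(zf, 0.70)
      expect_lte(zf, 0.90)
      expect_gt(var(y), mean(y))
    }
  }
})

test_that("empirical mode hits the profile mean at the closest distance", {
  s <- simulate_dataset(simulation_config(seed = 4))
  cp035 <- s$cp_percent[s$distance_m == 0.35]
  se <- sd(cp035) / sqrt(length(cp035))
  expect_lt(abs(mean(cp035) - 2.7767), 3 * se)
})

test_that("model mode draws from the exact zero-inflated law", {
  spec <- zi_model_spec("ZINB", "Weibull", Q = 2.5, a = 1.2, b = 1.3,
                        alpha = 1)
  cfg <- simulation_config(n_experiments = 10, mode = "model",
                           samples_per_distance_per_plot = 10,
                           model_spec = spec, seed = 21)
  s <- simulate_dataset(cfg)
  ms <- mean_structure(spec, design_distances())
  law_mean <- (1 - ms$pi) * ms$mu
  for (i in c(1, 5, 10, 19)) {
    d <- design_distances()[i]
    y <- model_counts(s[s$distance_m == d, ])  # 200 draws
    se <- sd(y) / sqrt(length(y))
    expect_lt(abs(mean(y) - law_mean[i]), 3 * se + 1e-9)
  }
})

test_that("model-mode draws pass a goodness-of-fit test against the pmf", {
  mu <- 3; pi <- 0.3; alpha <- 0.5
  set.seed(17)
  y <- rzicount(1e4, mu, pi, family = "ZINB", alpha = alpha)
  kmax <- max(y)
  p_full <- zinb_pmf(0:kmax, mu, pi, alpha)
  K <- max(which(p_full * length(y) >= 5))  # pool sparse tail bins
  probs <- c(p_full[1:K], 1 - sum(p_full[1:K]))
  obs <- c(tabulate(y + 1L, nbins = kmax + 1L)[1:K], sum(y >= K))
  chi <- stats::chisq.test(obs, p = probs)
  expect_gt(chi$p.value, 1e-3)
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(distances = c(2, 1)), "increasing")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  prof <- data.frame(distance_m = design_distances(), mean_cp = 150)
  expect_error(simulation_config(mean_profile = prof), "\\[0, 100\\]")
  expect_error(simulation_config(mode = "model"), "model_spec")
})
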