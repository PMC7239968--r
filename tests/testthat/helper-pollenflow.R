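# shared fixture builders (all data generated in code)

# a small but fit-able dataset: 2 experiments x 2 plots x 19 distances x 3
small_config <- function(seed = 1, ...) {
  simulation_config(n_experiments = 2, samples_per_distance_per_plot = 3,
                    seed = seed, ...)
}

# hand-built sample table at arbitrary counts
toy_samples <- function(counts, distances = NULL, n_seeds = 384L) {
  n <- length(counts)
  if (is.null(distances)) distances <- rep(design_distances(),
                                           length.out = n)
  pollination_samples(
    experiment_id = "t-1", site = "TARI",
    plot_side = rep(c("up", "down"), length.out = n),
    distance_m = distances, n_seeds = n_seeds, n_hybrid = counts)
}

# a zi_fit object with known parameter values (bypasses fitting), for
# testing prediction/isolation arithmetic against closed forms
fake_fit <- function(family = "ZINB", kernel = "negative-exponential",
                     pi_mode = "reconciled", Q = 3, a = 1, b = NA,
                     alpha = 1, loglik = -100, n_obs = 100) {
  spec <- zi_model_spec(family, kernel, pi_mode, Q = Q, a = a, b = b,
                        alpha = if (family == "ZINB") alpha else NA_real_)
  structure(list(spec = spec, loglik = loglik, n_obs = n_obs,
                 n_params = 3L, n_seeds = 384L, converged = TRUE,
                 start_points_tried = 1L, gradient_norm = 0),
            class = "zi_fit")
}
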