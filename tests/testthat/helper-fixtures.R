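# Fixtures are built in code: exponential-growth curves with known closed
# forms, and small two-site synthetic studies for calibration tests.

exp_curve <- function(mu = 0.5, t_end = 10, dt = 0.01, X0 = 1) {
  tt <- seq(0, t_end, by = dt)
  growth_curve(tt, X0 * exp(mu * tt), X0 = X0)
}

const_curve <- function(X = 1, t_end = 10, dt = 0.01) {
  tt <- seq(0, t_end, by = dt)
  growth_curve(tt, rep(X, length(tt)), X0 = X)
}

# closed-form average cell age under exponential growth at rate mu
age_exponential <- function(mu, t) (1 - exp(-mu * t)) / mu

# small two-site study for calibration/selection tests
small_study <- function(truth = truth_spec(), seed = 201, noise_sd = 0.02,
                        noise_type = "multiplicative") {
  study_config(
    site_config(6, 36, noise_sd = noise_sd, noise_type = noise_type),
    site_config(4, 24, age_range = c(1.237, 2.985), noise_sd = noise_sd,
                noise_type = noise_type),
    truth = truth, seed = seed)
}

fast_opts <- function(seed = 5, ...) {
  fit_options(seed = seed, n_starts = 1, ...)
}

# a random but admissible state for model-evaluation identities
random_state <- function(n = 7, seed = 99) {
  set.seed(seed)
  pmax_state(mu = runif(n, 0.05, 0.6), age = runif(n, 0.5, 4),
             X = runif(n, 2, 30), mu_ind = runif(1, 0.2, 0.5),
             age_ind = runif(1, 1.1, 3), X_ind = runif(1, 2, 10))
}
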