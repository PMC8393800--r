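test_that("growth simulation hits the requested induction age", {
  # exponential growth at mu = 0.5 reaches age 1.7293 at t ~ 4.0
  cfg <- site_config(1, 5, mu0_range = c(0.5, 0.5), mu_decay = 0,
                     t_batch = 2, X0_range = c(1, 1),
                     age_range = c(1.7293, 1.7293))
  set.seed(1)
  g <- simulate_growth(cfg)
  expect_equal(g$t_ind, 4.0, tolerance = 0.05)

  # biomass strictly increasing under a positive SGR profile
  expect_true(all(diff(g$curve$X) > 0))

  # identical RNG state -> identical curve
  set.seed(33); g1 <- simulate_growth(site_config(1, 5))
  set.seed(33); g2 <- simulate_growth(site_config(1, 5))
  expect_identical(g1$curve$X, g2$curve$X)
  expect_identical(g1$t_ind, g2$t_ind)

  # unreachable induction age is rejected, naming the config field
  expect_error(
    simulate_growth(site_config(1, 5, age_range = c(30, 31), t_max = 10)),
    "age_range")
})

test_that("generated induction ages stay inside the configured range", {
  cfg <- site_config(1, 5, age_range = c(1.14, 3.105))
  set.seed(77)
  ages <- vapply(seq_len(300), function(i) {
    g <- simulate_growth(cfg)
    st <- state_series(g$curve)
    induction_state(g$curve, st, g$t_ind)$age_ind
  }, numeric(1))
  expect_true(all(ages >= 1.14 - 0.01 & ages <= 3.105 + 0.01))
})

test_that("noiseless samples lie on the oracle trajectory", {
  tr <- truth_spec()
  cfg <- site_config(1, 5, noise_sd = 0)
  set.seed(5)
  rec <- simulate_experiment(cfg, tr, n_samples = 6)
  # re-integrate independently and compare at the sample times
  st <- state_series(rec$curve)
  ind <- induction_state(rec$curve, st, rec$t_ind)
  sub <- which(rec$curve$t >= rec$t_ind - 1e-9)[1]:length(rec$curve$t)
  state <- pmax_state(st$mu[sub], st$age[sub], rec$curve$X[sub],
                      ind$mu_ind, ind$age_ind, ind$X_ind)
  pm <- evaluate_pmax(tr$model, tr$params, state)
  orc <- integrate_protein_ode(rec$curve$t[sub],
                               approxfun(rec$curve$t[sub], pm, rule = 2),
                               tr$kt, X = rec$curve$X[sub])
  expect_equal(rec$samples$y,
               approx(orc$t, orc$P, xout = rec$samples$t_s)$y,
               tolerance = 1e-9)

  # a null truth yields all-zero samples
  set.seed(5)
  rec0 <- simulate_experiment(cfg, truth_spec(pmax_model("null"), param_vector()),
                              n_samples = 4)
  expect_true(all(rec0$samples$y == 0))
})

test_that("constant conditions reproduce the closed-form protein integral", {
  # Pmax = k0*mu_ind = 0.004 constant, X = 10, kt = 0:
  # P(t_ind + 5) = 0.004 * 5 * 10 = 0.2
  tt <- seq(0, 10, by = 0.01)
  orc <- integrate_protein_ode(tt, function(t) 0.01 * 0.4, kt = 0,
                               X = rep(10, length(tt)))
  expect_equal(approx(orc$t, orc$P, xout = 5)$y, 0.2, tolerance = 1e-9)
})

test_that("oracle and discrete scheme agree on default configurations", {
  st <- small_study(seed = 61, noise_sd = 0)
  st$site1$n_experiments <- 2L; st$site1$n_samples <- 10L
  st$site2$n_experiments <- 2L; st$site2$n_samples <- 10L
  ds <- simulate_dataset(st)
  for (rec in ds) {
    pr <- predict_protein(rec, st$truth$model, st$truth$params, dt = 0.01)
    # noiseless samples are oracle values; compare scheme at sample times
    expect_equal(pr$pred, rec$samples$y, tolerance = 0.01)
  }
})

test_that("benchmark-shaped study has the reference dimensions", {
  ds <- simulate_dataset(two_site_benchmark_study(seed = 11))
  expect_length(ds, 70L)
  sites <- vapply(ds, `[[`, integer(1), "site")
  expect_identical(sum(sites == 1L), 46L)
  expect_identical(sum(sites == 2L), 24L)
  counts <- vapply(ds, function(e) nrow(e$samples), integer(1))
  expect_identical(sum(counts[sites == 1L]), 196L)
  expect_identical(sum(counts[sites == 2L]), 131L)

  # deterministic under the seed; different seeds differ
  ds2 <- simulate_dataset(two_site_benchmark_study(seed = 11))
  expect_identical(ds[[1]]$samples$y, ds2[[1]]$samples$y)
  ds3 <- simulate_dataset(two_site_benchmark_study(seed = 12))
  expect_false(identical(ds[[1]]$samples$y, ds3[[1]]$samples$y))

  # pooled null RSS equals the site-weighted sums of squares
  y1 <- unlist(lapply(ds[sites == 1L], function(e) e$samples$y))
  y2 <- unlist(lapply(ds[sites == 2L], function(e) e$samples$y))
  expect_equal(rss_max(ds),
               (131 * sum(y1^2) + 196 * sum(y2^2)) / 327, tolerance = 1e-9)
})

test_that("infeasible sample allocations are rejected", {
  expect_error(site_config(10, 5), "infeasible")
})

test_that("recovery report tracks truth recovery across replicates", {
  st <- study_config(site_config(3, 12, noise_sd = 0), site2 = NULL,
                     truth = truth_spec(pmax_model("eq33"),
                                        param_vector(k0 = 0.01)),
                     seed = 19)
  rep0 <- recovery_report(st, n_replicates = 2,
                          opts = fast_opts(dt = 0.01, polish = 2))
  expect_identical(nrow(rep0), 2L)
  expect_true(all(rep0$k0_relerr <= 1e-3))

  # noise degrades recovery relative to the noiseless fit
  st$site1$noise_sd <- 0.05
  rep1 <- recovery_report(st, n_replicates = 2,
                          opts = fast_opts(dt = 0.01, polish = 2))
  expect_gt(median(rep1$k0_relerr), median(rep0$k0_relerr))
})
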