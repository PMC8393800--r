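test_that("discrete scheme reproduces the two-step hand recursion", {
  # kt = 0.5, dt = 1, Pmax = (0.1, 0.1), X = 1:
  # P1 = 0.1/1.5 = 0.0666667, P2 = (0.2 - 0.5*0.0666667)/1.5 = 0.1111111
  px <- pmaxsel:::scheme_px(c(0.1, 0.1, 0.1), kt = 0.5, dt = 1)
  expect_equal(px[2], 0.1 / 1.5, tolerance = 1e-12)
  expect_equal(px[3], (0.2 - 0.5 * px[2]) / 1.5, tolerance = 1e-12)
  expect_equal(px[3], 0.1111111, tolerance = 1e-6)
})

test_that("zero Pmax and constant Pmax have exact solutions", {
  gc <- exp_curve(mu = 0.3, t_end = 10, dt = 0.01)
  rec <- experiment_record("e1", 1, gc, t_ind = 3,
                           protein_samples(c(5, 7, 9), c(1, 2, 3)))
  # Pmax == 0 -> P == 0 for any kt
  pr0 <- predict_protein(rec, pmax_model("eq37"),
                         param_vector(k8 = 0, k_t = 1.7))
  expect_true(all(pr0$P == 0))

  # constant Pmax = k0*mu_ind with kt = 0: P(t) = c*(t - t_ind)*X(t) exactly
  pr1 <- predict_protein(rec, pmax_model("eq33"), param_vector(k0 = 0.02),
                         dt = 0.1)
  ind <- pr1$ind
  c0 <- 0.02 * ind$mu_ind
  expect_equal(pr1$P, c0 * (pr1$t - 3) * approx(gc$t, gc$X, pr1$t)$y,
               tolerance = 1e-10)
})

test_that("scheme converges to the Runge-Kutta oracle at order >= 1", {
  gc <- exp_curve(mu = 0.4, t_end = 10, dt = 0.005)
  t_ind <- 3
  rec <- experiment_record("e1", 1, gc, t_ind,
                           protein_samples(c(6, 8, 10), c(1, 1, 1)))
  model <- pmax_model("eq37") # k8 * age with free kt
  params <- param_vector(k8 = 0.05, k_t = 0.8)

  # oracle: fine RK4 of dPX/dt = k8*age(t) - kt*PX
  agef <- approxfun(gc$t, average_cell_age(gc))
  tfine <- seq(t_ind, 10, by = 0.002)
  orc <- integrate_protein_ode(tfine, function(t) 0.05 * agef(t), kt = 0.8)
  px_ref <- approxfun(orc$t, orc$PX)

  errs <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    pr <- predict_protein(rec, model, params, dt = dt)
    max(abs(pr$PX - px_ref(pr$t)))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 0.9))

  # steady-state bound: constant Pmax = c, PX <= c/kt + one-step truncation
  rec2 <- experiment_record("e2", 1, gc, t_ind,
                            protein_samples(10, 1))
  pr2 <- predict_protein(rec2, pmax_model("eq36"),
                         param_vector(k0 = 0.1, k_t = 2), dt = 0.05)
  cmax <- 0.1 * pr2$ind$mu_ind
  expect_true(all(pr2$PX <= cmax / 2 + cmax * 0.05))
})

test_that("protein predictions vanish before induction", {
  gc <- exp_curve(mu = 0.3, t_end = 10, dt = 0.01)
  rec <- experiment_record("e1", 1, gc, t_ind = 5,
                           protein_samples(c(2, 6, 9), c(0, 1, 2)))
  pr <- predict_protein(rec, pmax_model("eq34"), param_vector(k8 = 0.1))
  expect_identical(pr$pred[1], 0) # sample at t = 2 < t_ind
  expect_true(all(pr$pred[-1] > 0))
})

test_that("goodness-of-fit measures match hand arithmetic", {
  samples <- protein_samples(c(1, 2), c(2, 1))
  preds <- c(1, 3) # residuals (1, -2)
  expect_equal(residuals_rss(preds, samples), 5)
  expect_equal(mae_error(preds, samples), 1.5)
  expect_equal(residuals_rss(samples$y, samples), 0)
  # MAE <= sqrt(MSE)
  expect_lte(mae_error(preds, samples), sqrt(5 / 2))
})

test_that("pooled RSS weights sites evenly by average variance", {
  expect_equal(pooled_rss(2, 1, 196, 131), 458 / 327)
  expect_equal(pooled_rss(0, 0, 10, 20), 0)
  # equal counts -> arithmetic mean
  expect_equal(pooled_rss(3, 5, 7, 7), 4)
  # exchangeability under swapping (site, n) pairs
  expect_equal(pooled_rss(3, 5, 7, 11), pooled_rss(5, 3, 11, 7))
  # linearity in each site RSS
  expect_equal(pooled_rss(6, 5, 7, 11), 2 * pooled_rss(3, 5, 7, 11) -
                 pooled_rss(0, 5, 7, 11))
  expect_error(pooled_rss(1, 1, 0, 5), "positive")
})

test_that("entropy objective blends relative and absolute error", {
  samples <- protein_samples(1, 1)
  # perfect fit: 0 for any kexp, either variant
  for (v in c("consistent", "as_printed"))
    for (ke in c(0, 1, 2))
      expect_equal(entropy_objective(1, samples, kexp = ke, variant = v), 0)
  # consistent at kexp = 2 equals -RSS
  expect_equal(entropy_objective(1.5, samples, kexp = 2), -0.25)
  # printed form at kexp = 0: -e^2/(2 y^2)
  expect_equal(entropy_objective(1.5, samples, kexp = 0, variant = "as_printed"),
               -0.125)
  # zero observation rejected when the relative term is active
  s0 <- protein_samples(1, 0)
  expect_error(entropy_objective(0.5, s0, kexp = 0), "zero observations")
  expect_silent(entropy_objective(0.5, s0, kexp = 2))
})

test_that("maximising consistent entropy at kexp 2 minimises RSS", {
  gc <- exp_curve(mu = 0.3, t_end = 10, dt = 0.01)
  rec <- experiment_record("e1", 1, gc, t_ind = 3,
                           protein_samples(c(5, 7, 9), c(0.5, 1.2, 2.1)))
  k0_grid <- seq(0.001, 0.05, length.out = 40)
  stats <- vapply(k0_grid, function(k0) {
    pr <- predict_protein(rec, pmax_model("eq33"), param_vector(k0 = k0))
    c(rss = residuals_rss(pr, rec$samples),
      negL = -entropy_objective(pr, rec$samples, kexp = 2))
  }, numeric(2))
  expect_equal(stats["negL", ], stats["rss", ], tolerance = 1e-12)
  expect_identical(which.min(stats["rss", ]), which.min(stats["negL", ]))
})
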