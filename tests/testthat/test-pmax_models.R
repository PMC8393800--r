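test_that("registry owns every coefficient k0..k22 exactly once", {
  reg <- pmax_registry()
  syms <- unlist(lapply(reg, `[[`, "coeffs"), use.names = FALSE)
  expect_setequal(syms, paste0("k", 0:22))
  expect_false(anyDuplicated(syms) > 0)
  # term-level structure spot checks
  expect_identical(reg$age_lin$state_vars, "age")
  expect_setequal(reg$haldane_mu$dens, c("k14", "k15"))
  # denominator symbols are owned by their term
  for (tm in reg) expect_true(all(tm$dens %in% tm$coeffs))
})

test_that("evaluate_pmax matches hand evaluations and handles singularities", {
  s <- pmax_state(mu = 0.2, age = 2, X = 10, mu_ind = 0.4, age_ind = 1.5,
                  X_ind = 8)
  # all-zero coefficients give zero
  expect_equal(evaluate_pmax(pmax_model("full2021"), param_vector(), s), 0)
  # Monod age model at reported-style coefficients:
  # 0.00298 * 0.4 * 2 / (-1.302 + 2) + 0.00298
  expect_equal(
    evaluate_pmax(pmax_model("eq32"), param_vector(k16 = 0.00298, k20 = -1.302), s),
    0.00298 * 0.4 * 2 / 0.698 + 0.00298, tolerance = 1e-12)
  # induction-SGR singleton: 0.0159 * 0.5
  s2 <- pmax_state(0.1, 1, 1, mu_ind = 0.5, age_ind = 1, X_ind = 1)
  expect_equal(
    evaluate_pmax(pmax_model("eq33"), param_vector(k0 = 0.0159), s2), 0.00795)
  # singular denominator raises a classed domain error
  s3 <- pmax_state(0.2, age = 1.302, X = 10, mu_ind = 0.4, age_ind = 1.5, X_ind = 8)
  expect_error(
    evaluate_pmax(pmax_model("eq32"), param_vector(k16 = 0.1, k20 = -1.302), s3),
    class = "pmaxsel_domain_error")
  # ... as does a sign change of the denominator along the grid
  s4 <- pmax_state(c(0.2, 0.2), age = c(1.0, 2.0), X = c(5, 10),
                   mu_ind = 0.4, age_ind = 1.5, X_ind = 8)
  expect_error(
    evaluate_pmax(pmax_model("eq32"), param_vector(k16 = 0.1, k20 = -1.5), s4),
    class = "pmaxsel_domain_error")
})

test_that("full combined model is additive in its registry terms", {
  reg <- pmax_registry()
  s <- random_state(n = 9, seed = 11)
  set.seed(12)
  # positive denominators keep every term regular
  p <- param_vector()
  for (tm in reg) for (sym in tm$coeffs) p[sym] <- runif(1, 0.01, 0.5)
  total <- evaluate_pmax(pmax_model("full2021"), p, s)
  by_term <- Reduce(`+`, lapply(reg, function(tm) tm$fn(p, s)))
  expect_equal(total, by_term, tolerance = 1e-12)
})

test_that("growth-linked preset equals its explicit formula", {
  s <- random_state(n = 8, seed = 21)
  p <- param_vector(k1 = -0.00243, k3 = 0.074, k_t = -0.112)
  expect_equal(evaluate_pmax(pmax_model("eq38"), p, s),
               s$mu * (p[["k1"]] * (s$X - s$X_ind) + p[["k3"]]),
               tolerance = 1e-14)
  expect_identical(pmax_model("eq38")$k, 3L)
})

test_that("model presets count free coefficients like the reference tables", {
  ks <- vapply(c(eq29 = "eq29", eq32 = "eq32", eq33 = "eq33", eq36 = "eq36",
                 eq37 = "eq37", m1999 = "m1999", m2003 = "m2003",
                 m2019 = "m2019", full2021 = "full2021"),
               function(nm) pmax_model(nm)$k, integer(1))
  expect_identical(unname(ks), c(3L, 2L, 1L, 2L, 2L, 2L, 4L, 3L, 24L))
})

test_that("trapezoid activity is the standard 0-1-0 piecewise ramp", {
  act <- list(a1 = 1, a2 = 2, a3 = 3, a4 = 4)
  expect_equal(trapezoid_activity(act, c(2.5, 1.5, 5, 0, 2, 3.5)),
               c(1, 0.5, 0, 0, 1, 0.5))
  expect_error(trapezoid_activity(list(a1 = 2, a2 = 1, a3 = 3, a4 = 4), 1),
               "a1 <= a2")
})

test_that("active-biomass 1999 model telescopes and is scale invariant", {
  tt <- 0:5
  gc <- growth_curve(tt, c(1, 1.5, 2.2, 3.1, 4.5, 6), X0 = 1)
  plateau <- list(a1 = -2, a2 = -1, a3 = 1e6, a4 = 1e6 + 1)
  # m == 1 everywhere telescopes to (X_i - X0)/X_i
  expect_equal(pmax_1999(gc, plateau, 5), (6 - 1) / 6, tolerance = 1e-12)
  # m == 0 gives 0
  expect_equal(pmax_1999(gc, list(a1 = 50, a2 = 60, a3 = 70, a4 = 80), 5), 0)
  # scale invariance under X -> c*X with plateau activity
  gc2 <- growth_curve(tt, 7 * gc$X, X0 = 7)
  expect_equal(pmax_1999(gc2, plateau, 5), pmax_1999(gc, plateau, 5))
  # hand sum: increments (1, 1), X_i = 3, activities (0.5, 1) -> 0.5
  gc3 <- growth_curve(c(0, 1, 2), c(1, 2, 3), X0 = 1)
  act3 <- list(a1 = 0, a2 = 0, a3 = 0, a4 = 2) # m(0) = 1, m(1) = 0.5
  expect_equal(pmax_1999(gc3, act3, 2), 0.5)
})

test_that("candidate enumeration is complete, capped and deterministic", {
  reg <- pmax_registry()
  n_single <- sum(vapply(reg, function(tm) length(tm$coeffs), integer(1)) == 1L)

  c1 <- enumerate_candidates(reg, k_cap = 1, include_kt = FALSE)
  # singletons: one per single-coefficient term, plus the appended presets
  expect_identical(sum(vapply(c1, `[[`, integer(1), "k") == 1L &
                         !vapply(c1, `[[`, logical(1), "kt_free")),
                   n_single + 2L) # + presets eq33, eq34

  c1kt <- enumerate_candidates(reg, k_cap = 1, include_kt = TRUE)
  expect_identical(c1kt[[1]]$name, "kt_only")
  expect_identical(c1kt[[1]]$k, 1L)

  c3 <- enumerate_candidates(reg, k_cap = 3)
  expect_true(all(vapply(c3, `[[`, integer(1), "k") <= 3L |
                    vapply(c3, `[[`, character(1), "name") %in%
                      c("eq29", "eq30", "eq31")))
  expect_false(anyDuplicated(vapply(c3, `[[`, character(1), "name")) > 0)

  # stable output order across calls
  expect_identical(vapply(enumerate_candidates(reg, 3), `[[`, character(1), "name"),
                   vapply(c3, `[[`, character(1), "name"))
  expect_error(enumerate_candidates(reg, k_cap = 0), "k_cap")
})
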