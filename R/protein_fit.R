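## Protein trajectory prediction via the discrete left-Riemann scheme for
## dPX/dt = Pmax(t) - kt * PX, plus the goodness-of-fit measures used in
## calibration and model selection.

#' Offline protein samples
#'
#' @param t_s Numeric vector of sample times (hours).
#' @param y Numeric vector of measured product concentrations (>= 0); units
#'   are carried through unchanged (e.g. specific activity U/g or g/L).
#' @param sigma Optional per-sample standard deviations.
#' @return A data frame of class `protein_samples`.
#' @export
protein_samples <- function(t_s, y, sigma = NULL) {
  if (length(t_s) != length(y)) pmaxsel_stop("`t_s` and `y` must have equal length")
  if (any(y < 0)) pmaxsel_stop("protein measurements `y` must be non-negative")
  if (is.unsorted(t_s)) {
    o <- order(t_s)
    t_s <- t_s[o]; y <- y[o]
    if (!is.null(sigma)) sigma <- sigma[o]
  }
  out <- data.frame(t_s = t_s, y = y)
  if (!is.null(sigma)) {
    if (length(sigma) != length(y)) pmaxsel_stop("`sigma` length mismatch")
    out$sigma <- sigma
  }
  class(out) <- c("protein_samples", class(out))
  out
}

#' One fed-batch experiment record
#'
#' Bundles the biomass trajectory of one cultivation with its induction time
#' and offline protein samples.
#'
#' @param id Experiment identifier (character).
#' @param site Site number, 1 or 2.
#' @param curve A [growth_curve()].
#' @param t_ind Induction time (hours), within the trajectory span.
#' @param samples A [protein_samples()] data frame with at least one sample
#'   at or after `t_ind`.
#' @param our Optional numeric OUR series aligned to the curve grid.
#' @return An object of class `experiment_record`.
#' @export
experiment_record <- function(id, site, curve, t_ind, samples, our = NULL) {
  stopifnot_curve(curve)
  if (!site %in% c(1, 2)) pmaxsel_stop("`site` must be 1 or 2")
  n <- length(curve$t)
  if (!is_number(t_ind) || t_ind < curve$t[1] || t_ind > curve$t[n])
    pmaxsel_stop(sprintf("experiment '%s': t_ind outside trajectory span", id))
  if (!inherits(samples, "protein_samples"))
    samples <- protein_samples(samples$t_s, samples$y, samples$sigma)
  if (!any(samples$t_s >= t_ind))
    pmaxsel_stop(sprintf("experiment '%s': no protein sample at or after induction", id))
  if (any(samples$t_s < curve$t[1]) || any(samples$t_s > curve$t[n]))
    pmaxsel_stop(sprintf("experiment '%s': sample time outside trajectory span", id))
  if (!is.null(our) && length(our) != n)
    pmaxsel_stop(sprintf("experiment '%s': OUR series not aligned to curve grid", id))
  structure(list(id = as.character(id), site = as.integer(site), curve = curve,
                 t_ind = t_ind, samples = samples, our = our),
            class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("<experiment_record> %s (site %d): t_ind = %.3g h, %d samples\n",
              x$id, x$site, x$t_ind, nrow(x$samples)))
  invisible(x)
}

## Pre-resolve the state variables of one experiment on the prediction grid
## (everything that does not depend on model coefficients), so repeated
## objective evaluations only re-run the cheap coefficient-dependent part.
prep_experiment <- function(exp, dt, window = 1L) {
  st <- state_series(exp$curve, window = window)
  ind <- induction_state(exp$curve, st, exp$t_ind)
  t_end <- exp$curve$t[length(exp$curve$t)]
  tg <- seq(exp$t_ind, t_end, by = dt)
  if (tg[length(tg)] < t_end - 1e-12) tg <- c(tg, t_end)
  state <- pmax_state(
    mu = approx(st$t, st$mu, xout = tg)$y,
    age = approx(st$t, st$age, xout = tg)$y,
    X = approx(exp$curve$t, exp$curve$X, xout = tg)$y,
    mu_ind = ind$mu_ind, age_ind = ind$age_ind, X_ind = ind$X_ind)
  list(exp = exp, tg = tg, dt = dt, state = state, ind = ind,
       t_s = exp$samples$t_s, y = exp$samples$y)
}

## core recursion of the discrete scheme, vectorised through a linear filter:
##   P_i = (sum_{j<=i} Pmax_j dt - kt sum_{j<=i-1} PX_j dt) * X_i / (1 + dt kt)
## with Pmax taken at the left endpoint of each step (left-Riemann sums)
scheme_px <- function(pm, kt, dt) {
  np <- length(pm)
  A <- c(0, cumsum(pm[-np] * dt))
  cc <- 1 + dt * kt
  if (!is.finite(cc) || abs(cc) < 1e-12)
    domain_stop("degenerate implicit factor 1 + dt * k_t in the discrete scheme")
  B <- as.numeric(stats::filter(A * dt / cc, filter = 1 - kt * dt / cc,
                                method = "recursive"))
  (A - kt * c(0, B[-np])) / cc
}

#' Predict a protein trajectory with the discrete scheme
#'
#' Integrates the specific-activity balance `dPX/dt = Pmax - kt * PX` from
#' the induction time (with `PX(t_ind) = 0`) on a uniform grid of step `dt`,
#' using left-hand Riemann sums for both integrals; the current-step
#' self-inhibition contribution is absorbed implicitly, giving
#' `P_i = (sum_j Pmax_j dt - kt * sum_{j<i} PX_j dt) * X_i / (1 + dt * kt)`.
#' Protein is zero before induction. Per-sample predictions are linearly
#' interpolated from the grid.
#'
#' @param exp An [experiment_record()].
#' @param model A `model_spec`.
#' @param params Named coefficient vector; `k_t` is read from it when the
#'   model frees `k_t`.
#' @param dt Grid step (hours), default 0.01.
#' @param window Smoothing span passed to [compute_sgr()].
#' @return A list of class `prediction_set` with elements `t` (grid), `P`,
#'   `PX`, `pred` (per-sample predictions aligned to `exp$samples`), and the
#'   induction snapshot `ind`.
#' @examples
#' tt <- seq(0, 10, by = 0.01)
#' rec <- experiment_record("e1", 1, growth_curve(tt, 0.5 * exp(0.3 * tt)),
#'                          t_ind = 4, protein_samples(c(6, 8), c(0.1, 0.2)))
#' pr <- predict_protein(rec, pmax_model("eq33"), param_vector(k0 = 0.01))
#' @export
predict_protein <- function(exp, model, params, dt = 0.01, window = 1L) {
  if (!inherits(exp, "experiment_record"))
    pmaxsel_stop("`exp` must be an experiment_record")
  if (!is_number(dt) || dt <= 0) pmaxsel_stop("`dt` must be positive")
  prep <- prep_experiment(exp, dt = dt, window = window)
  predict_prepped(prep, model, as_param_vector(params))
}

predict_prepped <- function(prep, model, params) {
  pm <- evaluate_pmax(model, params, prep$state)
  kt <- model_kt(model, params)
  PX <- scheme_px(pm, kt, prep$dt)
  P <- PX * prep$state$X
  pred <- numeric(length(prep$t_s))
  after <- prep$t_s >= prep$tg[1]
  if (any(after))
    pred[after] <- approx(prep$tg, P, xout = prep$t_s[after])$y
  structure(list(t = prep$tg, P = P, PX = PX, pred = pred, ind = prep$ind),
            class = "prediction_set")
}

#' Residual sum of squares
#'
#' `RSS = sum((y_i - pred_i)^2)` over the samples of one experiment (or any
#' prediction/observation pair).
#'
#' @param preds A `prediction_set` from [predict_protein()], or a numeric
#'   vector of per-sample predictions.
#' @param samples A [protein_samples()] data frame (or any list with `y`).
#' @return Scalar RSS (>= 0).
#' @export
residuals_rss <- function(preds, samples) {
  p <- if (inherits(preds, "prediction_set")) preds$pred else preds
  if (length(p) != length(samples$y))
    pmaxsel_stop("every sample needs exactly one prediction")
  sum((samples$y - p)^2)
}

#' Pooled two-site residual sum of squares
#'
#' Normalised pooling of the two per-site RSS values so that each site's
#' average variance contributes evenly regardless of its sample count:
#' `RSS = (n2 * rss1 + n1 * rss2) / (n1 + n2)`.
#'
#' @param rss_site1,rss_site2 Per-site residual sums of squares.
#' @param n1,n2 Per-site sample counts (positive).
#' @return Scalar pooled RSS.
#' @examples
#' pooled_rss(2, 1, 196, 131) # 458/327
#' @export
pooled_rss <- function(rss_site1, rss_site2, n1, n2) {
  if (!is_number(n1) || !is_number(n2) || n1 <= 0 || n2 <= 0)
    pmaxsel_stop("sample counts `n1`, `n2` must be positive")
  (n2 * rss_site1 + n1 * rss_site2) / (n1 + n2)
}

#' Mean absolute error
#'
#' @inheritParams residuals_rss
#' @return Scalar MAE over the samples.
#' @export
mae_error <- function(preds, samples) {
  p <- if (inherits(preds, "prediction_set")) preds$pred else preds
  if (length(p) != length(samples$y))
    pmaxsel_stop("every sample needs exactly one prediction")
  mean(abs(samples$y - p))
}

#' Relative-entropy fitting objective
#'
#' Total log-likelihood of the predictions under the simplified
#' relative-entropy objective with trade-off coefficient `kexp` in
#' `[0, 2]`, which blends a relative (percentage-type) error term with an
#' absolute squared-error term. Two functional forms are provided:
#'
#' * `"as_printed"`: `L = sum(-e^2 * (1 - kexp) / (2 y^2) - e^2 * kexp / 2)`;
#' * `"consistent"`: `L = sum(-e^2 * (2 - kexp) / (2 y^2) - e^2 * kexp / 2)`,
#'
#' with `e_i = pred_i - y_i`. The consistent form reduces exactly to
#' `-RSS` at `kexp = 2`, so maximising it there is equivalent to ordinary
#' least squares; it is the package default. A zero observation is rejected
#' whenever the relative term is active.
#'
#' @inheritParams residuals_rss
#' @param kexp Trade-off coefficient in `[0, 2]`, default 2.
#' @param variant `"consistent"` (default) or `"as_printed"`.
#' @return Scalar total log-likelihood (0 for a perfect fit, negative
#'   otherwise).
#' @export
entropy_objective <- function(preds, samples, kexp = 2,
                              variant = c("consistent", "as_printed")) {
  variant <- match.arg(variant)
  p <- if (inherits(preds, "prediction_set")) preds$pred else preds
  if (length(p) != length(samples$y))
    pmaxsel_stop("every sample needs exactly one prediction")
  if (!is_number(kexp) || kexp < 0 || kexp > 2)
    pmaxsel_stop("`kexp` must lie in [0, 2]")
  y <- samples$y
  e <- p - y
  rel_coef <- if (variant == "as_printed") 1 - kexp else 2 - kexp
  if (abs(rel_coef) > 0 && any(y == 0))
    pmaxsel_stop("zero observations are incompatible with an active relative error term")
  rel <- if (abs(rel_coef) > 0) -e^2 * rel_coef / (2 * y^2) else 0
  sum(rel - e^2 * kexp / 2)
}

#' Reference integration of the specific-activity balance
#'
#' Integrates `dPX/dt = Pmax(t) - kt * PX` from induction with a classical
#' fixed-step Runge-Kutta solver (via \pkg{deSolve}), independent of the
#' discrete left-Riemann scheme of [predict_protein()]. Used as the
#' generating oracle for synthetic data and as the convergence reference in
#' tests.
#'
#' @param times Numeric time grid starting at the induction time (hours).
#' @param pmax_fun Function of time returning Pmax.
#' @param kt Self-inhibition constant (1/h).
#' @param X Optional biomass values on `times`; when supplied, the returned
#'   list gains `P = PX * X`.
#' @return List with `t`, `PX` and (optionally) `P`.
#' @export
integrate_protein_ode <- function(times, pmax_fun, kt, X = NULL) {
  if (length(times) < 2L) pmaxsel_stop("`times` must contain at least two points")
  sol <- deSolve::ode(
    y = c(PX = 0), times = times,
    func = function(t, y, parms) list(pmax_fun(t) - kt * y[1]),
    parms = NULL, method = "rk4")
  PX <- as.numeric(sol[, "PX"])
  out <- list(t = times, PX = PX)
  if (!is.null(X)) {
    if (length(X) != length(times)) pmaxsel_stop("`X` must align with `times`")
    out$P <- PX * X
  }
  out
}
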