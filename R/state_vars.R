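## Physiological state variables derived from a biomass trajectory:
## specific growth rate mu(t) = d(ln X)/dt and the biomass-increment-weighted
## average cell age. Both feed the Pmax candidate models.

#' Construct a biomass growth curve
#'
#' A growth curve holds one fed-batch biomass trajectory: a strictly
#' increasing time grid `t` (hours), positive biomass concentrations `X`
#' (g/L) and the inoculation biomass `X0` (g/L). `X0` anchors the initial
#' boundary condition of the average-cell-age integral: cells present at
#' inoculation are assumed to have age zero at `t = 0`.
#'
#' @param t Numeric vector of times in hours, strictly increasing,
#'   `t[1] >= 0`, length at least 2.
#' @param X Numeric vector of biomass concentrations in g/L, all positive,
#'   same length as `t`.
#' @param X0 Biomass concentration at inoculation (g/L). Defaults to `X[1]`.
#' @return An object of class `growth_curve` (a list with elements `t`, `X`,
#'   `X0`).
#' @examples
#' tt <- seq(0, 8, by = 0.01)
#' gc <- growth_curve(tt, 0.2 * exp(0.4 * tt))
#' @export
growth_curve <- function(t, X, X0 = X[1]) {
  if (!is.numeric(t) || !is.numeric(X) || length(t) != length(X) || length(t) < 2L)
    pmaxsel_stop("`t` and `X` must be numeric vectors of equal length >= 2")
  if (anyNA(t) || anyNA(X)) pmaxsel_stop("growth curve contains missing values")
  if (t[1] < 0 || any(diff(t) <= 0))
    pmaxsel_stop("`t` must be strictly increasing with t[1] >= 0")
  if (any(X <= 0)) pmaxsel_stop("all biomass values `X` must be positive")
  if (!is_number(X0) || X0 <= 0) pmaxsel_stop("`X0` must be a positive number")
  structure(list(t = as.numeric(t), X = as.numeric(X), X0 = as.numeric(X0)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %d points, t in [%.3g, %.3g] h, X in [%.3g, %.3g] g/L (X0 = %.3g)\n",
              length(x$t), x$t[1], x$t[length(x$t)], min(x$X), max(x$X), x$X0))
  invisible(x)
}

stopifnot_curve <- function(curve) {
  if (!inherits(curve, "growth_curve"))
    pmaxsel_stop("expected a `growth_curve` object; see growth_curve()")
  invisible(curve)
}

#' Specific growth rate from a biomass trajectory
#'
#' Estimates the specific growth rate (SGR) `mu(t) = d(ln X)/dt` (1/h) by
#' finite differences of `log(X)`: symmetric differences at interior points,
#' one-sided at the ends. `window` widens the difference stencil, which
#' smooths measurement noise at the cost of resolution; the default uses the
#' immediate neighbours.
#'
#' @param curve A [growth_curve()].
#' @param window Odd positive integer smoothing span, `< length(curve$t)`.
#'   `window = 1` differences the immediate neighbours; larger (odd) values
#'   difference points `(window + 1) / 2` steps apart.
#' @return Numeric vector of `mu` values (1/h), one per grid point.
#' @examples
#' tt <- seq(0, 10, by = 0.01)
#' mu <- compute_sgr(growth_curve(tt, exp(0.2 * tt), X0 = 1))
#' range(mu[2:(length(mu) - 1)]) # ~0.2 throughout
#' @export
compute_sgr <- function(curve, window = 1L) {
  stopifnot_curve(curve)
  n <- length(curve$t)
  if (!is_number(window) || window < 1 || window %% 2 != 1 || window >= n)
    pmaxsel_stop("`window` must be an odd integer >= 1 and < length(t)")
  h <- (as.integer(window) + 1L) %/% 2L
  lx <- log(curve$X)
  i <- seq_len(n)
  ip <- pmin(n, i + h)
  im <- pmax(1L, i - h)
  (lx[ip] - lx[im]) / (curve$t[ip] - curve$t[im])
}

#' Average cell age along a biomass trajectory
#'
#' The average cell age at time `t_i` is the biomass-increment-weighted mean
#' elapsed time of the cells present at `t_i`, including the inoculation
#' boundary condition:
#' `age_i = (X0 * t_i + sum_j (t_i - t_j) * dX_j) / X_i`,
#' where `dX_j = X_j - X_{j-1}` are the discrete biomass increments (a jump
#' `X_1 - X0` at the first grid point is included when the recorded curve
#' does not start at `X0`). The age is a proxy for the physiologically
#' active fraction of the biomass.
#'
#' @inheritParams compute_sgr
#' @return Numeric vector of ages (hours), one per grid point.
#' @examples
#' tt <- seq(0, 4, by = 0.01)
#' age <- average_cell_age(growth_curve(tt, exp(0.5 * tt), X0 = 1))
#' age[length(age)] # close to (1 - exp(-2)) / 0.5 = 1.7293
#' @export
average_cell_age <- function(curve) {
  stopifnot_curve(curve)
  t <- curve$t
  X <- curve$X
  dX <- c(X[1] - curve$X0, diff(X))
  (curve$X0 * t + t * cumsum(dX) - cumsum(t * dX)) / X
}

#' State-variable series for a growth curve
#'
#' Convenience wrapper computing both [compute_sgr()] and
#' [average_cell_age()] on the curve grid.
#'
#' @inheritParams compute_sgr
#' @return A data frame of class `state_series` with columns `t`, `mu`,
#'   `age`.
#' @export
state_series <- function(curve, window = 1L) {
  stopifnot_curve(curve)
  out <- data.frame(t = curve$t,
                    mu = compute_sgr(curve, window = window),
                    age = average_cell_age(curve))
  class(out) <- c("state_series", class(out))
  out
}

#' Physiological state at the induction time
#'
#' Interpolates biomass, specific growth rate and average cell age to the
#' induction time `t_ind` (the IPTG addition that starts product
#' biosynthesis). Interpolation is linear in time.
#'
#' @inheritParams compute_sgr
#' @param states A [state_series()] computed from `curve`.
#' @param t_ind Induction time in hours, inside the span of `curve$t`.
#' @return A list of class `induction_state` with elements `t_ind`, `X_ind`,
#'   `mu_ind`, `age_ind`.
#' @export
induction_state <- function(curve, states, t_ind) {
  stopifnot_curve(curve)
  if (!is.data.frame(states) || !all(c("t", "mu", "age") %in% names(states)))
    pmaxsel_stop("`states` must be a state_series data frame with t, mu, age")
  n <- length(curve$t)
  if (!is_number(t_ind) || t_ind < curve$t[1] || t_ind > curve$t[n])
    pmaxsel_stop(sprintf(
      "induction time t_ind = %s lies outside the trajectory span [%g, %g] h",
      format(t_ind), curve$t[1], curve$t[n]))
  structure(list(
    t_ind = t_ind,
    X_ind = approx(curve$t, curve$X, xout = t_ind)$y,
    mu_ind = approx(states$t, states$mu, xout = t_ind)$y,
    age_ind = approx(states$t, states$age, xout = t_ind)$y
  ), class = "induction_state")
}

#' Oxygen-uptake-rate model parameters
#'
#' Parameters of the forward oxygen uptake rate estimator
#' `OUR(t) = alpha * X'(t) + kgamma * (X(t) - X_ind) * dP/dt`:
#' `alpha` is the oxygen consumption yield for biomass growth (g O2 / g X)
#' and `kgamma` links oxygen consumption to the protein synthesis rate,
#' scaled by the biomass accumulated since induction.
#'
#' @param alpha Oxygen yield for growth (g O2 / g X).
#' @param kgamma Product-linked oxygen yield coefficient.
#' @return A list of class `our_params`.
#' @export
our_params <- function(alpha, kgamma) {
  if (!is_number(alpha) || !is_number(kgamma))
    pmaxsel_stop("`alpha` and `kgamma` must be finite numbers")
  structure(list(alpha = alpha, kgamma = kgamma), class = "our_params")
}

#' Forward oxygen uptake rate
#'
#' Evaluates the forward OUR estimator along a trajectory, given the protein
#' concentration series on the same grid. Derivatives use forward
#' differences (backward at the final point); this operation exists to
#' equip synthetic datasets with a realistic OUR channel, so mild derivative
#' accuracy suffices.
#'
#' @inheritParams compute_sgr
#' @param protein Numeric vector of protein concentrations aligned to
#'   `curve$t`.
#' @param params An [our_params()] object.
#' @param X_ind Biomass concentration at induction (g/L).
#' @return Numeric vector of OUR values on the curve grid.
#' @export
our_forward <- function(curve, protein, params, X_ind) {
  stopifnot_curve(curve)
  if (!inherits(params, "our_params")) pmaxsel_stop("`params` must be our_params()")
  n <- length(curve$t)
  if (!is.numeric(protein) || length(protein) != n)
    pmaxsel_stop("`protein` must be numeric and aligned to the curve grid")
  if (!is_number(X_ind)) pmaxsel_stop("`X_ind` must be a finite number")
  fwd <- function(y) {
    d <- diff(y) / diff(curve$t)
    c(d, d[n - 1L])
  }
  params$alpha * fwd(curve$X) +
    params$kgamma * (curve$X - X_ind) * fwd(protein)
}
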