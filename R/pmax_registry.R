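## Registry of the additive Pmax terms of the combined 24-coefficient model.
## Each term couples one lead coefficient (k0..k22) to a product of state
## variables; Monod-type terms carry an additional half-saturation
## coefficient in their denominator, and the substrate-inhibition term a
## Haldane-type denominator. Every symbol k0..k22 appears in exactly one
## term.

PMAX_EPS <- 1e-8

## guard a rational denominator; fitted half-saturation constants may be
## negative, so the denominator can cross zero anywhere along a trajectory
check_den <- function(den, term_id) {
  if (any(abs(den) < PMAX_EPS, na.rm = TRUE) || anyNA(den))
    domain_stop(sprintf(
      "singular denominator (|den| < %g) in Pmax term '%s'", PMAX_EPS, term_id))
  ## a sign change along the evaluation grid means the singularity sits
  ## between two grid points -- just as pathological as hitting it
  if (length(den) > 1L && any(den > 0) && any(den < 0))
    domain_stop(sprintf(
      "denominator of Pmax term '%s' changes sign along the trajectory", term_id))
  den
}

new_term <- function(term_id, coeffs, state_vars, form, fn, dens = character()) {
  structure(list(term_id = term_id, coeffs = coeffs, dens = dens,
                 state_vars = state_vars, form = form, fn = fn),
            class = "pmax_term")
}

#' Registry of additive Pmax model terms
#'
#' Returns the full library of additive terms of the combined
#' maximal-product-formation-rate model. The lead coefficients are
#' `k0 ... k22`; Monod-type terms additionally own their half-saturation
#' symbol (listed in `dens`). State variables are the running specific
#' growth rate `mu` (1/h), running average cell age `age` (h), biomass `X`
#' (g/L), and their induction-time snapshots `mu_ind`, `age_ind`, `X_ind`.
#'
#' @return A named list of `pmax_term` objects. Each term has fields
#'   `term_id`, `coeffs` (all coefficient symbols it owns), `dens`
#'   (denominator symbols, empty for linear terms), `state_vars`, `form`
#'   (`"linear"` or `"rational"`) and `fn(params, state)`.
#' @examples
#' reg <- pmax_registry()
#' names(reg)
#' reg$age_lin$coeffs # "k8"
#' @export
pmax_registry <- function() {
  list(
    mu_ind_lin = new_term("mu_ind_lin", "k0", "mu_ind", "linear",
      function(p, s) p[["k0"]] * s$mu_ind),
    growth_excess_biomass = new_term("growth_excess_biomass", "k1",
      c("mu", "X", "X_ind"), "linear",
      function(p, s) p[["k1"]] * s$mu * (s$X - s$X_ind)),
    growth_age_ind = new_term("growth_age_ind", "k2", c("mu", "age_ind"), "linear",
      function(p, s) p[["k2"]] * s$mu * s$age_ind),
    growth_lin = new_term("growth_lin", "k3", "mu", "linear",
      function(p, s) p[["k3"]] * s$mu),
    growth_mu_ind_offset = new_term("growth_mu_ind_offset", c("k4", "k13"),
      c("mu", "mu_ind"), "linear",
      function(p, s) p[["k4"]] * s$mu * (p[["k13"]] + s$mu_ind)),
    biomass_ind = new_term("biomass_ind", "k6", "X_ind", "linear",
      function(p, s) p[["k6"]] * s$X_ind),
    biomass_ind_age = new_term("biomass_ind_age", "k7", c("X_ind", "age"), "linear",
      function(p, s) p[["k7"]] * s$X_ind * s$age),
    age_lin = new_term("age_lin", "k8", "age", "linear",
      function(p, s) p[["k8"]] * s$age),
    haldane_mu = new_term("haldane_mu", c("k9", "k14", "k15"), "mu", "rational",
      function(p, s) {
        ## k15 -> 0 sends the inhibition term to infinity and the whole
        ## ratio to zero; keep that limit (the all-zero start relies on it)
        inh <- if (abs(p[["k15"]]) < PMAX_EPS) Inf else s$mu^2 / p[["k15"]]
        den <- p[["k14"]] + s$mu + inh
        fin <- is.finite(den)
        if (any(fin)) check_den(den[fin], "haldane_mu")
        out <- p[["k9"]] * s$mu / den
        out[!fin] <- 0
        out
      },
      dens = c("k14", "k15")),
    age_ind_lin = new_term("age_ind_lin", "k10", "age_ind", "linear",
      function(p, s) p[["k10"]] * s$age_ind),
    mu_ind_age_ind = new_term("mu_ind_age_ind", "k11", c("mu_ind", "age_ind"),
      "linear",
      function(p, s) p[["k11"]] * s$mu_ind * s$age_ind),
    mu_ind_sq = new_term("mu_ind_sq", "k12", "mu_ind", "linear",
      function(p, s) p[["k12"]] * s$mu_ind^2),
    monod_mu_ind_age = new_term("monod_mu_ind_age", c("k16", "k20"),
      c("mu_ind", "age"), "rational",
      function(p, s) p[["k16"]] * s$mu_ind * s$age /
        check_den(p[["k20"]] + s$age, "monod_mu_ind_age"),
      dens = "k20"),
    monod_mu = new_term("monod_mu", c("k17", "k19"), "mu", "rational",
      function(p, s) p[["k17"]] * s$mu /
        check_den(p[["k19"]] + s$mu, "monod_mu"),
      dens = "k19"),
    monod_mu_age = new_term("monod_mu_age", c("k18", "k21"), c("mu", "age"),
      "rational",
      function(p, s) p[["k18"]] * s$mu * s$age /
        check_den(p[["k21"]] + s$age, "monod_mu_age"),
      dens = "k21"),
    monod_mu_age_ind = new_term("monod_mu_age_ind", c("k22", "k5"),
      c("mu", "age_ind"), "rational",
      function(p, s) p[["k22"]] * s$mu * s$age_ind /
        check_den(p[["k5"]] + s$age_ind, "monod_mu_age_ind"),
      dens = "k5")
  )
}

## all coefficient symbols a ParamVector may carry
PARAM_SYMBOLS <- c("k_t", paste0("k", 0:22), paste0("a", 1:4),
                   "km0", "km1", "kmu", "kimu")

#' Coefficient vector for Pmax models
#'
#' Builds a named coefficient vector over the full symbol set
#' (`k_t`, `k0 ... k22`, trapezoid breakpoints `a1 ... a4`, and the
#' historical aliases `km0`, `km1`, `kmu`, `kimu`), defaulting every symbol
#' to zero -- the conventional starting point of the convex search.
#'
#' @param ... Named numeric scalars, e.g. `param_vector(k16 = 0.003, k20 = 1.3)`.
#' @return A named numeric vector covering all symbols.
#' @export
param_vector <- function(...) {
  vals <- c(...)
  out <- setNames(numeric(length(PARAM_SYMBOLS)), PARAM_SYMBOLS)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals))))
      pmaxsel_stop("all coefficients passed to param_vector() must be named")
    bad <- setdiff(names(vals), PARAM_SYMBOLS)
    if (length(bad))
      pmaxsel_stop(paste0("unknown coefficient symbol(s): ",
                          paste(bad, collapse = ", ")))
    out[names(vals)] <- vals
  }
  out
}

## complete a possibly partial named vector to the full symbol set
as_param_vector <- function(params) {
  if (is.null(params)) return(param_vector())
  if (!is.numeric(params) || is.null(names(params)))
    pmaxsel_stop("`params` must be a named numeric vector; see param_vector()")
  do.call(param_vector, as.list(params))
}
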