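## Candidate Pmax model specifications: registry subsets, named presets
## (reduced combined-model variants and the historical 1999/2003/2019
## models), and their evaluation at a physiological state.

#' Physiological state for Pmax evaluation
#'
#' Bundles the running state variables (vectors over a time grid) and the
#' induction-time snapshot (scalars) at which a Pmax model is evaluated.
#'
#' @param mu,age,X Numeric vectors (equal length): specific growth rate
#'   (1/h), average cell age (h) and biomass (g/L) along the grid.
#' @param mu_ind,age_ind,X_ind Scalars: the same quantities at induction.
#' @return A list of class `pmax_state`.
#' @export
pmax_state <- function(mu, age, X, mu_ind, age_ind, X_ind) {
  n <- length(mu)
  if (length(age) != n || length(X) != n)
    pmaxsel_stop("`mu`, `age`, `X` must have equal length")
  if (!is_number(mu_ind) || !is_number(age_ind) || !is_number(X_ind))
    pmaxsel_stop("induction snapshot values must be finite scalars")
  structure(list(mu = mu, age = age, X = X,
                 mu_ind = mu_ind, age_ind = age_ind, X_ind = X_ind),
            class = "pmax_state")
}

new_model_spec <- function(name, free, kt_free, terms = NULL, eval_fn = NULL,
                           kt_fixed = 0) {
  k <- length(free) + as.integer(kt_free)
  structure(list(name = name, free = free, kt_free = kt_free,
                 kt_fixed = kt_fixed, terms = terms, eval_fn = eval_fn, k = k),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: k = %d (%s%s)\n", x$name, x$k,
              paste(x$free, collapse = ", "),
              if (x$kt_free) " + k_t" else ""))
  invisible(x)
}

## shared Monod building block of the reduced combined-model variants
monod_ind_age <- function(p, s) {
  s$mu_ind * s$age / check_den(p[["k20"]] + s$age, "monod_mu_ind_age")
}

preset_defs <- function() {
  list(
    ## reduced combined-model variants retained at kmax = 33; the
    ## "+ k16 - k16*mu" tails share the single symbol k16 with the Monod term
    eq29 = new_model_spec("eq29", c("k0", "k16", "k20"), FALSE,
      eval_fn = function(p, s)
        p[["k0"]] * (s$mu_ind - s$mu_ind^2) +
          p[["k16"]] * (monod_ind_age(p, s) + 1 - s$mu)),
    eq30 = new_model_spec("eq30", c("k0", "k16", "k20"), FALSE,
      eval_fn = function(p, s)
        p[["k0"]] * s$mu_ind + p[["k16"]] * (monod_ind_age(p, s) + 1 - s$mu)),
    eq31 = new_model_spec("eq31", c("k0", "k16", "k20"), FALSE,
      eval_fn = function(p, s)
        p[["k0"]] * s$mu_ind + p[["k16"]] * (monod_ind_age(p, s) + 1)),
    eq32 = new_model_spec("eq32", c("k16", "k20"), FALSE,
      eval_fn = function(p, s) p[["k16"]] * (monod_ind_age(p, s) + 1)),
    ## alternatives retained at kmax = 6
    eq33 = new_model_spec("eq33", "k0", FALSE,
      eval_fn = function(p, s) p[["k0"]] * s$mu_ind),
    eq34 = new_model_spec("eq34", "k8", FALSE,
      eval_fn = function(p, s) p[["k8"]] * s$age),
    eq35 = new_model_spec("eq35", c("k16", "k20"), FALSE,
      eval_fn = function(p, s)
        p[["k16"]] * (monod_ind_age(p, s) + 1 - s$mu)),
    eq36 = new_model_spec("eq36", "k0", TRUE,
      eval_fn = function(p, s) p[["k0"]] * s$mu_ind),
    eq37 = new_model_spec("eq37", "k8", TRUE,
      eval_fn = function(p, s) p[["k8"]] * s$age),
    ## growth-linked model with biomass accumulated since induction
    eq38 = new_model_spec("eq38", c("k1", "k3"), TRUE,
      eval_fn = function(p, s)
        s$mu * (p[["k1"]] * (s$X - s$X_ind) + p[["k3"]])),
    ## historical models in their combined-model coefficient aliases
    m1999 = new_model_spec("m1999", "k8", TRUE,
      eval_fn = function(p, s) p[["k8"]] * s$age),
    m2003 = new_model_spec("m2003", c("k9", "k14", "k15"), TRUE,
      terms = "haldane_mu"),
    m2019 = new_model_spec("m2019", c("k1", "k3"), TRUE,
      eval_fn = function(p, s)
        s$mu * (p[["k1"]] * (s$X - s$X_ind) + p[["k3"]])),
    null = new_model_spec("null", character(), FALSE,
      eval_fn = function(p, s) rep(0, length(s$mu)))
  )
}

#' Named Pmax model presets
#'
#' Retrieves a candidate model by name. `eq29 ... eq38` are the reduced
#' variants of the combined model (the shortlists retained at `kmax = 33`
#' and `kmax = 6`); `m1999` (age-proportional), `m2003` (substrate-type
#' growth inhibition) and `m2019` (induction-biomass growth model) are the
#' historical models expressed through combined-model coefficients;
#' `full2021` activates every registry term plus `k_t`; `null` has no free
#' coefficients (`Pmax == 0`).
#'
#' @param name One of `"eq29" ... "eq38"`, `"m1999"`, `"m2003"`, `"m2019"`,
#'   `"full2021"`, `"null"`.
#' @return A `model_spec` object with fields `name`, `free` (free
#'   coefficient symbols), `kt_free`, `k` (total free coefficient count,
#'   including `k_t` when free).
#' @examples
#' pmax_model("eq32") # k16 * (mu_ind * age / (k20 + age) + 1), kt = 0
#' @export
pmax_model <- function(name) {
  defs <- preset_defs()
  if (identical(name, "full2021")) {
    reg <- pmax_registry()
    return(new_model_spec("full2021",
                          unlist(lapply(reg, `[[`, "coeffs"), use.names = FALSE),
                          TRUE, terms = names(reg)))
  }
  if (!name %in% names(defs))
    pmaxsel_stop(paste0("unknown model preset '", name, "'; available: ",
                        paste(c(names(defs), "full2021"), collapse = ", ")))
  defs[[name]]
}

#' Pmax model from a set of registry terms
#'
#' Assembles a candidate model as an additive subset of [pmax_registry()]
#' terms, optionally freeing the self-inhibition constant `k_t`.
#'
#' @param term_ids Character vector of registry term ids.
#' @param kt_free Should `k_t` be a free coefficient?
#' @param name Model name; defaults to the sorted term ids joined by `+`.
#' @return A `model_spec`.
#' @export
model_from_terms <- function(term_ids, kt_free = FALSE, name = NULL) {
  reg <- pmax_registry()
  bad <- setdiff(term_ids, names(reg))
  if (length(bad))
    pmaxsel_stop(paste0("unknown registry term(s): ", paste(bad, collapse = ", ")))
  term_ids <- names(reg)[names(reg) %in% term_ids] # registry order, de-duplicated
  free <- unlist(lapply(reg[term_ids], `[[`, "coeffs"), use.names = FALSE)
  if (is.null(name))
    name <- paste0(paste(term_ids, collapse = "+"), if (kt_free) "+kt" else "")
  new_model_spec(name, free, kt_free, terms = term_ids)
}

#' Evaluate a Pmax model at a physiological state
#'
#' Sums the model's active terms at the supplied state. Rational terms whose
#' denominator passes within `1e-8` of zero raise a condition of class
#' `pmaxsel_domain_error` naming the term; the calibration layer converts
#' this into a finite objective penalty.
#'
#' @param model A `model_spec` from [pmax_model()], [model_from_terms()] or
#'   [enumerate_candidates()].
#' @param params Named coefficient vector (see [param_vector()]); missing
#'   symbols default to zero.
#' @param state A [pmax_state()].
#' @return Numeric vector of Pmax values (same units as `dPX/dt`, e.g.
#'   U/g/h), one per state grid point.
#' @examples
#' s <- pmax_state(mu = 0.2, age = 2, X = 10,
#'                 mu_ind = 0.4, age_ind = 1.5, X_ind = 8)
#' evaluate_pmax(pmax_model("eq32"), param_vector(k16 = 0.00298, k20 = -1.302), s)
#' @export
evaluate_pmax <- function(model, params, state) {
  if (!inherits(model, "model_spec")) pmaxsel_stop("`model` must be a model_spec")
  if (!inherits(state, "pmax_state")) pmaxsel_stop("`state` must be a pmax_state")
  p <- as_param_vector(params)
  out <- rep(0, length(state$mu))
  if (!is.null(model$eval_fn)) out <- out + model$eval_fn(p, state)
  if (!is.null(model$terms)) {
    reg <- pmax_registry()
    for (id in model$terms) out <- out + reg[[id]]$fn(p, state)
  }
  out
}

## kt actually used by a model given a parameter vector
model_kt <- function(model, params) {
  if (model$kt_free) as_param_vector(params)[["k_t"]] else model$kt_fixed
}

#' Trapezoid relative-activity function
#'
#' The 1999 active-biomass model weighs each biomass increment by a relative
#' activity ratio `m` in `[0, 1]` that depends on the increment's elapsed
#' age: zero below `a1`, rising linearly to 1 on `[a1, a2]`, flat at 1 on
#' `[a2, a3]`, falling linearly to 0 on `[a3, a4]`, zero above `a4`.
#'
#' @param act List or vector with breakpoints `a1 <= a2 <= a3 <= a4` (hours).
#' @param age_elapsed Numeric vector of elapsed ages (hours).
#' @return Numeric vector of activities in `[0, 1]`.
#' @export
trapezoid_activity <- function(act, age_elapsed) {
  a <- unlist(act)[c("a1", "a2", "a3", "a4")]
  if (anyNA(a)) pmaxsel_stop("`act` must provide a1, a2, a3, a4")
  if (is.unsorted(a)) pmaxsel_stop("trapezoid breakpoints must satisfy a1 <= a2 <= a3 <= a4")
  x <- age_elapsed
  m <- numeric(length(x))
  m[x >= a[2] & x <= a[3]] <- 1
  ramp_up <- x > a[1] & x < a[2]
  m[ramp_up] <- (x[ramp_up] - a[1]) / (a[2] - a[1])
  ramp_dn <- x > a[3] & x < a[4]
  m[ramp_dn] <- (a[4] - x[ramp_dn]) / (a[4] - a[3])
  m
}

#' Active-biomass Pmax (1999 trapezoid model)
#'
#' Evaluates the 1999 active-biomass production rate at a grid time `t_i`:
#' each biomass increment is weighted by its trapezoid activity at its
#' elapsed age, and the weighted sum is normalised by the current biomass:
#' `Pmax(t_i) = (1 / X_i) * sum_j dX_j * m(t_i - t_j)`.
#'
#' @inheritParams compute_sgr
#' @param act Trapezoid breakpoints, see [trapezoid_activity()].
#' @param t_i A time on the curve grid (hours).
#' @return Scalar production rate.
#' @export
pmax_1999 <- function(curve, act, t_i) {
  stopifnot_curve(curve)
  i <- which(abs(curve$t - t_i) < 1e-9)
  if (length(i) != 1L)
    pmaxsel_stop("`t_i` must coincide with a point of the curve grid")
  dX <- c(curve$X[1] - curve$X0, diff(curve$X))[seq_len(i)]
  m <- trapezoid_activity(act, t_i - curve$t[seq_len(i)])
  sum(dX * m) / curve$X[i]
}

#' Enumerate candidate Pmax models up to a complexity cap
#'
#' Lists every additive subset of registry terms whose total free
#' coefficient count is at most `k_cap`, in a deterministic order (subsets
#' of increasing size, lexicographic in registry order). With
#' `include_kt = TRUE`, each subset still within the cap after adding `k_t`
#' is duplicated with `k_t` free, and the `k_t`-only model (`Pmax == 0`) is
#' prepended. The named presets `eq29 ... eq38` are always appended.
#'
#' @param registry Term registry, defaults to [pmax_registry()].
#' @param k_cap Maximum total number of free coefficients (>= 1).
#' @param include_kt Also enumerate variants with `k_t` free.
#' @return A list of `model_spec` objects, duplicate-free and stable across
#'   runs.
#' @export
enumerate_candidates <- function(registry = pmax_registry(), k_cap = 6L,
                                 include_kt = FALSE) {
  if (!is_number(k_cap) || k_cap < 1) pmaxsel_stop("`k_cap` must be >= 1")
  costs <- vapply(registry, function(tm) length(tm$coeffs), integer(1))
  ids <- names(registry)
  n <- length(ids)
  subsets <- list()
  recurse <- function(start, chosen, cost) {
    if (length(chosen)) subsets[[length(subsets) + 1L]] <<- chosen
    if (start > n) return()
    for (j in start:n) {
      if (cost + costs[j] <= k_cap) recurse(j + 1L, c(chosen, j), cost + costs[j])
    }
  }
  recurse(1L, integer(), 0L)
  ## stable order: by subset size, then lexicographic on term indices
  keys <- vapply(subsets, function(s) paste(sprintf("%02d", s), collapse = ""),
                 character(1))
  ord <- order(lengths(subsets), keys)
  subsets <- subsets[ord]

  out <- list()
  if (include_kt)
    out[[length(out) + 1L]] <- new_model_spec("kt_only", character(), TRUE,
                                              eval_fn = function(p, s)
                                                rep(0, length(s$mu)))
  for (s in subsets) {
    base <- model_from_terms(ids[s], kt_free = FALSE)
    out[[length(out) + 1L]] <- base
    if (include_kt && sum(costs[s]) + 1L <= k_cap)
      out[[length(out) + 1L]] <- model_from_terms(ids[s], kt_free = TRUE)
  }
  presets <- paste0("eq", 29:38)
  for (nm in presets) out[[length(out) + 1L]] <- pmax_model(nm)
  out
}
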