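## Pseudo-global calibration: one set of coefficients fitted simultaneously
## across every experiment of both sites, by multi-start derivative-free
## local search on the (negated) relative-entropy objective. Site sums are
## pooled with the normalised two-site weighting, so at the default
## kexp = 2 the objective is exactly the pooled RSS.

#' Calibration options
#'
#' @param kexp,variant Passed to [entropy_objective()]; the defaults
#'   (`kexp = 2`, consistent form) make the objective the pooled RSS.
#' @param n_starts Number of optimisation starts (>= 1). The first start is
#'   the all-zero coefficient vector; the remainder are seeded Gaussian
#'   perturbations of it.
#' @param perturb Standard deviation of the start perturbations, per
#'   coefficient.
#' @param maxit Iteration cap per Nelder-Mead run.
#' @param reltol Relative convergence tolerance of each run.
#' @param dt Prediction grid step (hours) used during fitting.
#' @param window SGR smoothing span, see [compute_sgr()].
#' @param seed Integer seed; fixing it makes the fit fully deterministic.
#' @param polish Number of restarts of the simplex from its own optimum
#'   (each restart re-expands the simplex, sharpening convergence).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(kexp = 2, variant = "consistent", n_starts = 3L,
                        perturb = 0.01, maxit = 1000L, reltol = 1e-10,
                        dt = 0.02, window = 1L, seed = 1L, polish = 2L) {
  if (n_starts < 1) pmaxsel_stop("`n_starts` must be >= 1")
  structure(list(kexp = kexp, variant = variant, n_starts = as.integer(n_starts),
                 perturb = perturb, maxit = as.integer(maxit), reltol = reltol,
                 dt = dt, window = window, seed = as.integer(seed),
                 polish = as.integer(polish)),
            class = "fit_options")
}

PENALTY <- 1e12

## negated, site-pooled entropy objective over prepped experiments;
## domain errors (singular denominators) become a finite penalty so the
## simplex can retreat from them
dataset_objective <- function(par, free, model, preps, sites, opts) {
  params <- param_vector()
  params[free] <- par
  tot <- c(`1` = 0, `2` = 0)
  ok <- tryCatch({
    for (pr in preps) {
      ps <- predict_prepped(pr, model, params)
      ll <- entropy_objective(ps$pred, pr$exp$samples,
                              kexp = opts$kexp, variant = opts$variant)
      tot[[as.character(pr$exp$site)]] <- tot[[as.character(pr$exp$site)]] - ll
    }
    TRUE
  }, pmaxsel_domain_error = function(e) FALSE)
  if (!ok) return(PENALTY)
  val <- if (all(sites$n > 0) && length(sites$n) == 2L)
    pooled_rss(tot[[1]], tot[[2]], sites$n[1], sites$n[2])
  else
    sum(tot)
  if (!is.finite(val)) PENALTY else val
}

site_counts <- function(dataset) {
  s <- vapply(dataset, `[[`, integer(1), "site")
  n <- vapply(dataset, function(e) nrow(e$samples), integer(1))
  list(site = c(1L, 2L), n = c(sum(n[s == 1L]), sum(n[s == 2L])))
}

#' Pseudo-global fit of a Pmax model to a multi-experiment dataset
#'
#' Minimises the negated relative-entropy objective (the pooled RSS at the
#' default `kexp = 2`) over the model's free coefficients, simultaneously
#' across every experiment of the dataset. Each start runs a Nelder-Mead
#' simplex (restarted from its own optimum `opts$polish` times); the best
#' start wins, ties going to the lowest start index. Rational-term domain
#' errors are mapped to a large finite penalty. The all-zero start makes the
#' fitted objective never worse than the null model.
#'
#' @param dataset List of [experiment_record()]s (one or both sites).
#' @param model A `model_spec`.
#' @param opts A [fit_options()].
#' @return A list of class `fit_result`: `model`, `params` (full coefficient
#'   vector), `rss_site1`, `rss_site2`, `rss_pooled`, `mae`, `objective`,
#'   `k`, `n1`, `n2`, `converged`, `n_evals`, `start_used`.
#' @export
fit_model <- function(dataset, model, opts = fit_options()) {
  if (!length(dataset)) pmaxsel_stop("`dataset` must contain at least one experiment")
  if (!inherits(model, "model_spec")) pmaxsel_stop("`model` must be a model_spec")
  free <- c(model$free, if (model$kt_free) "k_t")
  preps <- lapply(dataset, prep_experiment, dt = opts$dt, window = opts$window)
  sites <- site_counts(dataset)
  obj <- function(par) dataset_objective(par, free, model, preps, sites, opts)

  n_evals <- 0L
  obj_counted <- function(par) { n_evals <<- n_evals + 1L; obj(par) }

  if (length(free) == 0L) {
    best <- list(par = numeric(0), value = obj(numeric(0)), conv = TRUE, start = 0L)
  } else {
    set.seed(opts$seed)
    starts <- c(list(numeric(length(free))),
                if (opts$n_starts > 1L)
                  lapply(seq_len(opts$n_starts - 1L), function(i)
                    rnorm(length(free), sd = opts$perturb)))
    best <- NULL
    for (i in seq_along(starts)) {
      par <- starts[[i]]
      value <- Inf
      conv <- FALSE
      for (rep in seq_len(1L + opts$polish)) {
        res <- suppressWarnings(optim(
          par, obj_counted, method = "Nelder-Mead",
          control = list(maxit = opts$maxit, reltol = opts$reltol)))
        par <- res$par; value <- res$value; conv <- res$convergence == 0
      }
      if (is.null(best) || value < best$value)
        best <- list(par = par, value = value, conv = conv, start = i)
    }
  }

  params <- param_vector()
  params[free] <- best$par
  ## recompute the reported statistics at the returned coefficients
  rss <- c(`1` = 0, `2` = 0)
  abs_err <- numeric(0)
  for (pr in preps) {
    ps <- predict_prepped(pr, model, params)
    rss[[as.character(pr$exp$site)]] <-
      rss[[as.character(pr$exp$site)]] + residuals_rss(ps, pr$exp$samples)
    abs_err <- c(abs_err, abs(pr$exp$samples$y - ps$pred))
  }
  both <- all(sites$n > 0)
  structure(list(
    model = model$name, spec = model, params = params,
    rss_site1 = rss[[1]], rss_site2 = rss[[2]],
    rss_pooled = if (both) pooled_rss(rss[[1]], rss[[2]], sites$n[1], sites$n[2])
                 else sum(rss),
    mae = mean(abs_err), objective = best$value, k = model$k,
    n1 = sites$n[1], n2 = sites$n[2],
    converged = isTRUE(best$conv), n_evals = n_evals, start_used = best$start,
    opts = opts
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  free <- c(x$spec$free, if (x$spec$kt_free) "k_t")
  cat(sprintf("<fit_result> %s: pooled RSS = %.5g, MAE = %.4g, k = %d\n",
              x$model, x$rss_pooled, x$mae, x$k))
  if (length(free)) {
    cat("  coefficients:\n")
    for (nm in free) cat(sprintf("    %-5s = %.6g\n", nm, x$params[[nm]]))
  }
  invisible(x)
}

#' Singleton significance scan
#'
#' Fits every single-coefficient model: `k_t` alone (whose `Pmax == 0`
#' prediction is identically zero, so its RSS equals the null-model RSS),
#' and each registry coefficient alone with `k_t = 0` (coefficients of the
#' same term that are not being scanned are held at zero). Rows are ranked
#' by AIC. Denominator-only and offset-only coefficients carry no signal on
#' their own and fall back to the null RSS; they are reported as fitted.
#'
#' @inheritParams fit_model
#' @param registry Term registry, defaults to [pmax_registry()].
#' @return A data frame with one row per coefficient (plus `k_t`): `param`,
#'   `value`, `k`, `rss`, `aic`, `bic`, sorted by AIC.
#' @export
singleton_scan <- function(dataset, registry = pmax_registry(),
                           opts = fit_options()) {
  sites <- site_counts(dataset)
  n <- sum(sites$n)
  rows <- list()
  scan_one <- function(sym, model) {
    fit <- fit_model(dataset, model, opts)
    data.frame(param = sym,
               value = if (sym == "k_t") fit$params[["k_t"]] else fit$params[[sym]],
               k = 1L, rss = fit$rss_pooled,
               aic = aic(fit$rss_pooled, n, 1L),
               bic = bic(fit$rss_pooled, n, 1L))
  }
  rows[[1]] <- scan_one("k_t", new_model_spec("kt_only", character(), TRUE,
                                              eval_fn = function(p, s)
                                                rep(0, length(s$mu))))
  for (tm in registry) {
    for (sym in tm$coeffs) {
      mdl <- new_model_spec(paste0("single_", sym), sym, FALSE,
                            terms = tm$term_id)
      rows[[length(rows) + 1L]] <- scan_one(sym, mdl)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$aic, out$param), , drop = FALSE]
}
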