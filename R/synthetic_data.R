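## Two-site synthetic fed-batch study generator. Growth curves follow a
## batch phase at a sampled SGR followed by a feeding phase with an
## exponentially decaying SGR; induction fires when the average cell age
## first reaches a sampled target inside the configured range; protein is
## generated by a Runge-Kutta oracle integration of the specific-activity
## balance, deliberately independent of the discrete fitting scheme so that
## scheme errors remain detectable.

#' Site configuration for the synthetic study generator
#'
#' @param n_experiments Number of fed-batch experiments at the site.
#' @param n_samples Total number of offline protein samples at the site
#'   (allocated as evenly as possible across experiments, remainders
#'   assigned at random).
#' @param mu0_range Batch-phase specific growth rate range (1/h).
#' @param mu_decay Feeding-phase SGR decay rate (1/h): after `t_batch` the
#'   SGR decays as `mu0 * exp(-mu_decay * (t - t_batch))`.
#' @param t_batch Batch-phase duration (h).
#' @param X0_range Inoculation biomass range (g/L).
#' @param age_range Induction trigger: target average cell age range (h);
#'   induction fires when the age first reaches a target drawn uniformly
#'   from this range.
#' @param post_induction Production-phase duration after induction (h).
#' @param noise_sd Relative protein measurement noise (standard deviation).
#' @param noise_type `"multiplicative"` (sd relative to each sample) or
#'   `"additive_max"` (Gaussian with sd `noise_sd * max(P)` per experiment).
#' @param dt Simulation grid step (h).
#' @param t_max Horizon within which the induction age must be reached (h).
#' @param our Optional [our_params()]; when supplied each experiment gains a
#'   forward-simulated OUR channel.
#' @return A list of class `site_config`.
#' @export
site_config <- function(n_experiments, n_samples,
                        mu0_range = c(0.35, 0.55), mu_decay = 0.15,
                        t_batch = 2, X0_range = c(0.8, 1.5),
                        age_range = c(1.14, 3.105), post_induction = 6,
                        noise_sd = 0.02,
                        noise_type = c("multiplicative", "additive_max"),
                        dt = 0.01, t_max = 48, our = NULL) {
  noise_type <- match.arg(noise_type)
  if (n_experiments < 1) pmaxsel_stop("`n_experiments` must be >= 1")
  if (n_samples < n_experiments)
    pmaxsel_stop("infeasible allocation: `n_samples` must be >= `n_experiments`")
  if (diff(range(age_range)) < 0 || any(age_range <= 0))
    pmaxsel_stop("`age_range` must be positive and ordered")
  structure(list(n_experiments = as.integer(n_experiments),
                 n_samples = as.integer(n_samples),
                 mu0_range = mu0_range, mu_decay = mu_decay, t_batch = t_batch,
                 X0_range = X0_range, age_range = age_range,
                 post_induction = post_induction, noise_sd = noise_sd,
                 noise_type = noise_type, dt = dt, t_max = t_max, our = our),
            class = "site_config")
}

#' Ground-truth generating model
#'
#' @param model A `model_spec` used to generate protein trajectories.
#' @param params Named coefficient vector of the truth.
#' @param kt Self-inhibition constant of the truth (read from `params` for
#'   models that free `k_t`).
#' @return List of class `truth_spec`.
#' @export
truth_spec <- function(model = pmax_model("eq32"),
                       params = param_vector(k16 = 20, k20 = 1.3),
                       kt = NULL) {
  params <- as_param_vector(params)
  if (is.null(kt)) kt <- model_kt(model, params)
  structure(list(model = model, params = params, kt = kt), class = "truth_spec")
}

#' Two-site synthetic study configuration
#'
#' @param site1,site2 [site_config()]s; `site2 = NULL` gives a single-site
#'   study.
#' @param truth A [truth_spec()]; the default is the Monod age model with a
#'   positive half-saturation constant (`k16 = 20`, `k20 = +1.3`,
#'   `k_t = 0`). The positive `k20` keeps the denominator away from zero
#'   along any trajectory; the magnitude of `k16` yields specific
#'   activities of a few thousand U/g, typical of enzymatic assays.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return List of class `study_config`.
#' @export
study_config <- function(site1, site2 = NULL, truth = truth_spec(), seed = 1L) {
  if (!inherits(site1, "site_config")) pmaxsel_stop("`site1` must be a site_config")
  if (!is.null(site2) && !inherits(site2, "site_config"))
    pmaxsel_stop("`site2` must be a site_config or NULL")
  structure(list(site1 = site1, site2 = site2, truth = truth,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Benchmark-shaped two-site study
#'
#' The default study layout mirrors the dimensions of the two-site
#' industrial benchmark: 46 experiments with 196 protein samples at site 1
#' (induction ages within 1.14-3.105 h) and 24 experiments with 131 samples
#' at site 2 (1.237-2.985 h), 327 pooled samples in total.
#'
#' @inheritParams study_config
#' @param noise_sd Relative measurement noise applied at both sites.
#' @return A [study_config()].
#' @export
two_site_benchmark_study <- function(truth = truth_spec(), seed = 1L,
                                     noise_sd = 0.02) {
  study_config(
    site1 = site_config(46L, 196L, age_range = c(1.14, 3.105),
                        noise_sd = noise_sd),
    site2 = site_config(24L, 131L, age_range = c(1.237, 2.985),
                        noise_sd = noise_sd),
    truth = truth, seed = seed)
}

#' Simulate one fed-batch growth curve and its induction time
#'
#' Biomass grows exponentially at a sampled batch SGR, then under an
#' exponentially decaying SGR during feeding. The induction time is the
#' first grid time at which the average cell age reaches a target drawn
#' from `cfg$age_range`. Consumes the current RNG state.
#'
#' @param cfg A [site_config()].
#' @return List with `curve` (a [growth_curve()] truncated at
#'   `t_ind + post_induction`) and `t_ind` (hours).
#' @export
simulate_growth <- function(cfg) {
  if (!inherits(cfg, "site_config")) pmaxsel_stop("`cfg` must be a site_config")
  mu0 <- runif(1, cfg$mu0_range[1], cfg$mu0_range[2])
  X0 <- runif(1, cfg$X0_range[1], cfg$X0_range[2])
  target <- runif(1, cfg$age_range[1], cfg$age_range[2])
  t <- seq(0, cfg$t_max, by = cfg$dt)
  mu <- mu0 * ifelse(t <= cfg$t_batch, 1, exp(-cfg$mu_decay * (t - cfg$t_batch)))
  n <- length(t)
  X <- X0 * exp(c(0, cumsum(mu[-n] * cfg$dt)))
  curve <- growth_curve(t, X, X0 = X0)
  age <- average_cell_age(curve)
  hit <- which(age >= target)
  if (!length(hit))
    pmaxsel_stop(sprintf(
      "induction age target %.3g h not reached within t_max = %g h; widen `age_range` or `t_max`",
      target, cfg$t_max))
  it <- hit[1]
  iend <- min(n, it + as.integer(round(cfg$post_induction / cfg$dt)))
  list(curve = growth_curve(t[1:iend], X[1:iend], X0 = X0), t_ind = t[it])
}

#' Simulate one complete experiment
#'
#' Generates a growth curve, integrates the truth model's specific-activity
#' balance with the Runge-Kutta oracle ([integrate_protein_ode()]) from the
#' induction time, draws sample times after induction and applies
#' measurement noise (clipped at zero). Consumes the current RNG state.
#'
#' @inheritParams simulate_growth
#' @param truth A [truth_spec()].
#' @param id Experiment identifier.
#' @param site Site number (1 or 2).
#' @param n_samples Number of offline samples for this experiment.
#' @return An [experiment_record()].
#' @export
simulate_experiment <- function(cfg, truth = truth_spec(), id = "exp1",
                                site = 1L, n_samples = 5L) {
  if (!inherits(truth, "truth_spec")) pmaxsel_stop("`truth` must be a truth_spec")
  g <- simulate_growth(cfg)
  curve <- g$curve
  st <- state_series(curve)
  ind <- induction_state(curve, st, g$t_ind)
  n <- length(curve$t)
  it <- which(curve$t >= g$t_ind - 1e-9)[1]
  sub <- it:n
  state <- pmax_state(st$mu[sub], st$age[sub], curve$X[sub],
                      ind$mu_ind, ind$age_ind, ind$X_ind)
  pm <- evaluate_pmax(truth$model, truth$params, state)
  pmfun <- approxfun(curve$t[sub], pm, rule = 2)
  orc <- integrate_protein_ode(curve$t[sub], pmfun, truth$kt, X = curve$X[sub])
  t_end <- curve$t[n]
  t_s <- sort(runif(n_samples, min(g$t_ind + 0.25, t_end), t_end))
  y0 <- approx(orc$t, orc$P, xout = t_s)$y
  y <- switch(cfg$noise_type,
    multiplicative = y0 * (1 + rnorm(n_samples, sd = cfg$noise_sd)),
    additive_max = y0 + rnorm(n_samples, sd = cfg$noise_sd * max(orc$P)))
  y <- pmax(y, 0)
  our <- NULL
  if (!is.null(cfg$our)) {
    P_full <- numeric(n)
    P_full[sub] <- orc$P
    our <- our_forward(curve, P_full, cfg$our, ind$X_ind)
  }
  experiment_record(id, site, curve, g$t_ind, protein_samples(t_s, y), our = our)
}

allocate_samples <- function(n_total, n_exp) {
  base <- n_total %/% n_exp
  rem <- n_total %% n_exp
  counts <- rep(base, n_exp)
  if (rem > 0) {
    extra <- sample.int(n_exp, rem)
    counts[extra] <- counts[extra] + 1L
  }
  counts
}

#' Simulate a complete (one- or two-site) dataset
#'
#' Deterministic under `study$seed`; the per-site experiment counts and
#' total sample counts match the configuration exactly.
#'
#' @param study A [study_config()].
#' @return List of [experiment_record()]s.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(two_site_benchmark_study(seed = 7))
#' length(ds) # 70
#' sum(vapply(ds, function(e) nrow(e$samples), integer(1))) # 327
#' }
#' @export
simulate_dataset <- function(study) {
  if (!inherits(study, "study_config")) pmaxsel_stop("`study` must be a study_config")
  set.seed(study$seed)
  out <- list()
  for (site in 1:2) {
    cfg <- if (site == 1L) study$site1 else study$site2
    if (is.null(cfg)) next
    counts <- allocate_samples(cfg$n_samples, cfg$n_experiments)
    for (i in seq_len(cfg$n_experiments)) {
      out[[length(out) + 1L]] <- simulate_experiment(
        cfg, study$truth, id = sprintf("s%d_e%02d", site, i),
        site = site, n_samples = counts[i])
    }
  }
  out
}

#' Parameter-recovery and selection-rank report
#'
#' Runs replicated generate-and-refit studies: for each replicate the study
#' is re-simulated with seed `study$seed + replicate - 1`, the truth model
#' is refitted, and the recovered coefficients are compared with the truth.
#' When `candidates` are supplied, every candidate is fitted too and the
#' rank of the truth model under the entropic criterion is recorded.
#'
#' @param study A [study_config()].
#' @param n_replicates Number of replicates.
#' @param opts [fit_options()] used for every fit (its seed is offset per
#'   replicate).
#' @param candidates Optional list of `model_spec`s to rank against (the
#'   truth model is added if absent).
#' @param kmax Entropic tuning coefficient used for ranking.
#' @param file Optional path; when given the report is also written as CSV.
#' @return Data frame with one row per replicate: recovered coefficient
#'   values, their relative errors, the pooled RSS, and (with candidates)
#'   `rank_true`.
#' @export
recovery_report <- function(study, n_replicates = 5L, opts = fit_options(),
                            candidates = NULL, kmax = 6L, file = NULL) {
  truth <- study$truth
  free <- c(truth$model$free, if (truth$model$kt_free) "k_t")
  if (!is.null(candidates) &&
      !truth$model$name %in% vapply(candidates, `[[`, character(1), "name"))
    candidates <- c(list(truth$model), candidates)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    st <- study
    st$seed <- study$seed + r - 1L
    ds <- simulate_dataset(st)
    o <- opts
    o$seed <- opts$seed + r - 1L
    fit <- fit_model(ds, truth$model, o)
    rec <- fit$params[free]
    tru <- truth$params[free]
    rel <- abs(rec - tru) / pmax(abs(tru), .Machine$double.eps)
    row <- data.frame(replicate = r, seed = st$seed,
                      rss_pooled = fit$rss_pooled)
    for (nm in free) {
      row[[paste0(nm, "_hat")]] <- rec[[nm]]
      row[[paste0(nm, "_relerr")]] <- rel[[nm]]
    }
    if (!is.null(candidates)) {
      fits <- lapply(candidates, function(m) fit_model(ds, m, o))
      tab <- rank_models(fits, kmax = kmax, rssmax = rss_max(ds))
      row$rank_true <- tab$rank[tab$model == truth$model$name][1]
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
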