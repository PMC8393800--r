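## Model selection: classical information criteria on the pooled RSS, the
## entropic extensions S_A / S_B with their tunable maximum-parameter-count
## coefficient kmax, kmax tuning by correlation against AIC/BIC, and
## candidate ranking.

#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = n * ln(RSS / n) + 2 k`, i.e. the mean squared error `RSS / n`
#' enters the log-likelihood term.
#'
#' @param rss Residual sum of squares (> 0); vectorised.
#' @param n Number of observations.
#' @param k Number of free model coefficients; vectorised.
#' @return AIC value(s).
#' @examples
#' aic(16.79, 327, 2) # about -967
#' @export
aic <- function(rss, n, k) {
  if (any(rss <= 0)) pmaxsel_stop("`rss` must be positive for log-based criteria")
  if (!is_number(n) || n <= 0) pmaxsel_stop("`n` must be a positive count")
  n * log(rss / n) + 2 * k
}

#' Bayesian information criterion from a residual sum of squares
#'
#' `BIC = n * ln(RSS / n) + k * ln(n)`, the standard sample-size-dependent
#' complexity penalty on the error-variance log-likelihood.
#'
#' @inheritParams aic
#' @return BIC value(s).
#' @export
bic <- function(rss, n, k) {
  if (any(rss <= 0)) pmaxsel_stop("`rss` must be positive for log-based criteria")
  if (!is_number(n) || n <= 0) pmaxsel_stop("`n` must be a positive count")
  n * log(rss / n) + k * log(n)
}

#' Null-model (maximum-likelihood) residual sum of squares
#'
#' The RSS of the zero-coefficient model, whose prediction is identically
#' zero: site-wise `sum(y^2)`, pooled with the normalised two-site
#' weighting when both sites are present. This is the `RSS_max` entering
#' the entropic criteria.
#'
#' @param dataset List of [experiment_record()]s.
#' @return Scalar null RSS.
#' @export
rss_max <- function(dataset) {
  if (!length(dataset)) pmaxsel_stop("`dataset` must be non-empty")
  s <- vapply(dataset, `[[`, integer(1), "site")
  ss <- vapply(dataset, function(e) sum(e$samples$y^2), numeric(1))
  n <- vapply(dataset, function(e) nrow(e$samples), integer(1))
  n1 <- sum(n[s == 1L]); n2 <- sum(n[s == 2L])
  if (n1 > 0 && n2 > 0)
    pooled_rss(sum(ss[s == 1L]), sum(ss[s == 2L]), n1, n2)
  else
    sum(ss)
}

#' Entropic model-selection criterion
#'
#' The entropic extensions of AIC with tunable maximum-parameter-count
#' coefficient `kmax` (natural logarithms throughout):
#'
#' * variant A:
#'   `ln S_A = ln[(kmax - k) * RSS * ln(RSS) + k * (RSSmax - RSS) * ln(RSSmax - RSS)]`
#' * variant B:
#'   `ln S_B = ln[(kmax - k) * RSS * ln(RSS) + k * RSSmax * ln(RSSmax / RSS)]`
#'
#' Lower values indicate a better complexity/fit trade-off; as `kmax` grows
#' the ranking behaves asymptotically like AIC/BIC. For `RSS < 1` the first
#' term is negative and the argument of the outer log can become
#' non-positive; that case is rejected with a diagnostic rather than
#' silently producing `NaN`.
#'
#' @param kmax Tuning coefficient, `> k` for every scored model.
#' @param k Number of free coefficients; vectorised.
#' @param rss Fitted (pooled) RSS, `0 < rss < rssmax`; vectorised.
#' @param rssmax Null-model RSS, see [rss_max()].
#' @param variant `"A"` (default) or `"B"`.
#' @return `ln S` value(s).
#' @examples
#' entropic_s(33, 2, 11.782, 53.3) # about 7.10
#' @export
entropic_s <- function(kmax, k, rss, rssmax, variant = c("A", "B")) {
  variant <- match.arg(variant)
  if (any(rss <= 0) || any(rss >= rssmax))
    pmaxsel_stop("`rss` must satisfy 0 < rss < rssmax")
  if (any(kmax <= k)) pmaxsel_stop("`kmax` must exceed `k` for every scored model")
  arg <- if (variant == "A")
    (kmax - k) * rss * log(rss) + k * (rssmax - rss) * log(rssmax - rss)
  else
    (kmax - k) * rss * log(rss) + k * rssmax * log(rssmax / rss)
  if (any(arg <= 0))
    pmaxsel_stop(paste0(
      "entropic criterion argument is non-positive (RSS < 1 can do this); ",
      "S_", variant, " is undefined for this (kmax, k, rss, rssmax)"))
  log(arg)
}

#' Estimate a common null RSS from scored criterion rows
#'
#' Given rows `(kmax, k, rss, lnS)` scored with variant A, recovers the
#' single scalar `RSSmax` that best reproduces the reported `lnS` values in
#' the least-squares sense. Useful for auditing reported criterion tables
#' whose underlying dataset is unavailable.
#'
#' @param rows Data frame with columns `kmax`, `k`, `rss`, `lnS`.
#' @param interval Search interval; defaults to just above `max(rows$rss)`
#'   up to 100 times it.
#' @return The estimated scalar `RSSmax`.
#' @export
estimate_rss_max <- function(rows, interval = NULL) {
  need <- c("kmax", "k", "rss", "lnS")
  if (!is.data.frame(rows) || !all(need %in% names(rows)))
    pmaxsel_stop("`rows` must have columns kmax, k, rss, lnS")
  if (any(rows$k <= 0))
    pmaxsel_stop("rows with k = 0 carry no information about RSSmax")
  if (is.null(interval)) interval <- c(max(rows$rss) * 1.0001, max(rows$rss) * 100)
  loss <- function(rm) {
    pred <- tryCatch(
      entropic_s(rows$kmax, rows$k, rows$rss, rm, variant = "A"),
      pmaxsel_error = function(e) rep(NA_real_, nrow(rows)))
    if (anyNA(pred)) return(1e10)
    sum((pred - rows$lnS)^2)
  }
  optimize(loss, interval = interval, tol = 1e-8)$minimum
}

#' Tune kmax by correlation against a classical criterion
#'
#' Sweeps integer `kmax` values and, for each, computes the Pearson
#' correlation between the entropic criterion `lnS(kmax)` and the reference
#' criterion (AIC or BIC) across the supplied fitted rows. Returns the
#' `kmax` maximising the correlation together with the whole correlation
#' curve. This is the asymptotic-matching procedure that makes the entropic
#' criterion behave like the classical one while retaining a complexity
#' dial.
#'
#' @param rows Data frame with columns `k` and `rss` (one row per fitted
#'   candidate model); at least 3 rows with non-degenerate criterion values.
#' @param n Pooled number of observations (for the reference criterion).
#' @param rssmax Null-model RSS.
#' @param reference `"aic"` (default) or `"bic"`.
#' @param variant Entropic variant, `"A"` or `"B"`.
#' @param kmax_range Integer range to sweep; defaults to
#'   `(max(rows$k) + 1) : 2000`.
#' @return List with `kmax` (argmax, lowest on ties), `cor` (the achieved
#'   correlation) and `curve` (data frame `kmax`, `cor`).
#' @export
tune_kmax <- function(rows, n, rssmax, reference = c("aic", "bic"),
                      variant = c("A", "B"), kmax_range = NULL) {
  reference <- match.arg(reference)
  variant <- match.arg(variant)
  if (!is.data.frame(rows) || !all(c("k", "rss") %in% names(rows)))
    pmaxsel_stop("`rows` must have columns k and rss")
  if (nrow(rows) < 3L) pmaxsel_stop("need at least 3 fitted rows to tune kmax")
  ref <- if (reference == "aic") aic(rows$rss, n, rows$k) else bic(rows$rss, n, rows$k)
  if (stats::sd(ref) == 0)
    pmaxsel_stop("reference criterion is degenerate (zero variance) over the rows")
  if (is.null(kmax_range)) kmax_range <- seq(max(rows$k) + 1L, 2000L)
  cors <- vapply(kmax_range, function(km) {
    s <- tryCatch(entropic_s(km, rows$k, rows$rss, rssmax, variant = variant),
                  pmaxsel_error = function(e) rep(NA_real_, nrow(rows)))
    if (anyNA(s) || stats::sd(s) == 0) return(NA_real_)
    cor(s, ref)
  }, numeric(1))
  if (all(is.na(cors)))
    pmaxsel_stop("entropic criterion undefined over the whole kmax range")
  best <- which.max(cors) # first maximum -> lowest kmax on ties
  list(kmax = as.integer(kmax_range[best]), cor = cors[best],
       curve = data.frame(kmax = as.integer(kmax_range), cor = cors))
}

#' Criterion table for a set of fitted models
#'
#' Assembles the per-model selection statistics: `k`, pooled RSS, MAE, AIC,
#' BIC and the entropic criteria `lnS_A`, `lnS_B` at the supplied `kmax`.
#'
#' @param fits List of `fit_result`s from [fit_model()], all on the same
#'   dataset.
#' @param kmax Entropic tuning coefficient (must exceed every model's `k`).
#' @param rssmax Null-model RSS of the common dataset; see [rss_max()].
#' @return A data frame with columns `model`, `k`, `rss`, `mae`, `aic`,
#'   `bic`, `lnS_A`, `lnS_B`.
#' @export
criterion_table <- function(fits, kmax, rssmax) {
  if (!length(fits)) pmaxsel_stop("`fits` must be non-empty")
  ns <- vapply(fits, function(f) f$n1 + f$n2, numeric(1))
  if (length(unique(ns)) != 1L)
    pmaxsel_stop("all fits must come from the same dataset (sample counts differ)")
  n <- ns[1]
  data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    rss = vapply(fits, `[[`, numeric(1), "rss_pooled"),
    mae = vapply(fits, `[[`, numeric(1), "mae"),
    aic = vapply(fits, function(f) aic(f$rss_pooled, n, f$k), numeric(1)),
    bic = vapply(fits, function(f) bic(f$rss_pooled, n, f$k), numeric(1)),
    lnS_A = vapply(fits, function(f)
      entropic_s(kmax, f$k, f$rss_pooled, rssmax, "A"), numeric(1)),
    lnS_B = vapply(fits, function(f)
      entropic_s(kmax, f$k, f$rss_pooled, rssmax, "B"), numeric(1))
  )
}

#' Rank candidate models
#'
#' Orders a [criterion_table()] ascending by the requested criterion
#' (entropic variant A by default); ties are broken by fewer coefficients,
#' then lexicographic model name.
#'
#' @inheritParams criterion_table
#' @param by `"lnS_A"`, `"lnS_B"`, `"aic"`, `"bic"`, `"rss"` or `"mae"`.
#' @return The sorted criterion table with a `rank` column prepended.
#' @export
rank_models <- function(fits, kmax, rssmax,
                        by = c("lnS_A", "lnS_B", "aic", "bic", "rss", "mae")) {
  by <- match.arg(by)
  tab <- criterion_table(fits, kmax, rssmax)
  ord <- order(tab[[by]], tab$k, tab$model)
  out <- tab[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}
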