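## Dataset serialisation: one trajectory CSV and one samples CSV per
## experiment plus a YAML manifest tying them together, and deterministic
## selection reports. CSVs are UTF-8, comma-separated, dot decimal, with a
## header row.

#' Write a dataset to CSV files plus a manifest
#'
#' Writes, for every experiment, `<id>_trajectory.csv` (columns `time_h`,
#' `biomass_g_per_l` and optionally `our_mmol_per_l_h`) and
#' `<id>_samples.csv` (columns `time_h`, `protein`, optionally `sigma`),
#' and a `manifest.yaml` recording site membership, induction times,
#' inoculation biomass, file paths and a units declaration.
#'
#' @param dataset List of [experiment_record()]s.
#' @param dir Output directory (created if needed).
#' @param units Units declaration stored verbatim in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir,
                          units = list(time = "h", biomass = "g/L",
                                       protein = "U/g")) {
  if (!length(dataset)) pmaxsel_stop("`dataset` must be non-empty")
  ids <- vapply(dataset, `[[`, character(1), "id")
  if (anyDuplicated(ids)) pmaxsel_stop("experiment ids must be unique")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(dataset, function(e) {
    traj <- data.frame(time_h = e$curve$t, biomass_g_per_l = e$curve$X)
    if (!is.null(e$our)) traj$our_mmol_per_l_h <- e$our
    traj_file <- paste0(e$id, "_trajectory.csv")
    samp_file <- paste0(e$id, "_samples.csv")
    write.csv(traj, file.path(dir, traj_file), row.names = FALSE)
    samp <- data.frame(time_h = e$samples$t_s, protein = e$samples$y)
    if (!is.null(e$samples$sigma)) samp$sigma <- e$samples$sigma
    write.csv(samp, file.path(dir, samp_file), row.names = FALSE)
    list(id = e$id, site = e$site, t_ind = e$t_ind, X0 = e$curve$X0,
         trajectory = traj_file, samples = samp_file)
  })
  manifest <- list(units = units, experiments = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 12)
  invisible(path)
}

#' Read a dataset from a manifest
#'
#' Loads and validates every experiment referenced by a `manifest.yaml`
#' written by [write_dataset()] (or hand-edited to the same schema). Schema
#' violations fail hard with the offending file named.
#'
#' @param manifest Path to the manifest file.
#' @return List of [experiment_record()]s.
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest))
    pmaxsel_stop(paste0("manifest not found: ", manifest))
  m <- yaml::read_yaml(manifest)
  if (is.null(m$experiments) || !length(m$experiments))
    pmaxsel_stop("manifest lists no experiments")
  dir <- dirname(manifest)
  ids <- vapply(m$experiments, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    pmaxsel_stop("manifest contains duplicate experiment ids")
  lapply(m$experiments, function(entry) {
    tf <- file.path(dir, entry$trajectory)
    sf <- file.path(dir, entry$samples)
    for (f in c(tf, sf)) if (!file.exists(f))
      pmaxsel_stop(paste0("experiment '", entry$id, "': file not found: ", f))
    traj <- read.csv(tf)
    if (!all(c("time_h", "biomass_g_per_l") %in% names(traj)))
      pmaxsel_stop(paste0("missing required columns in ", tf,
                          " (need time_h, biomass_g_per_l)"))
    bad <- which(diff(traj$time_h) <= 0)
    if (length(bad))
      pmaxsel_stop(sprintf("non-increasing time in %s at row %d", tf, bad[1] + 1L))
    samp <- read.csv(sf)
    if (!all(c("time_h", "protein") %in% names(samp)))
      pmaxsel_stop(paste0("missing required columns in ", sf,
                          " (need time_h, protein)"))
    if (any(samp$time_h < 0))
      pmaxsel_stop(paste0("sample before t = 0 in ", sf))
    X0 <- if (!is.null(entry$X0)) entry$X0 else traj$biomass_g_per_l[1]
    curve <- growth_curve(traj$time_h, traj$biomass_g_per_l, X0 = X0)
    our <- if ("our_mmol_per_l_h" %in% names(traj)) traj$our_mmol_per_l_h
    experiment_record(entry$id, entry$site, curve, entry$t_ind,
                      protein_samples(samp$time_h, samp$protein, samp$sigma),
                      our = our)
  })
}

#' Write a model-selection report
#'
#' Renders a [criterion_table()] (or [rank_models()] output) with a
#' deterministic column order `model, k, RSS, MAE, AIC, BIC, lnS_A, lnS_B`.
#' Criteria are rendered at 3 decimals, coefficients at 5. The text format
#' appends a footer recording the `kmax` and `RSSmax` the entropic columns
#' were computed with. Regenerating the report from the same inputs is
#' byte-identical.
#'
#' @param tab A criterion table.
#' @param path Output file path.
#' @param format `"csv"` or `"text"`.
#' @param kmax,rssmax Provenance recorded in the text footer.
#' @return `path`, invisibly.
#' @export
write_report <- function(tab, path, format = c("csv", "text"),
                         kmax = NA, rssmax = NA) {
  format <- match.arg(format)
  cols <- c("model", "k", "rss", "mae", "aic", "bic", "lnS_A", "lnS_B")
  out <- data.frame(model = character(0), k = integer(0), RSS = numeric(0),
                    MAE = numeric(0), AIC = numeric(0), BIC = numeric(0),
                    lnS_A = numeric(0), lnS_B = numeric(0))
  if (!is.null(tab) && nrow(tab)) {
    missing_cols <- setdiff(cols, names(tab))
    if (length(missing_cols))
      pmaxsel_stop(paste0("report input lacks columns: ",
                          paste(missing_cols, collapse = ", ")))
    fmt3 <- function(x) sprintf("%.3f", x)
    out <- data.frame(model = tab$model, k = tab$k, RSS = fmt3(tab$rss),
                      MAE = fmt3(tab$mae), AIC = fmt3(tab$aic),
                      BIC = fmt3(tab$bic), lnS_A = fmt3(tab$lnS_A),
                      lnS_B = fmt3(tab$lnS_B))
  }
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    widths <- vapply(names(out), function(nm)
      max(nchar(nm), if (nrow(out)) max(nchar(as.character(out[[nm]]))) else 0L),
      integer(1))
    pad <- function(vals) paste(mapply(formatC, as.character(vals),
                                       width = widths, flag = "-"),
                                collapse = "  ")
    writeLines(pad(names(out)), con)
    for (i in seq_len(nrow(out))) writeLines(pad(out[i, ]), con)
    writeLines(sprintf("# kmax = %s, RSSmax = %s",
                       format(kmax), format(rssmax)), con)
  }
  invisible(path)
}
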