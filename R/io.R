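#' Write a trace set as CSV files plus a manifest
#'
#' One CSV per trace with columns `time_s`, `fluorescence_au`, and a
#' manifest CSV (`file`, `e0_uM`, `s0_uM`, `fluorophore`) referencing them.
#' Concentrations in user-facing files are micromolar; all internal math is
#' molar, converted at this boundary only.
#'
#' @param series A [trace_set()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix for the trace CSVs.
#' @return Path of the written manifest, invisibly.
#' @export
write_series <- function(series, dir, prefix = "trace") {
  stopifnot(inherits(series, "trace_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(series$traces), function(i) {
    tr <- series$traces[[i]]
    fn <- sprintf("%s_%02d.csv", prefix, i)
    utils::write.csv(
      data.frame(time_s = tr$time, fluorescence_au = tr$signal),
      file.path(dir, fn), row.names = FALSE)
    data.frame(file = fn, e0_uM = tr$e0 * 1e6, s0_uM = tr$s0 * 1e6,
               fluorophore = tr$fluorophore %||% "unknown")
  })
  manifest <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Load a concentration series from a manifest
#'
#' Reads a manifest CSV (`file`, `e0_uM`, `s0_uM`, `fluorophore`) whose rows
#' reference per-trace CSVs (`time_s`, `fluorescence_au`) relative to the
#' manifest's directory, validates each trace, and converts concentrations
#' to molar.
#'
#' @param manifest Path to the manifest CSV.
#' @return A [trace_set()].
#' @export
load_series <- function(manifest) {
  if (!file.exists(manifest))
    stop("manifest not found: ", manifest, call. = FALSE)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("file", "e0_uM", "s0_uM", "fluorophore")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(manifest)
  traces <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(base, man$file[i])
    if (!file.exists(path))
      stop("manifest row ", i, ": trace file not found: ", man$file[i],
           call. = FALSE)
    d <- utils::read.csv(path)
    if (!all(c("time_s", "fluorescence_au") %in% names(d)))
      stop("manifest row ", i, " (", man$file[i],
           "): need columns time_s, fluorescence_au", call. = FALSE)
    if (any(!is.finite(d$fluorescence_au)))
      stop("manifest row ", i, " (", man$file[i], "): NaN/Inf signal",
           call. = FALSE)
    if (any(diff(d$time_s) <= 0))
      stop("manifest row ", i, " (", man$file[i],
           "): time not strictly increasing", call. = FALSE)
    list(time = d$time_s, signal = d$fluorescence_au,
         e0 = man$e0_uM[i] * 1e-6, s0 = man$s0_uM[i] * 1e-6,
         fluorophore = man$fluorophore[i])
  })
  trace_set(traces)
}

#' Write a fit report as JSON and a flat parameter CSV
#'
#' Serializes an [fit_traces()] result: mechanism description, parameter
#' estimates with both uncertainty measures, per-trace backgrounds,
#' observation coefficients, residual statistics, AIC, and the seed, with
#' deterministic field ordering. A sibling `<path>.csv` holds the flat
#' parameter table.
#'
#' @param fit An `sf_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "sf_fit"))
  report <- list(
    scheme = list(
      n_reversible = fit$scheme$n_reversible,
      include_catalysis = fit$scheme$include_catalysis,
      include_release = fit$scheme$include_release,
      labeled_molecule = fit$scheme$labeled_molecule
    ),
    parameters = lapply(seq_along(fit$estimates), function(i) {
      list(name = names(fit$estimates)[i],
           estimate = unname(fit$estimates[i]),
           se = unname(fit$se[i]),
           multistart_sd = unname(fit$multistart_sd[i]))
    }),
    observation = list(f_per_uM = as.list(fit$f_per_uM),
                       F_b = fit$F_b),
    residuals = list(sse = fit$sse, n_obs = fit$n_obs, n_par = fit$n_par,
                     aic = fit$aic),
    options = list(n_starts = fit$options$n_starts, seed = fit$options$seed,
                   weighting = fit$options$weighting,
                   release_rate = fit$options$release_rate)
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tab <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    se = unname(fit$se),
                    multistart_sd = unname(fit$multistart_sd))
  utils::write.csv(tab, sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}

#' Read back a JSON fit report
#'
#' @param path Path written by [write_report()].
#' @return The report as a nested list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
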