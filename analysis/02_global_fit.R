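#!/usr/bin/env Rscript
# Globally fits the m3C-like synthetic concentration series from stage 01:
# loads the traces from their manifest, runs sequential-complication scheme
# selection up to three reversible steps, and writes the chosen fit as a
# JSON report plus a flat parameter CSV. Expected outcome: the two-step
# binding/isomerization scheme is selected and its four rate constants land
# within a few percent of the generating truth recorded alongside the data.

suppressPackageStartupMessages(library(sfkin))

manifest <- "results/data/m3C_manifest.csv"
if (!file.exists(manifest))
  stop("run analysis/01_simulate_series.R first", call. = FALSE)

series <- load_series(manifest)
# window indices for residual weighting are not part of the CSV format;
# re-attach them from the default acquisition grid
grid <- make_time_grid()
series$traces <- lapply(series$traces, function(tr) {
  if (length(tr$time) == length(grid$times)) tr$window <- grid$window
  tr
})

sel <- select_scheme(series, 3, fit_options(n_starts = 4, seed = 11))
cat("Selected scheme:", sel$scheme$n_reversible, "reversible steps\n")
print(sel$table)
print(sel$fit)

dir.create("results", showWarnings = FALSE)
write_report(sel$fit, "results/m3C_fit.json")
utils::write.csv(sel$table, "results/m3C_selection.csv", row.names = FALSE)

truth <- jsonlite::read_json("results/data/m3C_truth.json",
                             simplifyVector = TRUE)
truth_k <- c(k1 = truth$k_fwd[1], k2 = truth$k_fwd[2],
             km1 = truth$k_rev[1], km2 = truth$k_rev[2])
rel <- 100 * (sel$fit$estimates[names(truth_k)] / truth_k - 1)
cat("\nRecovery vs generating truth (% deviation):\n")
print(round(rel, 2))
cat("Report written to results/m3C_fit.json\n")
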