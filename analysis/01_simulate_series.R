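#!/usr/bin/env Rscript
# Generates the synthetic stopped-flow concentration series for the three
# lesion-like reference mechanisms under the single-turnover design
# (fluorescent component fixed at 1.5 uM, counterpart 0.5-5 uM, split-window
# grid 1 ms - 550 s, 1% noise) and writes trace CSVs + manifests with the
# generating truth, so the later fitting stages run on files alone.

suppressPackageStartupMessages(library(sfkin))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed0 <- 20220804

for (nm in c("m1A-like", "m3C-like", "epsilonA-like")) {
  p <- kinetic_preset(nm)
  g <- generate_sf_series(p$scheme, p$rates, p$obs,
                          seed = seed0 + match(nm, c("m1A-like", "m3C-like",
                                                     "epsilonA-like")),
                          fluorophore = p$fluorophore)
  tag <- sub("-like", "", nm)
  manifest <- write_series(g$series, out_dir, prefix = tag)
  truth <- c(
    as.list(g$truth$rates[c("k_fwd", "k_rev", "k_r", "K_d_product")]),
    list(noise_sd = g$truth$noise_sd, seed = g$truth$seed)
  )
  jsonlite::write_json(truth, file.path(out_dir, paste0(tag, "_truth.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cat(sprintf("%-14s -> %d traces, manifest %s\n", nm, length(g$series),
              manifest))
}
cat("Synthetic series written under", out_dir, "\n")
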