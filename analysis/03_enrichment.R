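#!/usr/bin/env Rscript
# Summarize the over-representation analyses of script 02: per-layer,
# combined-oxidation and integrative scopes, with the planted pathway as a
# positive control.

suppressPackageStartupMessages(library(oxidiff))

res_dir <- "results/run/results"
if (!dir.exists(res_dir)) stop("run analysis/02_differential.R first")

files <- list.files(res_dir, pattern = "^enrichment_.*_24h\\.tsv$",
                    full.names = TRUE)
for (f in files) {
  e <- read_table(f)
  scope <- sub("^enrichment_(.*)_24h\\.tsv$", "\\1", basename(f))
  planted <- e[e$set_name == "SET_PLANTED", ]
  message(sprintf(
    "%-12s 24h: %d/%d sets significant; SET_PLANTED fdr = %.2e (%s)",
    scope, sum(e$significant), nrow(e), planted$fdr,
    ifelse(nrow(planted) > 0 && planted$significant, "detected",
           "not detected")))
}
message("\nDecoy sets flagged at FDR <= 0.05 (expected to be rare):")
for (f in files) {
  e <- read_table(f)
  decoys <- e$set_name[e$significant & e$set_name != "SET_PLANTED"]
  if (length(decoys) > 0) {
    message(basename(f), ": ", paste(decoys, collapse = ", "))
  }
}
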