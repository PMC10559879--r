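#!/usr/bin/env Rscript
# Cross-timepoint dynamics (Pearson correlation of 4 h vs 24 h mean log2
# fold changes, split into significant and not-affected entities) and the
# overlap of proteins significant at protein, oxidation and phosphorylation
# level, from the tables written by script 02.

suppressPackageStartupMessages(library(oxidiff))

res_dir <- "results/run/results"
if (!dir.exists(res_dir)) stop("run analysis/02_differential.R first")

dyn <- read_table(file.path(res_dir, "dynamics.tsv"))
message("Cross-timepoint Pearson correlations (4 h vs 24 h):")
print(dyn[c("layer", "subset", "n", "r", "p")], row.names = FALSE)

for (tp in c("4h", "24h")) {
  ov <- read_table(file.path(res_dir, sprintf("overlap_%s.tsv", tp)))
  message(sprintf(
    "\n%s: %d proteins significant in >= 1 layer; %d multiply modified",
    tp, nrow(ov), sum(ov$multiply_modified)))
  print(table(venn_class = ov$venn_class))
}

ann_path <- file.path(res_dir, "annotated_ox_sites.tsv")
if (file.exists(ann_path)) {
  ann <- read_table(ann_path)
  message(sprintf(
    "\nSignificant oxidation sites: %d; known modified: %d; in disulfide bonds: %d",
    nrow(ann), sum(ann$known_modified),
    sum(!is.na(ann$disulfide_partner))))
}
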