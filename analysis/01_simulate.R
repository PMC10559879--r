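#!/usr/bin/env Rscript
# Generate the synthetic experiment that the downstream analysis scripts
# consume: 3 runs x 4 replicates (12 biological replicates), time points 4 h
# and 24 h, paired treated/control samples in every TMT mix, three layers
# (proteome, redoxome with TMT1/TMT2 label stages, phosphoproteome), planted
# log2 effects of size 1 and one planted gene set.

suppressPackageStartupMessages(library(oxidiff))

out_dir <- "results/experiment"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20260919L)
sim <- simulate_experiment(cfg)

write_design(sim$design, file.path(out_dir, "design.tsv"))
for (ly in names(sim$peptides)) {
  write_table(sim$peptides[[ly]],
              file.path(out_dir, paste0("peptides_", ly, ".tsv")))
  write_impurity_matrix(sim$impurity[[ly]],
                        file.path(out_dir, paste0("impurity_", ly, ".tsv")))
}
write_gmt(sim$gene_sets, file.path(out_dir, "gene_sets.gmt"))
write_mapping(sim$mapping, file.path(out_dir, "mapping.tsv"))
write_table(sim$annotations, file.path(out_dir, "annotations.tsv"))
# no binary outputs: the ground truth is recomputable from the seed

message("Simulated ", cfg$n_proteins, " proteins, ",
        nrow(sim$truth$ox_sites), " cysteine sites, ",
        nrow(sim$truth$phospho_sites), " phosphosites across ",
        length(unique(sim$design$mix_id)), " TMT mixes.")
message("Planted gene set: SET_PLANTED (",
        length(sim$gene_sets$sets$SET_PLANTED), " genes, effect prob ",
        cfg$planted_effect_prob, "); background effect prob ",
        cfg$prop_protein_affected, ".")
message("Inputs written under ", out_dir)
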