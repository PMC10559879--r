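# End-to-end workflow: simulate (optional) -> read -> impurity-correct ->
# rollup -> fold changes -> filter -> median normalize -> invert ox_all ->
# PTM-to-protein normalization -> t test/BH -> enrichment -> dynamics ->
# overlap -> annotation -> recovery report. Every intermediate table is
# written as TSV; a manifest records parameters and output checksums so a
# rerun with the same configuration is byte-identical.

#' Differential analysis of one quantification layer at one time point
#'
#' Runs the statistical chain on a rolled-up quantification matrix:
#' mix-internal log2 fold changes, the at-least-in-triplicate filter, median
#' normalization, sign inversion for the free-thiol layer, optional
#' normalization to protein-level changes, and the one-sample t test with
#' Benjamini-Hochberg adjustment.
#'
#' @param q `quant_matrix` of the layer.
#' @param timepoint time point label.
#' @param protein_fc optional proteome `fc_matrix` at the same time point;
#'   required to normalize PTM layers to protein level.
#' @param min_replicates reliability filter threshold.
#' @param alpha FDR threshold.
#' @return list with elements `fc` (the final `fc_matrix`) and `result`
#'   (`DifferentialResult`).
#' @export
differential_layer <- function(q, timepoint, protein_fc = NULL,
                               min_replicates = 3L, alpha = 0.05) {
  fc <- compute_fold_changes(q, timepoint)
  fc <- filter_min_replicates(fc, min_replicates)
  fc <- median_normalize(fc)
  if (attr(fc, "layer") == "ox_all") fc <- invert_overall_oxidation(fc)
  if (!is.null(protein_fc) && attr(fc, "layer") != "proteome") {
    fc <- normalize_site_to_protein(fc, protein_fc)
    fc <- filter_min_replicates(fc, min_replicates)
  }
  list(fc = fc, result = test_differential(fc, alpha = alpha))
}

#' Run the full integrative analysis on a synthetic experiment
#'
#' Simulates an experiment, writes its input tables, reads them back through
#' the package's readers, and executes every analysis stage, writing all
#' result tables plus a run manifest under `out_dir`. Rerunning with the same
#' configuration produces byte-identical result files.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param min_replicates reliability filter threshold.
#' @param alpha FDR threshold for differential and enrichment calls.
#' @param correct_impurity apply reporter-ion impurity correction.
#' @param normalize_to_protein normalize PTM-site fold changes to
#'   protein-level changes; requires the proteome layer.
#' @return invisibly, a list with the differential results, counts,
#'   enrichment tables, dynamics, overlap, recovery report, and paths.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         min_replicates = 3L, alpha = 0.05,
                         correct_impurity = TRUE,
                         normalize_to_protein = TRUE) {
  if (normalize_to_protein && !"proteome" %in% config$layers) {
    stop("PTM-to-protein normalization requires the proteome layer",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_dir <- file.path(out_dir, "inputs")
  res_dir <- file.path(out_dir, "results")
  dir.create(in_dir, showWarnings = FALSE)
  dir.create(res_dir, showWarnings = FALSE)

  sim <- simulate_experiment(config)
  tps <- config$timepoints

  # ---- write inputs, then consume them through the readers -------------
  write_design(sim$design, file.path(in_dir, "design.tsv"))
  for (ly in names(sim$peptides)) {
    write_table(sim$peptides[[ly]],
                file.path(in_dir, paste0("peptides_", ly, ".tsv")))
    write_impurity_matrix(sim$impurity[[ly]],
                          file.path(in_dir, paste0("impurity_", ly, ".tsv")))
  }
  write_gmt(sim$gene_sets, file.path(in_dir, "gene_sets.gmt"))
  write_mapping(sim$mapping, file.path(in_dir, "mapping.tsv"))
  write_table(sim$annotations, file.path(in_dir, "annotations.tsv"))

  design <- read_design(file.path(in_dir, "design.tsv"))
  gene_sets <- read_gmt(file.path(in_dir, "gene_sets.gmt"))
  mapping <- read_mapping(file.path(in_dir, "mapping.tsv"))
  annotations <- read_site_annotations(file.path(in_dir, "annotations.tsv"))

  quant_layers <- c(
    if ("proteome" %in% config$layers) "proteome",
    if ("redoxome" %in% config$layers) c("ox_all", "ox_rev"),
    if ("phospho" %in% config$layers) "phospho")

  quants <- list()
  for (ql in quant_layers) {
    src <- quant_layer_source(ql)$layer
    rec <- read_peptide_table(file.path(in_dir,
                                        paste0("peptides_", src, ".tsv")),
                              design, layer = src)
    if (correct_impurity) {
      m <- read_impurity_matrix(file.path(in_dir,
                                          paste0("impurity_", src, ".tsv")))
      rec <- correct_impurities(rec, m)
    }
    quants[[ql]] <- rollup_sites(rec, design, ql)
  }

  # ---- differential analysis per layer x time point --------------------
  has_proteome <- "proteome" %in% quant_layers
  diff_results <- list()
  fcs <- list()
  for (tp in tps) {
    protein_fc <- NULL
    if (has_proteome) {
      d <- differential_layer(quants$proteome, tp,
                              min_replicates = min_replicates, alpha = alpha)
      protein_fc <- d$fc
      fcs[[paste("proteome", tp)]] <- d$fc
      diff_results[[paste("proteome", tp)]] <- d$result
    }
    for (ql in setdiff(quant_layers, "proteome")) {
      d <- differential_layer(quants[[ql]], tp,
                              protein_fc = if (normalize_to_protein)
                                protein_fc,
                              min_replicates = min_replicates, alpha = alpha)
      fcs[[paste(ql, tp)]] <- d$fc
      diff_results[[paste(ql, tp)]] <- d$result
    }
  }
  all_diff <- do.call(rbind, c(diff_results, make.row.names = FALSE))
  for (nm in names(diff_results)) {
    f <- sprintf("differential_%s.tsv", gsub(" ", "_", nm))
    write_table(diff_results[[nm]], file.path(res_dir, f))
  }
  counts <- summarize_counts(all_diff)
  write_table(counts, file.path(res_dir, "counts.tsv"))

  # ---- enrichment -------------------------------------------------------
  enrichments <- list()
  for (tp in tps) {
    tp_res <- diff_results[paste(quant_layers, tp)]
    names(tp_res) <- quant_layers
    sig_by_layer <- lapply(tp_res, function(r) r$entity[r$significant])
    uni_by_layer <- lapply(tp_res, function(r) r$entity)
    fc_by_layer <- lapply(tp_res, function(r) {
      data.frame(entity = r$entity[r$significant],
                 log2fc = r$log2fc_mean[r$significant],
                 stringsAsFactors = FALSE)
    })
    scopes <- as.list(quant_layers)
    names(scopes) <- quant_layers
    if (all(c("ox_all", "ox_rev") %in% quant_layers)) {
      scopes$ox_combined <- c("ox_all", "ox_rev")
    }
    for (sc in names(scopes)) {
      lys <- scopes[[sc]]
      sig <- map_to_genes(unique(unlist(sig_by_layer[lys])), mapping)
      uni <- map_to_genes(unique(unlist(uni_by_layer[lys])), mapping)
      if (length(uni) == 0) next
      member_fc <- do.call(rbind, fc_by_layer[lys])
      member_fc <- data.frame(
        gene = unname(mapping[parent_accession(member_fc$entity)]),
        log2fc = member_fc$log2fc, stringsAsFactors = FALSE)
      e <- enrich(sig, uni, gene_sets, member_fc = member_fc, alpha = alpha)
      enrichments[[paste(sc, tp)]] <- e
      write_table(e, file.path(res_dir,
                               sprintf("enrichment_%s_%s.tsv", sc, tp)))
    }
    if (length(quant_layers) >= 2) {
      e <- integrative_enrich(sig_by_layer, uni_by_layer, gene_sets, mapping,
                              member_fc_by_layer = fc_by_layer, alpha = alpha)
      enrichments[[paste("integrative", tp)]] <- e
      write_table(e, file.path(res_dir,
                               sprintf("enrichment_integrative_%s.tsv", tp)))
    }
  }

  # ---- dynamics and overlap --------------------------------------------
  dynamics <- NULL
  if (length(tps) >= 2) {
    dyn <- list()
    for (ql in quant_layers) {
      for (ss in c("significant", "not_affected")) {
        dyn[[paste(ql, ss)]] <- correlate_timepoints(
          diff_results[[paste(ql, tps[1])]],
          diff_results[[paste(ql, tps[2])]], subset = ss)
      }
    }
    dynamics <- do.call(rbind, c(dyn, make.row.names = FALSE))
    write_table(dynamics, file.path(res_dir, "dynamics.tsv"))
  }

  overlaps <- list()
  if (all(c("proteome", "ox_all", "ox_rev", "phospho") %in% quant_layers)) {
    for (tp in tps) {
      ov <- overlap_multiply_modified(
        diff_results[[paste("proteome", tp)]],
        rbind(diff_results[[paste("ox_all", tp)]],
              diff_results[[paste("ox_rev", tp)]]),
        diff_results[[paste("phospho", tp)]])
      overlaps[[tp]] <- ov
      write_table(ov, file.path(res_dir, sprintf("overlap_%s.tsv", tp)))
    }
  }

  annotated <- NULL
  ox_rows <- all_diff[all_diff$layer %in% c("ox_all", "ox_rev") &
                        all_diff$significant, ]
  if (nrow(ox_rows) > 0) {
    annotated <- annotate_sites(ox_rows, annotations)
    write_table(annotated, file.path(res_dir, "annotated_ox_sites.tsv"))
  }

  recovery <- truth_report(sim$truth, all_diff)
  write_table(recovery, file.path(res_dir, "recovery.tsv"))

  # ---- manifest ---------------------------------------------------------
  outputs <- sort(list.files(res_dir, full.names = TRUE))
  manifest <- data.frame(
    key = c("seed", "n_proteins", "min_replicates", "alpha",
            "correct_impurity", "layers",
            paste0("md5:", basename(outputs))),
    value = c(config$seed, config$n_proteins, min_replicates, alpha,
              correct_impurity, paste(config$layers, collapse = ","),
              unname(tools::md5sum(outputs))),
    stringsAsFactors = FALSE)
  write_table(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(differential = all_diff, counts = counts,
                 enrichment = enrichments, dynamics = dynamics,
                 overlap = overlaps, annotated = annotated,
                 recovery = recovery, truth = sim$truth,
                 out_dir = out_dir))
}
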