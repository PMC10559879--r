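# Monte-Carlo calibration and recovery studies over the synthetic generator.
# These run the same pipeline stages as the full workflow (simulate ->
# impurity-correct -> rollup -> fold changes -> filter -> median normalize ->
# t test/BH) many times and summarize operating characteristics.

run_null_once <- function(seed, n_proteins, alpha, min_replicates) {
  cfg <- simulation_config(seed = seed, n_proteins = n_proteins,
                           peptides_per_protein = 1,
                           prop_protein_affected = 0,
                           planted_effect_prob = 0,
                           n_gene_sets = 2L,
                           layers = "proteome")
  sim <- simulate_experiment(cfg)
  rec <- suppressMessages(
    correct_impurities(sim$peptides$proteome, sim$impurity$proteome))
  q <- rollup_sites(rec, sim$design, "proteome")
  out <- lapply(cfg$timepoints, function(tp) {
    d <- suppressMessages(
      differential_layer(q, tp, min_replicates = min_replicates,
                         alpha = alpha))
    r <- d$result
    n_sig <- sum(r$significant)
    # under the global null every discovery is false
    list(p = r$p[!is.na(r$p)], fdp = if (n_sig > 0) 1 else 0)
  })
  list(p = unlist(lapply(out, `[[`, "p")),
       fdp = vapply(out, `[[`, 1, "fdp"))
}

#' Null-calibration study of the differential pipeline
#'
#' Simulates global-null experiments (no planted effects anywhere), runs the
#' full differential chain, and summarizes the realized false discovery
#' proportion at the FDR threshold and the uniformity of the pooled p-value
#' distribution (Kolmogorov-Smirnov test).
#'
#' @param n_runs number of Monte-Carlo runs.
#' @param n_proteins entities per run.
#' @param seed base RNG seed; run i uses `seed + i`.
#' @param alpha FDR threshold.
#' @param min_replicates reliability filter.
#' @return list: `mean_fdp`, `fdp_se` (Monte-Carlo standard error), `fdp`
#'   (per-contrast vector), `ks_p` (pooled uniformity p-value),
#'   `n_pvalues`.
#' @export
null_calibration_study <- function(n_runs = 200L, n_proteins = 2000L,
                                   seed = 1L, alpha = 0.05,
                                   min_replicates = 3L) {
  runs <- lapply(seq_len(n_runs), function(i) {
    run_null_once(seed + i, n_proteins, alpha, min_replicates)
  })
  fdp <- unlist(lapply(runs, `[[`, "fdp"))
  p <- unlist(lapply(runs, `[[`, "p"))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(mean_fdp = mean(fdp),
       fdp_se = stats::sd(fdp) / sqrt(length(fdp)),
       fdp = fdp, ks_p = ks$p.value, n_pvalues = length(p))
}

#' Recovery and planted-pathway study
#'
#' Simulates experiments with planted log2 effects and a planted gene set,
#' runs the differential chain and over-representation analysis, and
#' summarizes estimation bias over truly affected entities, sensitivity and
#' realized false discovery proportion at the significance call, the
#' detection rate of the planted gene set, and the false discovery
#' proportion over the decoy (unplanted) sets.
#'
#' @param n_runs Monte-Carlo runs.
#' @param n_proteins entities per run.
#' @param seed base seed; run i uses `seed + i`.
#' @param effect_size planted log2 effect magnitude.
#' @param noise_sd measurement noise (log2 sd).
#' @param alpha FDR threshold.
#' @param min_replicates reliability filter.
#' @return list of summary metrics and per-run vectors.
#' @export
recovery_study <- function(n_runs = 100L, n_proteins = 500L, seed = 1L,
                           effect_size = 1, noise_sd = 0.2, alpha = 0.05,
                           min_replicates = 3L) {
  bias <- sens <- fdp <- planted_fdr <- enr_fdp <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- simulation_config(seed = seed + i, n_proteins = n_proteins,
                             peptides_per_protein = 1,
                             effect_size = effect_size,
                             noise_sd = noise_sd,
                             layers = "proteome")
    sim <- simulate_experiment(cfg)
    rec <- suppressMessages(
      correct_impurities(sim$peptides$proteome, sim$impurity$proteome))
    q <- rollup_sites(rec, sim$design, "proteome")
    d <- suppressMessages(
      differential_layer(q, "4h", min_replicates = min_replicates,
                         alpha = alpha))
    rep_ <- truth_report(sim$truth, d$result)
    bias[i] <- rep_$bias_affected
    sens[i] <- rep_$sensitivity
    fdp[i] <- rep_$fdp
    sig_genes <- suppressMessages(
      map_to_genes(d$result$entity[d$result$significant], sim$mapping))
    uni_genes <- suppressMessages(
      map_to_genes(d$result$entity, sim$mapping))
    e <- enrich(sig_genes, uni_genes, sim$gene_sets, alpha = alpha)
    planted_fdr[i] <- e$fdr[e$set_name == "SET_PLANTED"]
    decoy_sig <- sum(e$significant & e$set_name != "SET_PLANTED")
    enr_fdp[i] <- if (any(e$significant))
      decoy_sig / sum(e$significant) else 0
  }
  list(mean_bias = mean(bias), mean_sensitivity = mean(sens),
       mean_fdp = mean(fdp),
       planted_detection_rate = mean(planted_fdr <= alpha),
       mean_enrichment_fdp = mean(enr_fdp),
       enrichment_fdp_se = stats::sd(enr_fdp) / sqrt(n_runs),
       bias = bias, sensitivity = sens, fdp = fdp,
       planted_fdr = planted_fdr, enrichment_fdp = enr_fdp)
}
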