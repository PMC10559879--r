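test_that("the generator is deterministic given the seed", {
  cfg <- simulation_config(seed = 99, n_proteins = 30)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$peptides, b$peptides)
  expect_identical(a$truth, b$truth)
  expect_identical(a$gene_sets, b$gene_sets)
  c_ <- simulate_experiment(simulation_config(seed = 100, n_proteins = 30))
  expect_false(identical(a$peptides$proteome$ch01,
                         c_$peptides$proteome$ch01))
})

test_that("no noise and no effects is a fixed point: every fold change is 0", {
  cfg <- simulation_config(seed = 5, n_proteins = 25, noise_sd = 0,
                           missing_rate = 0, prop_protein_affected = 0,
                           prop_ox_affected = 0, prop_phospho_affected = 0,
                           planted_effect_prob = 0)
  sim <- simulate_experiment(cfg)
  for (ql in c("proteome", "ox_all", "ox_rev", "phospho")) {
    src <- oxidiff:::quant_layer_source(ql)$layer
    rec <- correct_impurities(sim$peptides[[src]], sim$impurity[[src]])
    q <- rollup_sites(rec, sim$design, ql)
    for (tp in cfg$timepoints) {
      fc <- compute_fold_changes(q, tp)
      expect_lt(max(abs(unclass(fc)), na.rm = TRUE), 1e-9)
    }
  }
})

test_that("noise-free label-stage pair reconstructs one abundance per sample", {
  cfg <- simulation_config(seed = 8, n_proteins = 25, noise_sd = 0,
                           missing_rate = 0, multi_cys_peptide_prob = 0,
                           irreversible_fraction = 0,
                           prop_protein_affected = 0,
                           planted_effect_prob = 0,
                           prop_ox_affected = 0.5,
                           layers = c("proteome", "redoxome"))
  sim <- simulate_experiment(cfg)
  rec <- correct_impurities(sim$peptides$redoxome, sim$impurity$redoxome)
  q1 <- rollup_sites(rec, sim$design, "ox_all")
  q2 <- rollup_sites(rec, sim$design, "ox_rev")
  total <- unclass(q1) + unclass(q2) # abundance x peptide efficiency
  # fractions moved (ox effects planted) but the pair sum is treatment-free
  tr <- total[, grepl("treated", colnames(total))]
  ct <- total[, grepl("control", colnames(total))]
  expect_equal(tr, ct, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("null p-values are uniform in a single large run", {
  cfg <- simulation_config(seed = 17, n_proteins = 1200,
                           peptides_per_protein = 1,
                           prop_protein_affected = 0,
                           planted_effect_prob = 0, layers = "proteome")
  sim <- simulate_experiment(cfg)
  rec <- suppressMessages(
    correct_impurities(sim$peptides$proteome, sim$impurity$proteome))
  q <- rollup_sites(rec, sim$design, "proteome")
  d <- differential_layer(q, "4h")
  ks <- suppressWarnings(stats::ks.test(d$result$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-layer null calibration holds for the PTM layers too", {
  cfg <- simulation_config(seed = 23, n_proteins = 250,
                           cys_sites_per_protein = 2,
                           phospho_sites_per_protein = 2,
                           prop_protein_affected = 0, prop_ox_affected = 0,
                           prop_phospho_affected = 0,
                           planted_effect_prob = 0)
  sim <- simulate_experiment(cfg)
  design <- sim$design
  qp <- rollup_sites(suppressMessages(
    correct_impurities(sim$peptides$proteome, sim$impurity$proteome)),
    design, "proteome")
  pfc <- suppressMessages(
    differential_layer(qp, "4h"))$fc
  for (ql in c("ox_all", "ox_rev", "phospho")) {
    src <- oxidiff:::quant_layer_source(ql)$layer
    q <- rollup_sites(suppressMessages(
      correct_impurities(sim$peptides[[src]], sim$impurity[[src]])),
      design, ql)
    d <- suppressMessages(differential_layer(q, "4h", protein_fc = pfc))
    ks <- suppressWarnings(stats::ks.test(d$result$p, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_lt(mean(d$result$significant), 0.02)
  }
})

test_that("planted oxidation effects propagate with the expected signs", {
  cfg <- simulation_config(seed = 12, n_proteins = 80, noise_sd = 0,
                           missing_rate = 0, multi_cys_peptide_prob = 0,
                           prop_protein_affected = 0,
                           planted_effect_prob = 0, prop_ox_affected = 0.4,
                           layers = c("proteome", "redoxome"))
  sim <- simulate_experiment(cfg)
  rec <- correct_impurities(sim$peptides$redoxome, sim$impurity$redoxome)
  tp <- "4h"
  truth <- sim$truth$ox_sites
  up <- truth$entity[truth[[paste0("delta_", tp)]] > 0]
  # TMT2 fold change positive for sites with increased oxidation
  q2 <- rollup_sites(rec, sim$design, "ox_rev")
  fc2 <- compute_fold_changes(q2, tp)
  expect_true(all(unclass(fc2)[up, ] > 0))
  # TMT1 fold change negative (less free thiol), positive after inversion
  q1 <- rollup_sites(rec, sim$design, "ox_all")
  fc1 <- compute_fold_changes(q1, tp)
  expect_true(all(unclass(fc1)[up, ] < 0))
  inv <- invert_overall_oxidation(fc1)
  expect_true(all(unclass(inv)[up, ] > 0))
})

test_that("truth_report returns zero bias for perfect estimates", {
  cfg <- simulation_config(seed = 14, n_proteins = 40, layers = "proteome")
  sim <- simulate_experiment(cfg)
  tt <- true_log2fc(sim$truth, "proteome", "4h")
  res <- make_result(tt$entity, tt$true_log2fc, tt$true_log2fc != 0)
  rep_ <- truth_report(sim$truth, res)
  expect_equal(rep_$bias_all, 0)
  expect_equal(rep_$rmse, 0)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$fdp, 0)
  # global-null variant: no affected entities, sensitivity undefined
  res0 <- make_result(tt$entity, rep(0, nrow(tt)), rep(FALSE, nrow(tt)))
  sim0 <- simulate_experiment(
    simulation_config(seed = 14, n_proteins = 40,
                      prop_protein_affected = 0, planted_effect_prob = 0,
                      layers = "proteome"))
  rep0 <- truth_report(sim0$truth, res0)
  expect_true(is.na(rep0$sensitivity))
  expect_equal(rep0$fdp, 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(missing_rate = 1), "rates")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  cfg <- simulation_config(seed = 1, n_proteins = 3,
                           cys_sites_per_protein = 1e-9)
  expect_error(simulate_experiment(cfg), "no cysteine sites")
})
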