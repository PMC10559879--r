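test_that("fold changes are mix-internal log2 ratios with the zero rule", {
  design <- tiny_design("proteome")
  x <- data.frame(
    mix_id = c("prot_r01", "prot_r02"),
    protein_accession = "P1", peptide_sequence = "AAK", sites = "",
    ch01 = c(100, 100), ch02 = c(200, 100),
    ch03 = c(50, 0), ch04 = c(25, 80), stringsAsFactors = FALSE)
  attr(x, "channels") <- paste0("ch0", 1:4)
  q <- rollup_sites(x, design, "proteome")
  fc4 <- compute_fold_changes(q, "4h")
  expect_equal(unname(unclass(fc4)["P1", ]), c(1, 0)) # 200/100, 100/100
  expect_message(fc24 <- compute_fold_changes(q, "24h"), "zero")
  expect_equal(unname(unclass(fc24)["P1", "r01"]), -1) # 25/50
  expect_true(is.na(unclass(fc24)["P1", "r02"])) # control 0 -> missing
  expect_error(compute_fold_changes(q, "48h"), "not in design")
})

test_that("replicate filter keeps entities observed at least k times", {
  v <- rbind(c(1, 2, NA, NA), c(1, 2, 3, NA), c(1, NA, NA, NA))
  fc <- make_fc(v)
  expect_equal(rownames(filter_min_replicates(fc, 3)), "P00002")
  expect_equal(nrow(filter_min_replicates(fc, 2)), 2L)
  expect_equal(nrow(filter_min_replicates(fc, 1)), 3L)
})

test_that("median normalization centers each replicate column", {
  fc <- make_fc(cbind(c(1.0, 0.5, -0.5)))
  out <- median_normalize(fc)
  expect_equal(unname(unclass(out)[, 1]), c(0.5, 0.0, -1.0))
  # idempotent on centered data
  expect_equal(unclass(median_normalize(out)), unclass(out))
  # single entity column becomes 0
  one <- median_normalize(make_fc(cbind(3.7)))
  expect_equal(unname(unclass(one)[1, 1]), 0)
  # all-missing column is left untouched
  v <- cbind(c(1, 2, 3), NA_real_)
  expect_message(out2 <- median_normalize(make_fc(v)), "all-missing")
  expect_true(all(is.na(unclass(out2)[, 2])))
  expect_equal(unname(apply(unclass(out2), 2, median, na.rm = TRUE)[1]), 0)
})

test_that("free-thiol inversion flips signs once and only for ox_all", {
  fc <- make_fc(cbind(c(0.5, 0, -0.2)), layer = "ox_all")
  inv <- invert_overall_oxidation(fc)
  expect_equal(unname(unclass(inv)[, 1]), c(-0.5, 0, 0.2))
  expect_true(attr(inv, "inverted"))
  expect_error(invert_overall_oxidation(inv), "already inverted")
  # forced double inversion is the identity
  back <- invert_overall_oxidation(inv, force = TRUE)
  expect_equal(unclass(back), unclass(fc))
  expect_error(invert_overall_oxidation(make_fc(cbind(1), layer = "ox_rev")),
               "ox_all")
})

test_that("site-to-protein normalization subtracts matched replicate values", {
  site <- make_fc(rbind(P00001_C10 = c(1.2, 0.5), P00009_S5 = c(1, 1)),
                  layer = "phospho")
  prot <- make_fc(rbind(P00001 = c(1.0, 0.5)), layer = "proteome")
  expect_message(out <- normalize_site_to_protein(site, prot), "dropped 1")
  expect_equal(unname(unclass(out)["P00001_C10", ]), c(0.2, 0.0))
  expect_equal(attr(out, "n_dropped"), 1L)
  # an inverted layer adds the protein value so pure abundance cancels
  site_inv <- make_fc(rbind(P00001_C10 = c(-1.0, -0.5)), layer = "ox_all",
                      inverted = TRUE)
  out2 <- normalize_site_to_protein(site_inv, prot)
  expect_equal(unname(unclass(out2)[1, ]), c(0, 0))
  expect_error(normalize_site_to_protein(prot, prot), "PTM layer")
})

test_that("protein value missing in a replicate propagates to the site", {
  site <- make_fc(rbind(P00001_C10 = c(1.2, 0.5, 0.3)), layer = "ox_rev")
  prot <- make_fc(rbind(P00001 = c(1.0, NA, 0.1)), layer = "proteome")
  out <- normalize_site_to_protein(site, prot)
  expect_true(is.na(unclass(out)[1, 2]))
  expect_equal(unname(unclass(out)[1, c(1, 3)]), c(0.2, 0.2))
})

test_that("one-sample t test matches the closed-form df=2 case", {
  fc <- make_fc(rbind(A = c(0.5, 0.7, 0.9)))
  res <- test_differential(fc)
  t_exp <- 0.7 / (0.2 / sqrt(3))
  expect_equal(res$t_stat, t_exp, tolerance = 1e-12)
  expect_equal(res$t_stat, 6.062, tolerance = 1e-4)
  # closed form of the t CDF for df = 2: F(t) = 1/2 (1 + t / sqrt(2 + t^2))
  p_exp <- 2 * (1 - 0.5 * (1 + t_exp / sqrt(2 + t_exp^2)))
  expect_equal(res$p, p_exp, tolerance = 1e-12)
  expect_equal(res$p, 0.0262, tolerance = 1e-2)
  expect_equal(res$n, 3L)
})

test_that("zero-variance entities are excluded from the adjustment", {
  fc <- make_fc(rbind(A = c(0, 0, 0), B = c(0.5, 0.7, 0.9)))
  expect_message(res <- test_differential(fc), "zero-variance")
  expect_true(is.na(res$p[res$entity == "A"]))
  expect_true(is.na(res$fdr[res$entity == "A"]))
  expect_false(res$significant[res$entity == "A"])
  # BH family excludes the undefined p-value
  expect_equal(res$fdr[res$entity == "B"], res$p[res$entity == "B"])
})

test_that("BH adjustment matches the hand-derived three-entity example", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
})

test_that("t p-values and BH agree with independent oracles across n and cases", {
  set.seed(11)
  for (n in 3:12) {
    v <- matrix(rnorm(5 * n, mean = 0.3, sd = 0.5), nrow = 5)
    res <- test_differential(make_fc(v))
    for (i in 1:5) {
      expect_equal(res$p[i], t_pvalue_integral(res$t_stat[i], n - 1),
                   tolerance = 1e-9)
    }
    expect_equal(res$fdr, bh_oracle(res$p), tolerance = 1e-12)
  }
})

test_that("entity order does not change any statistic", {
  set.seed(5)
  v <- matrix(rnorm(60), nrow = 10,
              dimnames = list(sprintf("P%05d", 1:10), NULL))
  res <- test_differential(median_normalize(make_fc(v)))
  perm <- sample(10)
  res2 <- test_differential(median_normalize(make_fc(v[perm, ])))
  res2 <- res2[match(res$entity, res2$entity), ]
  expect_equal(res2$p, res$p)
  expect_equal(res2$fdr, res$fdr)
  expect_equal(res2$log2fc_mean, res$log2fc_mean)
})

test_that("direction counts use strict inequalities", {
  res <- make_result(c("A", "B", "C", "D"),
                     log2fc_mean = c(1, -1, 0, 2),
                     significant = c(TRUE, TRUE, TRUE, FALSE))
  expect_message(cnt <- summarize_counts(res), "neither")
  expect_equal(cnt$n_up, 1L)
  expect_equal(cnt$n_down, 1L)
  none <- make_result("A", 1, FALSE)
  cnt2 <- summarize_counts(none)
  expect_equal(c(cnt2$n_up, cnt2$n_down), c(0L, 0L))
})
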