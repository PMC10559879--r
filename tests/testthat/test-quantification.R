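test_that("identity impurity matrix leaves intensities unchanged", {
  x <- toy_redox_records()
  m <- default_impurity_matrix(paste0("ch0", 1:4), leakage = 0)
  y <- correct_impurities(x, m)
  expect_equal(y$ch01, x$ch01)
  expect_equal(y$ch04, x$ch04)
})

test_that("2x2 impurity correction solves the hand-derived cases", {
  m <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  x <- data.frame(mix_id = "m1", protein_accession = "P1",
                  peptide_sequence = "ACDK", sites = "",
                  a = c(0.9, 0.1), b = c(0.1, 0.9),
                  stringsAsFactors = FALSE)
  attr(x, "channels") <- c("a", "b")
  y <- correct_impurities(x, m)
  expect_equal(y$a, c(1, 0), tolerance = 1e-12)
  expect_equal(y$b, c(0, 1), tolerance = 1e-12)
})

test_that("correction inverts forward mixing and respects missingness", {
  set.seed(42)
  channels <- paste0("ch0", 1:4)
  m <- default_impurity_matrix(channels, leakage = 0.03)
  true <- matrix(stats::runif(40, 10, 1000), nrow = 10,
                 dimnames = list(NULL, channels))
  observed <- true %*% t(m)
  # punch in missing values after mixing (identification failures)
  observed[1, 2] <- NA
  observed[5, c(1, 4)] <- NA
  x <- data.frame(mix_id = "m1", protein_accession = "P1",
                  peptide_sequence = "ACDK", sites = "",
                  observed, stringsAsFactors = FALSE, check.names = FALSE)
  attr(x, "channels") <- channels
  y <- correct_impurities(x, m)
  v <- as.matrix(y[channels])
  # missing stays missing
  expect_true(is.na(v[1, 2]) && all(is.na(v[5, c(1, 4)])))
  # fully observed rows recover the true signal within 1e-9 relative
  full <- setdiff(1:10, c(1, 5))
  expect_equal(v[full, ], true[full, ], tolerance = 1e-9)
  # re-applying the forward matrix reproduces the observed values
  expect_equal(v[full, ] %*% t(m), observed[full, ], tolerance = 1e-9)
})

test_that("negative corrected intensities are clipped to zero and counted", {
  m <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  # observed vector impossible under the forward model -> negative solve
  x <- data.frame(mix_id = "m1", protein_accession = "P1",
                  peptide_sequence = "ACDK", sites = "",
                  a = 0.05, b = 1, stringsAsFactors = FALSE)
  attr(x, "channels") <- c("a", "b")
  expect_message(y <- correct_impurities(x, m), "clipped")
  expect_equal(y$a, 0)
  expect_equal(attr(y, "n_clipped"), 1L)
})

test_that("impurity matrix validation rejects malformed matrices", {
  bad <- matrix(c(0.9, 0.3, 0.3, 0.9), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(validate_impurity_matrix(bad), "column sums")
  sing <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(validate_impurity_matrix(sing), "singular")
})

test_that("site rollup sums all peptide isoforms carrying a site", {
  design <- tiny_design()
  x <- toy_redox_records()
  q <- rollup_sites(x, design, "ox_all") # TMT1 channels: ch01, ch03
  # peptide 1 carries C152 and C156 (100), peptide 2 carries C152 (50)
  expect_equal(unname(q["P10001_C152", "r01_4h_control"]), 150)
  expect_equal(unname(q["P10001_C156", "r01_4h_control"]), 100)
  expect_equal(unname(q["P10002_C31", "r01_4h_treated"]), 10)
  # samples from the other replicate/timepoint are missing
  expect_true(is.na(q["P10002_C31", "r02_24h_control"]))

  # TMT2 stage feeds ox_rev with different values
  q2 <- rollup_sites(x, design, "ox_rev")
  expect_equal(unname(q2["P10001_C152", "r01_4h_control"]), 30)
  expect_equal(unname(q2["P10002_C31", "r01_4h_control"]), 40)
})

test_that("rollup skips missing channel values and keeps unobserved sites missing", {
  design <- tiny_design()
  x <- toy_redox_records()
  x$ch01[2] <- NA # peptide 2 (C152) missing in control TMT1
  q <- rollup_sites(x, design, "ox_all")
  expect_equal(unname(q["P10001_C152", "r01_4h_control"]), 100)
  x$ch01[1] <- NA # now no observed peptide for C156 in that sample
  q2 <- rollup_sites(x, design, "ox_all")
  expect_true(is.na(q2["P10001_C156", "r01_4h_control"]))
})

test_that("rollup conserves total intensity weighted by site multiplicity", {
  design <- tiny_design()
  x <- toy_redox_records()
  q <- rollup_sites(x, design, "ox_all")
  n_sites <- lengths(strsplit(x$sites, ";"))
  expect_equal(sum(q[, "r01_4h_control"], na.rm = TRUE),
               sum(x$ch01 * n_sites))
  # permutation invariance
  q_perm <- rollup_sites(x[c(3, 1, 2), ], design, "ox_all")
  expect_equal(unclass(q_perm), unclass(q))
})

test_that("proteome rollup aggregates peptides per protein", {
  design <- tiny_design()
  x <- data.frame(
    mix_id = "prot_r01",
    protein_accession = c("P1", "P1", "P2"),
    peptide_sequence = c("AAK", "CCK", "DDK"),
    sites = "",
    ch01 = c(10, 20, 5), ch02 = c(1, 2, 3),
    ch03 = c(0, 0, 0), ch04 = c(4, 5, 6), stringsAsFactors = FALSE)
  attr(x, "channels") <- paste0("ch0", 1:4)
  q <- rollup_sites(x, design, "proteome")
  expect_equal(unname(q["P1", "r01_4h_control"]), 30)
  expect_equal(unname(q["P2", "r01_4h_control"]), 5)
  expect_equal(nrow(q), 2L)
})
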