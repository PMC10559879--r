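# Small in-code fixtures shared across test files.

# A 2-replicate single-run design covering all three layers.
tiny_design <- function(layers = c("proteome", "redoxome", "phospho")) {
  default_design(n_runs = 1L, reps_per_run = 2L,
                 timepoints = c("4h", "24h"), layers = layers)
}

# Hand-built redoxome peptide records for one mix of tiny_design().
# Channels ch01..ch04 = (control TMT1, control TMT2, treated TMT1,
# treated TMT2) for replicate 1 at 4h.
toy_redox_records <- function() {
  x <- data.frame(
    mix_id = "redox_r01_4h",
    protein_accession = c("P10001", "P10001", "P10002"),
    peptide_sequence = c("ACDEFCK", "MCNPQR", "WYCSTV"),
    sites = c("C152;C156", "C152", "C31"),
    ch01 = c(100, 50, 10), ch02 = c(20, 10, 40),
    ch03 = c(100, 50, 10), ch04 = c(20, 10, 40),
    stringsAsFactors = FALSE)
  attr(x, "channels") <- paste0("ch0", 1:4)
  x
}

# Build an fc_matrix directly (bypassing rollup) for unit tests of the
# statistical chain.
make_fc <- function(values, layer = "proteome", timepoint = "4h",
                    inverted = FALSE) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("r%02d", seq_len(ncol(values)))
  }
  oxidiff:::fc_matrix(values, layer, timepoint, inverted = inverted)
}

# Minimal DifferentialResult for dynamics/overlap tests.
make_result <- function(entity, log2fc_mean, significant,
                        layer = "proteome", timepoint = "4h") {
  data.frame(entity = entity, layer = layer, timepoint = timepoint,
             n = 12L, log2fc_mean = log2fc_mean, t_stat = NA_real_,
             p = NA_real_, fdr = ifelse(significant, 0.01, 0.5),
             significant = significant, direction = sign(log2fc_mean),
             stringsAsFactors = FALSE)
}
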