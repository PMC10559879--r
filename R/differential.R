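# Mix-internal fold changes, triplicate filter, median normalization,
# free-thiol sign inversion, PTM-to-protein normalization, one-sample t test
# with Benjamini-Hochberg correction.

fc_matrix <- function(values, layer, timepoint, inverted = FALSE,
                      normalized = FALSE) {
  structure(values, layer = layer, timepoint = timepoint,
            inverted = inverted, normalized = normalized,
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("fc_matrix [", attr(x, "layer"), ", ", attr(x, "timepoint"), "]: ",
      nrow(x), " entities x ", ncol(x), " replicates",
      if (isTRUE(attr(x, "inverted"))) ", inverted", "\n", sep = "")
  invisible(x)
}

# Subsetting keeps the fold-change metadata.
#' @export
`[.fc_matrix` <- function(x, i, j, ..., drop = FALSE) {
  v <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(v)) {
    fc_matrix(v, attr(x, "layer"), attr(x, "timepoint"),
              attr(x, "inverted"), attr(x, "normalized"))
  } else v
}

#' Compute mix-internal treated-vs-control log2 fold changes
#'
#' For every entity and biological replicate, the log2 ratio of the treated
#' over the control intensity measured inside the same TMT mix at the given
#' time point. Ratios are only formed when both sides are observed and
#' strictly positive; zeros and missing values both invalidate the
#' replicate's ratio (no imputation). Time points are independent contrasts.
#'
#' @param q a `quant_matrix` from [rollup_sites()].
#' @param timepoint time point label, e.g. `"4h"`.
#' @return an `fc_matrix`: entities x replicates of log2 fold changes with
#'   attributes `layer` and `timepoint`.
#' @export
compute_fold_changes <- function(q, timepoint) {
  samples <- attr(q, "samples")
  if (!timepoint %in% samples$timepoint) {
    stop("time point not in design: ", timepoint, call. = FALSE)
  }
  s <- samples[samples$timepoint == timepoint, ]
  trt <- s[s$treatment == "treated", ]
  ctl <- s[s$treatment == "control", ]
  reps <- sort(intersect(trt$replicate_global, ctl$replicate_global))
  tcol <- trt$sample_id[match(reps, trt$replicate_global)]
  ccol <- ctl$sample_id[match(reps, ctl$replicate_global)]
  tv <- unclass(q)[, tcol, drop = FALSE]
  cv <- unclass(q)[, ccol, drop = FALSE]
  valid <- !is.na(tv) & !is.na(cv) & tv > 0 & cv > 0
  v <- matrix(NA_real_, nrow = nrow(q), ncol = length(reps),
              dimnames = list(rownames(q), sprintf("r%02d", reps)))
  v[valid] <- log2(tv[valid] / cv[valid])
  n_zero <- sum((!is.na(tv) & tv == 0) | (!is.na(cv) & cv == 0))
  if (n_zero > 0) {
    message("compute_fold_changes: ", n_zero,
            " ratios dropped due to zero intensities")
  }
  fc_matrix(v, attr(q, "layer"), timepoint)
}

#' Keep entities quantified in at least k replicates
#'
#' The reliability filter: only entities whose fold change was observed in at
#' least `k` replicates (default 3, i.e. at least in triplicate) are retained
#' for testing.
#'
#' @param fc an `fc_matrix`.
#' @param k minimum number of non-missing replicate fold changes; `k = 1`
#'   keeps every observed entity.
#' @return filtered `fc_matrix`.
#' @export
filter_min_replicates <- function(fc, k = 3L) {
  stopifnot(k >= 1L)
  keep <- rowSums(!is.na(fc)) >= k
  fc[keep, , drop = FALSE]
}

#' Median-normalize replicate fold-change columns
#'
#' Subtracts each replicate column's median over entities, centering every
#' replicate's log2 ratio distribution at 0. Columns with no observed values
#' are left untouched.
#'
#' @param fc an `fc_matrix` (already on the log2 scale).
#' @return normalized `fc_matrix`; every non-empty column has median 0.
#' @export
median_normalize <- function(fc) {
  v <- unclass(fc)
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  empty <- !is.finite(med)
  if (any(empty)) {
    message("median_normalize: ", sum(empty),
            " all-missing column(s) left untouched")
    med[empty] <- 0
  }
  v <- sweep(v, 2, med)
  fc_matrix(v, attr(fc, "layer"), attr(fc, "timepoint"),
            attr(fc, "inverted"), normalized = TRUE)
}

#' Invert free-thiol (TMT1) fold changes to an oxidation scale
#'
#' TMT1 reporter intensities label free thiols, so a positive log2 fold
#' change means more reduced cysteine under treatment. Negating every value
#' puts the overall-oxidation layer on the same "positive = more oxidized"
#' scale as the reversible-oxidation layer. The inversion is recorded in a
#' provenance flag and refuses to run twice unless `force = TRUE`.
#'
#' @param fc an `fc_matrix` with layer `ox_all`.
#' @param force bypass the provenance check (e.g. to undo an inversion).
#' @return inverted `fc_matrix`.
#' @export
invert_overall_oxidation <- function(fc, force = FALSE) {
  if (!identical(attr(fc, "layer"), "ox_all")) {
    stop("inversion applies only to the ox_all (TMT1) layer, got ",
         attr(fc, "layer"), call. = FALSE)
  }
  if (isTRUE(attr(fc, "inverted")) && !force) {
    stop("ox_all fold changes are already inverted", call. = FALSE)
  }
  fc_matrix(-unclass(fc), "ox_all", attr(fc, "timepoint"),
            inverted = !isTRUE(attr(fc, "inverted")),
            normalized = attr(fc, "normalized"))
}

#' Normalize modification-site fold changes to protein-level changes
#'
#' Removes the abundance component from a PTM layer replicate-wise: for each
#' site and replicate the parent protein's log2 fold change in the same
#' replicate is subtracted, so what remains reflects the change in
#' modification rather than in protein amount. For an already sign-inverted
#' layer (`ox_all`) the protein value is added instead — algebraically the
#' same as normalizing before inversion — so a pure abundance change still
#' cancels exactly. Sites are missing in replicates where the parent protein
#' is unquantified, and sites whose parent protein is absent from the
#' proteome are dropped.
#'
#' @param site_fc `fc_matrix` of a PTM layer (`ox_all`, `ox_rev`, `phospho`).
#' @param protein_fc `fc_matrix` of the proteome layer at the same time
#'   point.
#' @return normalized `fc_matrix`; attribute `n_dropped` counts sites whose
#'   parent protein was not quantified.
#' @export
normalize_site_to_protein <- function(site_fc, protein_fc) {
  if (attr(site_fc, "layer") == "proteome") {
    stop("site_fc must be a PTM layer", call. = FALSE)
  }
  if (attr(protein_fc, "layer") != "proteome") {
    stop("protein_fc must be the proteome layer", call. = FALSE)
  }
  if (!identical(attr(site_fc, "timepoint"), attr(protein_fc, "timepoint"))) {
    stop("site and protein fold changes must share a time point",
         call. = FALSE)
  }
  parents <- parent_accession(rownames(site_fc))
  present <- parents %in% rownames(protein_fc)
  n_dropped <- sum(!present)
  if (n_dropped > 0) {
    message("normalize_site_to_protein: dropped ", n_dropped,
            " site(s) whose parent protein is not in the proteome")
  }
  sv <- unclass(site_fc)[present, , drop = FALSE]
  parents <- parents[present]
  reps <- intersect(colnames(site_fc), colnames(protein_fc))
  pv <- unclass(protein_fc)[parents, reps, drop = FALSE]
  sv <- sv[, reps, drop = FALSE]
  sgn <- if (isTRUE(attr(site_fc, "inverted"))) 1 else -1
  out <- sv + sgn * pv # NA protein value propagates to the site
  res <- fc_matrix(out, attr(site_fc, "layer"), attr(site_fc, "timepoint"),
                   attr(site_fc, "inverted"), attr(site_fc, "normalized"))
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Test replicate log2 fold changes against zero
#'
#' Per entity: two-sided one-sample Student t test of the replicate log2 fold
#' changes against 0 (df = n - 1), followed by Benjamini-Hochberg adjustment
#' across all tested entities of the layer x time point. Entities with zero
#' variance across replicates get an undefined p-value and are excluded from
#' the adjustment.
#'
#' @param fc filtered, normalized `fc_matrix` (every entity with n >= 2).
#' @param alpha FDR significance threshold.
#' @return a `DifferentialResult` data.frame with columns `entity`, `layer`,
#'   `timepoint`, `n`, `log2fc_mean`, `t_stat`, `p`, `fdr`, `significant`,
#'   `direction`.
#' @export
test_differential <- function(fc, alpha = 0.05) {
  v <- unclass(fc)
  if (nrow(v) == 0) stop("no entities to test", call. = FALSE)
  n <- rowSums(!is.na(v))
  mean_fc <- rowMeans(v, na.rm = TRUE)
  centered <- v - mean_fc
  ss <- rowSums(centered^2, na.rm = TRUE)
  sd_fc <- sqrt(ss / pmax(n - 1, 1))
  zero_var <- sd_fc <= 0 | n < 2
  t_stat <- ifelse(zero_var, NA_real_, mean_fc / (sd_fc / sqrt(n)))
  p <- ifelse(zero_var, NA_real_,
              2 * stats::pt(-abs(t_stat), df = n - 1))
  if (any(zero_var)) {
    message("test_differential: ", sum(zero_var),
            " zero-variance entities excluded from adjustment")
  }
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  res <- data.frame(
    entity = rownames(v),
    layer = attr(fc, "layer"),
    timepoint = attr(fc, "timepoint"),
    n = as.integer(n),
    log2fc_mean = mean_fc,
    t_stat = t_stat,
    p = p,
    fdr = fdr,
    significant = !is.na(fdr) & fdr <= alpha,
    direction = sign(mean_fc),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  res
}

#' Count significantly increased and decreased entities
#'
#' Increased means significant with mean log2 fold change strictly above 0,
#' decreased strictly below 0; a significant entity with mean exactly 0
#' counts in neither.
#'
#' @param res a `DifferentialResult` (possibly several layers/time points
#'   stacked with `rbind`).
#' @return data.frame with one row per (layer, timepoint): `n_tested`,
#'   `n_up`, `n_down`.
#' @export
summarize_counts <- function(res) {
  groups <- unique(res[c("layer", "timepoint")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- res[res$layer == groups$layer[i] &
               res$timepoint == groups$timepoint[i], ]
    n_zero <- sum(g$significant & g$log2fc_mean == 0)
    if (n_zero > 0) {
      message("summarize_counts: ", n_zero,
              " significant entities with mean exactly 0 counted in neither",
              " direction")
    }
    data.frame(layer = groups$layer[i], timepoint = groups$timepoint[i],
               n_tested = nrow(g),
               n_up = sum(g$significant & g$log2fc_mean > 0),
               n_down = sum(g$significant & g$log2fc_mean < 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
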