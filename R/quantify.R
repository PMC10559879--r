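# Reporter-ion impurity correction and peptide-isoform -> site rollup.

#' Validate a reporter-ion impurity matrix
#'
#' Entry (i, j) is the fraction of channel j's true signal observed in
#' channel i. Columns must sum to at most 1 (isotope spill cannot create
#' signal), diagonal entries must be positive, and the matrix must be well
#' conditioned enough to invert.
#'
#' @param m square numeric matrix with identical row/column channel names.
#' @return the matrix, invisibly validated.
#' @export
validate_impurity_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("impurity matrix needs identical channel row/column names",
         call. = FALSE)
  }
  if (any(m < 0)) stop("impurity fractions must be >= 0", call. = FALSE)
  if (any(colSums(m) > 1 + 1e-6)) {
    stop("impurity matrix column sums exceed 1", call. = FALSE)
  }
  if (any(diag(m) <= 0)) {
    stop("impurity matrix diagonal must be positive", call. = FALSE)
  }
  k <- kappa(m, exact = TRUE)
  if (!is.finite(k) || k > 1e12) {
    stop("impurity matrix is singular or ill-conditioned", call. = FALSE)
  }
  m
}

#' Default impurity matrix with nearest-neighbour isotope leakage
#'
#' A simple symmetric spill model: each channel leaks `leakage` of its signal
#' into each adjacent channel; the diagonal absorbs the remainder so columns
#' sum to 1.
#'
#' @param channels ordered channel ids.
#' @param leakage fraction leaked to each neighbouring channel.
#' @return impurity matrix.
#' @export
default_impurity_matrix <- function(channels, leakage = 0.02) {
  k <- length(channels)
  stopifnot(k >= 1, leakage >= 0, leakage < 0.5)
  m <- diag(k)
  if (k > 1 && leakage > 0) {
    for (j in seq_len(k)) {
      nb <- c(j - 1L, j + 1L)
      nb <- nb[nb >= 1L & nb <= k]
      m[nb, j] <- leakage
      m[j, j] <- 1 - leakage * length(nb)
    }
  }
  dimnames(m) <- list(channels, channels)
  validate_impurity_matrix(m)
}

#' Correct reporter-ion intensities for channel isotope impurity
#'
#' Replaces each record's observed channel vector o by the solution x of
#' M x = o, restricted to the observed channels (missing channels stay
#' missing; the solve uses the corresponding submatrix). Negative solutions
#' are clipped to 0 and counted.
#'
#' @param records peptide table (data.frame) as returned by
#'   [read_peptide_table()].
#' @param m impurity matrix covering all of the table's channels.
#' @return corrected peptide table; attribute `n_clipped` counts clipped
#'   negative solutions.
#' @export
correct_impurities <- function(records, m) {
  m <- validate_impurity_matrix(m)
  channels <- attr(records, "channels") %||%
    intersect(colnames(m), names(records))
  absent <- setdiff(channels, colnames(m))
  if (length(absent) > 0) {
    stop("channel(s) absent from impurity matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(records[channels])
  obs <- !is.na(x)
  pattern <- apply(obs, 1, function(b) paste(as.integer(b), collapse = ""))
  n_clipped <- 0L
  for (p in unique(pattern)) {
    rows <- which(pattern == p)
    idx <- which(obs[rows[1], ])
    if (length(idx) == 0) next
    sub <- m[channels[idx], channels[idx], drop = FALSE]
    if (!is.finite(kappa(sub, exact = TRUE)) ||
        kappa(sub, exact = TRUE) > 1e12) {
      stop("singular impurity submatrix for record row ", rows[1],
           " (channels ", paste(channels[idx], collapse = ","), ")",
           call. = FALSE)
    }
    corrected <- t(solve(sub, t(x[rows, idx, drop = FALSE])))
    neg <- corrected < 0
    n_clipped <- n_clipped + sum(neg)
    corrected[neg] <- 0
    x[rows, idx] <- corrected
  }
  if (n_clipped > 0) {
    message("correct_impurities: clipped ", n_clipped,
            " negative corrected intensities to 0")
  }
  records[channels] <- as.data.frame(x)
  attr(records, "channels") <- channels
  attr(records, "n_clipped") <- n_clipped
  records
}

quant_layer_source <- function(layer) {
  switch(layer,
         proteome = list(layer = "proteome", stage = NULL),
         ox_all   = list(layer = "redoxome", stage = "TMT1"),
         ox_rev   = list(layer = "redoxome", stage = "TMT2"),
         phospho  = list(layer = "phospho", stage = NULL),
         stop("unknown quantification layer: ", layer, call. = FALSE))
}

#' Roll peptide-isoform intensities up to site (or protein) intensities
#'
#' A modification site's intensity in a sample is the sum of the intensities
#' of all peptide isoforms containing the site; a peptide carrying k sites
#' contributes its full intensity to each of them (no apportioning — the data
#' carry no site-level stoichiometry). For the proteome layer the rollup
#' entity is the protein and all of its peptides are summed. Missing channel
#' values are skipped; a site with no observed peptide in a sample is
#' missing. Redoxome rollup draws only from the requested label stage: TMT1
#' channels feed `ox_all` (free thiols), TMT2 channels feed `ox_rev`
#' (reversibly oxidized thiols).
#'
#' @param records peptide table (one layer), impurity-corrected.
#' @param design validated SampleDesign.
#' @param layer one of `"proteome"`, `"ox_all"`, `"ox_rev"`, `"phospho"`.
#' @return a `quant_matrix`: entities x samples numeric matrix with
#'   attributes `layer` and `samples` (data.frame of sample_id, replicate,
#'   timepoint, treatment).
#' @export
rollup_sites <- function(records, design, layer = QUANT_LAYERS) {
  layer <- match.arg(layer)
  src <- quant_layer_source(layer)
  des <- design[design$layer == src$layer, ]
  if (!is.null(src$stage)) des <- des[des$label_stage == src$stage, ]
  if (nrow(des) == 0) {
    stop("design has no channels for layer ", layer, call. = FALSE)
  }
  reps_per_run <- attr(design, "reps_per_run") %||% max(design$replicate)
  des$replicate_global <- global_replicate(des$run, des$replicate,
                                           reps_per_run)
  des$sample_id <- sample_key(des$replicate_global, des$timepoint,
                              des$treatment)

  samples <- unique(des[c("sample_id", "replicate_global", "timepoint",
                          "treatment")])
  samples <- samples[order(samples$replicate_global, samples$timepoint,
                           samples$treatment), ]
  rownames(samples) <- NULL

  by_protein <- layer == "proteome"
  # Explode PTM rows so each (peptide, site) is one row.
  if (by_protein) {
    ent <- records$protein_accession
    rec <- records
  } else {
    keep <- nzchar(records$sites)
    rec <- records[keep, , drop = FALSE]
    if (nrow(rec) == 0) stop("no modified peptides to roll up", call. = FALSE)
    site_list <- strsplit(rec$sites, ";", fixed = TRUE)
    n_sites <- lengths(site_list)
    rec <- rec[rep(seq_len(nrow(rec)), n_sites), , drop = FALSE]
    ent <- entity_key(rec$protein_accession, unlist(site_list))
  }

  entities <- sort(unique(ent))
  out <- matrix(NA_real_, nrow = length(entities), ncol = nrow(samples),
                dimnames = list(entities, samples$sample_id))
  n_skipped <- 0L
  for (mx in unique(rec$mix_id)) {
    dmx <- des[des$mix_id == mx, ]
    if (nrow(dmx) == 0) { # mix carries no channels for this layer/stage
      n_skipped <- n_skipped + sum(rec$mix_id == mx)
      next
    }
    rows <- rec$mix_id == mx
    vals <- as.matrix(rec[rows, dmx$channel_id, drop = FALSE])
    mode(vals) <- "double"
    grp <- ent[rows]
    sums <- rowsum(ifelse(is.na(vals), 0, vals), grp)
    counts <- rowsum((!is.na(vals)) + 0, grp)
    sums[counts == 0] <- NA_real_
    out[rownames(sums), dmx$sample_id] <- sums
  }
  if (n_skipped > 0) {
    message("rollup_sites: skipped ", n_skipped,
            " records whose mix has no ", layer, " channels")
  }
  structure(out, layer = layer, samples = samples, class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix [", attr(x, "layer"), "]: ", nrow(x), " entities x ",
      ncol(x), " samples\n", sep = "")
  invisible(x)
}
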