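# Synthetic experiment generator. Emulates the study design (3 runs x 4
# replicates, two time points, paired treated/control samples inside every
# TMT mix, sequential-label redoxome channels) and the measurement model:
#   proteome signal  ~ abundance
#   TMT1 (free thiol) ~ abundance x (1 - oxidized fraction)
#   TMT2 (rev. oxid.) ~ abundance x oxidized fraction
#   phospho signal    ~ abundance x occupancy
# with per-peptide ionization efficiency, multiplicative log-normal noise per
# (peptide, channel), completely-at-random peptide dropout per mix, and
# forward channel-impurity mixing, so the analysis stages all have work to
# do. Every simulated entity has exactly one ground-truth record.

#' Simulation configuration
#'
#' Defaults mirror the study design: 3 runs of 4 replicates (12 biological
#' replicates), time points 4 h and 24 h, paired treated/control samples in
#' each mix, planted log2 effects of size 1 and measurement noise of 0.2
#' log2 units.
#'
#' @param seed integer RNG seed; the generator is deterministic given the
#'   seed.
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein Poisson mean of proteome peptides per protein
#'   (at least 1 is always generated).
#' @param cys_sites_per_protein Poisson mean of cysteine sites per protein.
#' @param phospho_sites_per_protein Poisson mean of phosphosites per protein.
#' @param multi_cys_peptide_prob probability that a cysteine site shares a
#'   peptide with the protein's previous cysteine site (exercises the
#'   multi-site rollup ambiguity).
#' @param n_runs,reps_per_run multiplexing design; defaults give 12
#'   replicates.
#' @param timepoints time point labels.
#' @param base_log2_abundance_mean,base_log2_abundance_sd log-normal protein
#'   abundance parameters (log2 scale).
#' @param peptide_efficiency_sd log2 sd of the per-peptide ionization factor
#'   (constant across channels, cancels in mix-internal ratios).
#' @param noise_sd log2 sd of multiplicative measurement noise per
#'   (peptide, channel).
#' @param missing_rate probability that a peptide is missing from a mix.
#' @param prop_protein_affected,prop_ox_affected,prop_phospho_affected
#'   fractions of entities with planted treatment effects.
#' @param effect_size planted effect magnitude in log2 units; signs are
#'   drawn at random per entity and time point.
#' @param ox_fraction_shape1,ox_fraction_shape2 Beta parameters of the
#'   baseline reversibly-oxidized fraction per cysteine (kept strictly
#'   inside (0, 1) so both label stages carry signal).
#' @param irreversible_fraction fraction of cysteine signal lost to
#'   irreversible oxidation (absent from both labels).
#' @param impurity_leakage nearest-neighbour channel leakage fraction of the
#'   forward impurity mixing.
#' @param n_gene_sets,gene_set_size decoy gene-set collection dimensions.
#' @param planted_effect_prob elevated protein-effect probability for
#'   members of the planted gene set (`SET_PLANTED`); decoy sets are drawn
#'   from non-planted genes so they are true nulls for enrichment.
#' @param layers layers to generate.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 300L,
                              peptides_per_protein = 2,
                              cys_sites_per_protein = 1.5,
                              phospho_sites_per_protein = 1,
                              multi_cys_peptide_prob = 0.25,
                              n_runs = 3L,
                              reps_per_run = 4L,
                              timepoints = c("4h", "24h"),
                              base_log2_abundance_mean = 20,
                              base_log2_abundance_sd = 2,
                              peptide_efficiency_sd = 1,
                              noise_sd = 0.2,
                              missing_rate = 0.1,
                              prop_protein_affected = 0.1,
                              prop_ox_affected = 0.1,
                              prop_phospho_affected = 0.1,
                              effect_size = 1,
                              ox_fraction_shape1 = 2,
                              ox_fraction_shape2 = 8,
                              irreversible_fraction = 0.05,
                              impurity_leakage = 0.02,
                              n_gene_sets = 20L,
                              gene_set_size = 15L,
                              planted_effect_prob = 0.8,
                              layers = LAYERS) {
  cfg <- as.list(environment())
  rates <- c(cfg$missing_rate, cfg$prop_protein_affected,
             cfg$prop_ox_affected, cfg$prop_phospho_affected,
             cfg$irreversible_fraction)
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)",
                                        call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$n_proteins < 1) stop("need at least one protein", call. = FALSE)
  cfg$layers <- match.arg(layers, LAYERS, several.ok = TRUE)
  class(cfg) <- "simulation_config"
  cfg
}

random_peptide_sequences <- function(n, min_len = 8L, max_len = 20L) {
  if (n == 0) return(character(0))
  lens <- sample(min_len:max_len, n, replace = TRUE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- sample(aa, sum(lens), replace = TRUE)
  idx <- factor(rep(seq_len(n), lens), levels = seq_len(n))
  vapply(split(chars, idx), paste0, "", collapse = "")
}

draw_effects <- function(n, prob, effect_size, timepoints) {
  affected <- stats::runif(n) < prob
  delta <- matrix(0, nrow = n, ncol = length(timepoints),
                  dimnames = list(NULL, timepoints))
  for (tp in timepoints) {
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    delta[affected, tp] <- effect_size * sgn[affected]
  }
  list(affected = affected, delta = delta)
}

# Assemble one layer's peptide table: carve the peptide x column intensity
# matrix into per-mix blocks, apply forward impurity mixing and per-mix
# dropout, and stack into the wide TSV layout the readers consume.
assemble_layer_table <- function(intensity, colkeys, des, pep_meta,
                                 missing_rate, impurity, colkey_fun) {
  mixes <- unique(des$mix_id)
  blocks <- vector("list", length(mixes))
  npep <- nrow(intensity)
  for (i in seq_along(mixes)) {
    dmx <- des[des$mix_id == mixes[i], ]
    vals <- intensity[, match(colkey_fun(dmx), colkeys), drop = FALSE]
    m <- impurity[dmx$channel_id, dmx$channel_id, drop = FALSE]
    vals <- vals %*% t(m)
    if (missing_rate > 0) {
      vals[stats::runif(npep) < missing_rate, ] <- NA_real_
    }
    colnames(vals) <- dmx$channel_id
    blocks[[i]] <- data.frame(mix_id = mixes[i],
                              protein_accession = pep_meta$accession,
                              peptide_sequence = pep_meta$sequence,
                              sites = pep_meta$sites,
                              vals, stringsAsFactors = FALSE,
                              check.names = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "channels") <- unique(des$channel_id)
  out
}

#' Simulate a complete synthetic experiment
#'
#' Generates the sample design, peptide-isoform quantification tables for the
#' requested layers, impurity matrices, a gene-set collection with one
#' planted set, an accession-to-gene mapping, a synthetic site-annotation
#' table, and the ground truth of every simulated entity. Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `design`, `peptides` (named list of layer
#'   tables), `impurity` (named list of matrices), `gene_sets`, `mapping`,
#'   `annotations`, `truth` (list of `proteins`, `ox_sites`,
#'   `phospho_sites`), `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tps <- config$timepoints
  n_reps <- config$n_runs * config$reps_per_run

  design <- default_design(config$n_runs, config$reps_per_run, tps,
                           config$layers)

  # --- proteins, genes, gene sets -------------------------------------
  acc <- sprintf("P%05d", seq_len(config$n_proteins))
  gene <- sprintf("GENE%04d", seq_len(config$n_proteins))
  mapping <- stats::setNames(gene, acc)

  set_size <- min(config$gene_set_size, max(1L, config$n_proteins %/% 4L))
  planted_genes <- sample(gene, set_size)
  decoy_pool <- setdiff(gene, planted_genes)
  sets <- list(SET_PLANTED = planted_genes)
  for (i in seq_len(max(0L, config$n_gene_sets - 1L))) {
    sets[[sprintf("SET_%02d", i)]] <- sample(decoy_pool,
                                             min(set_size,
                                                 length(decoy_pool)))
  }
  gene_sets <- gene_set_collection("synthetic_reactome", sets)

  # --- planted effects -------------------------------------------------
  in_planted <- gene %in% planted_genes
  prot_prob <- ifelse(in_planted, config$planted_effect_prob,
                      config$prop_protein_affected)
  prot_affected <- stats::runif(config$n_proteins) < prot_prob
  prot_delta <- matrix(0, config$n_proteins, length(tps),
                       dimnames = list(NULL, tps))
  for (tp in tps) {
    sgn <- sample(c(-1, 1), config$n_proteins, replace = TRUE)
    prot_delta[prot_affected, tp] <-
      config$effect_size * sgn[prot_affected]
  }
  base_ab <- stats::rnorm(config$n_proteins,
                          config$base_log2_abundance_mean,
                          config$base_log2_abundance_sd)

  truth_proteins <- data.frame(accession = acc, gene = gene,
                               in_planted = in_planted,
                               affected = prot_affected,
                               stringsAsFactors = FALSE)
  for (tp in tps) truth_proteins[[paste0("delta_", tp)]] <- prot_delta[, tp]

  # --- sample grid and abundance --------------------------------------
  grid <- expand.grid(treatment = c("control", "treated"), timepoint = tps,
                      replicate = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sample_id <- sample_key(grid$replicate, grid$timepoint,
                               grid$treatment)
  ab_log2 <- matrix(base_ab, nrow = config$n_proteins, ncol = nrow(grid))
  colnames(ab_log2) <- grid$sample_id
  for (tp in tps) {
    cols <- grid$timepoint == tp & grid$treatment == "treated"
    ab_log2[, cols] <- ab_log2[, cols] + prot_delta[, tp]
  }

  peptides <- list()
  impurity <- list()
  truth_ox <- NULL
  truth_ph <- NULL

  noisy <- function(log2_signal) {
    if (config$noise_sd > 0) {
      log2_signal <- log2_signal +
        stats::rnorm(length(log2_signal), 0, config$noise_sd)
    }
    2^log2_signal
  }

  # --- proteome layer ---------------------------------------------------
  if ("proteome" %in% config$layers) {
    n_pep <- pmax(1L, stats::rpois(config$n_proteins,
                                   config$peptides_per_protein))
    pep_acc_idx <- rep(seq_len(config$n_proteins), n_pep)
    npep <- length(pep_acc_idx)
    eff <- stats::rnorm(npep, 0, config$peptide_efficiency_sd)
    sig <- ab_log2[pep_acc_idx, , drop = FALSE] + eff
    intensity <- noisy(sig)
    des <- design[design$layer == "proteome", ]
    des$sample_id <- sample_key(global_replicate(des$run, des$replicate,
                                                 config$reps_per_run),
                                des$timepoint, des$treatment)
    impurity$proteome <- default_impurity_matrix(unique(des$channel_id),
                                                 config$impurity_leakage)
    meta <- data.frame(accession = acc[pep_acc_idx],
                       sequence = random_peptide_sequences(npep),
                       sites = "", stringsAsFactors = FALSE)
    peptides$proteome <- assemble_layer_table(
      intensity, grid$sample_id, des, meta, config$missing_rate,
      impurity$proteome, function(d) d$sample_id)
  }

  # --- redoxome layer ---------------------------------------------------
  if ("redoxome" %in% config$layers) {
    n_cys <- stats::rpois(config$n_proteins, config$cys_sites_per_protein)
    site_acc_idx <- rep(seq_len(config$n_proteins), n_cys)
    n_sites <- length(site_acc_idx)
    if (n_sites == 0) stop("infeasible config: no cysteine sites generated",
                           call. = FALSE)
    positions <- unlist(lapply(n_cys[n_cys > 0],
                               function(k) sort(sample.int(600L, k))))
    site_id <- format_site_id("C", positions)

    f_ctrl <- stats::rbeta(n_sites, config$ox_fraction_shape1,
                           config$ox_fraction_shape2)
    f_ctrl <- pmin(pmax(f_ctrl, 0.02), 0.9)
    ox <- draw_effects(n_sites, config$prop_ox_affected,
                       config$effect_size, tps)
    f_trt <- matrix(f_ctrl, n_sites, length(tps), dimnames = list(NULL, tps))
    for (tp in tps) {
      f_trt[, tp] <- pmin(f_ctrl * 2^ox$delta[, tp], 0.95)
    }

    # Group consecutive cysteines of a protein into shared peptides.
    pep_of_site <- integer(n_sites)
    pep_counter <- 0L
    for (i in seq_len(n_sites)) {
      same_prot <- i > 1 && site_acc_idx[i] == site_acc_idx[i - 1L]
      if (same_prot &&
          stats::runif(1) < config$multi_cys_peptide_prob) {
        pep_of_site[i] <- pep_counter
      } else {
        pep_counter <- pep_counter + 1L
        pep_of_site[i] <- pep_counter
      }
    }
    npep <- pep_counter
    pep_first_site <- match(seq_len(npep), pep_of_site)
    pep_acc_idx <- site_acc_idx[pep_first_site]

    # Site-level stage fractions per sample, averaged over each peptide's
    # sites to give the peptide's labeled-pool factor.
    frac <- matrix(f_ctrl, n_sites, nrow(grid))
    colnames(frac) <- grid$sample_id
    for (tp in tps) {
      cols <- grid$timepoint == tp & grid$treatment == "treated"
      frac[, cols] <- f_trt[, tp]
    }
    sites_per_pep <- tabulate(pep_of_site, npep)
    pep_frac_rev <- rowsum(frac, pep_of_site) / sites_per_pep
    pep_frac_free <- rowsum(1 - frac, pep_of_site) / sites_per_pep

    eff <- stats::rnorm(npep, 0, config$peptide_efficiency_sd)
    base <- ab_log2[pep_acc_idx, , drop = FALSE] + eff +
      log2(1 - config$irreversible_fraction)
    sig1 <- base + log2(pep_frac_free) # TMT1: free thiols
    sig2 <- base + log2(pep_frac_rev)  # TMT2: reversibly oxidized
    colkeys <- c(paste(grid$sample_id, "TMT1", sep = "|"),
                 paste(grid$sample_id, "TMT2", sep = "|"))
    intensity <- cbind(noisy(sig1), noisy(sig2))
    colnames(intensity) <- colkeys

    des <- design[design$layer == "redoxome", ]
    des$sample_id <- sample_key(global_replicate(des$run, des$replicate,
                                                 config$reps_per_run),
                                des$timepoint, des$treatment)
    impurity$redoxome <- default_impurity_matrix(unique(des$channel_id),
                                                 config$impurity_leakage)
    sites_str <- vapply(seq_len(npep), function(p) {
      paste(site_id[pep_of_site == p], collapse = ";")
    }, "")
    meta <- data.frame(accession = acc[pep_acc_idx],
                       sequence = random_peptide_sequences(npep),
                       sites = sites_str, stringsAsFactors = FALSE)
    peptides$redoxome <- assemble_layer_table(
      intensity, colkeys, des, meta, config$missing_rate,
      impurity$redoxome,
      function(d) paste(d$sample_id, d$label_stage, sep = "|"))

    truth_ox <- data.frame(accession = acc[site_acc_idx], site = site_id,
                           entity = entity_key(acc[site_acc_idx], site_id),
                           affected = ox$affected, f_ctrl = f_ctrl,
                           stringsAsFactors = FALSE)
    for (tp in tps) {
      truth_ox[[paste0("f_trt_", tp)]] <- f_trt[, tp]
      truth_ox[[paste0("delta_", tp)]] <- ox$delta[, tp]
      # Expected normalized log2FCs implied by the fractions.
      truth_ox[[paste0("true_log2fc_rev_", tp)]] <-
        log2(f_trt[, tp] / f_ctrl)
      truth_ox[[paste0("true_log2fc_all_", tp)]] <-
        -(log2(1 - f_trt[, tp]) - log2(1 - f_ctrl))
    }
  }

  # --- phospho layer ----------------------------------------------------
  if ("phospho" %in% config$layers) {
    n_ph <- stats::rpois(config$n_proteins,
                         config$phospho_sites_per_protein)
    site_acc_idx <- rep(seq_len(config$n_proteins), n_ph)
    n_sites <- length(site_acc_idx)
    if (n_sites == 0) stop("infeasible config: no phosphosites generated",
                           call. = FALSE)
    positions <- unlist(lapply(n_ph[n_ph > 0],
                               function(k) sort(sample.int(600L, k))))
    residue <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                      prob = c(0.83, 0.155, 0.015))
    site_id <- format_site_id(residue, positions)
    occ <- stats::runif(n_sites, 0.05, 0.5)
    ph <- draw_effects(n_sites, config$prop_phospho_affected,
                       config$effect_size, tps)

    occ_log2 <- matrix(log2(occ), n_sites, nrow(grid))
    colnames(occ_log2) <- grid$sample_id
    for (tp in tps) {
      cols <- grid$timepoint == tp & grid$treatment == "treated"
      occ_log2[, cols] <- occ_log2[, cols] + ph$delta[, tp]
    }
    eff <- stats::rnorm(n_sites, 0, config$peptide_efficiency_sd)
    sig <- ab_log2[site_acc_idx, , drop = FALSE] + occ_log2 + eff
    intensity <- noisy(sig)

    des <- design[design$layer == "phospho", ]
    des$sample_id <- sample_key(global_replicate(des$run, des$replicate,
                                                 config$reps_per_run),
                                des$timepoint, des$treatment)
    impurity$phospho <- default_impurity_matrix(unique(des$channel_id),
                                                config$impurity_leakage)
    meta <- data.frame(accession = acc[site_acc_idx],
                       sequence = random_peptide_sequences(n_sites),
                       sites = site_id, stringsAsFactors = FALSE)
    peptides$phospho <- assemble_layer_table(
      intensity, grid$sample_id, des, meta, config$missing_rate,
      impurity$phospho, function(d) d$sample_id)

    truth_ph <- data.frame(accession = acc[site_acc_idx], site = site_id,
                           entity = entity_key(acc[site_acc_idx], site_id),
                           affected = ph$affected, occupancy = occ,
                           stringsAsFactors = FALSE)
    for (tp in tps) truth_ph[[paste0("delta_", tp)]] <- ph$delta[, tp]
  }

  # --- synthetic site annotations (stand-in for an offline UniProt export)
  annotations <- data.frame(protein_accession = character(0),
                            site = character(0), annotation = character(0),
                            partner = character(0), stringsAsFactors = FALSE)
  if (!is.null(truth_ox)) {
    known <- stats::runif(nrow(truth_ox)) < 0.3
    ann1 <- data.frame(protein_accession = truth_ox$accession[known],
                       site = truth_ox$site[known],
                       annotation = "known_modified",
                       partner = NA_character_, stringsAsFactors = FALSE)
    # Pair the first two cysteines of multi-cysteine proteins as a
    # disulfide bond for a subset of proteins.
    ss <- NULL
    multi <- names(which(table(truth_ox$accession) >= 2))
    multi <- multi[stats::runif(length(multi)) < 0.2]
    if (length(multi) > 0) {
      ss <- do.call(rbind, lapply(multi, function(a) {
        s <- truth_ox$site[truth_ox$accession == a][1:2]
        data.frame(protein_accession = a, site = s,
                   annotation = "disulfide_partner", partner = rev(s),
                   stringsAsFactors = FALSE)
      }))
    }
    annotations <- rbind(ann1[!paste(ann1$protein_accession, ann1$site) %in%
                                paste(ss$protein_accession, ss$site), ], ss)
    annotations <- annotations[order(annotations$protein_accession,
                                     annotations$site), ]
    rownames(annotations) <- NULL
  }

  list(design = design, peptides = peptides, impurity = impurity,
       gene_sets = gene_sets, mapping = mapping, annotations = annotations,
       truth = list(proteins = truth_proteins, ox_sites = truth_ox,
                    phospho_sites = truth_ph),
       config = config)
}

#' Ground-truth values on the normalized log2 fold-change scale
#'
#' The expected post-normalization log2 fold change of each entity of a
#' quantification layer: the planted abundance effect for proteins, the
#' occupancy effect for phosphosites, and the fraction-implied values for the
#' oxidation layers (after sign inversion for `ox_all` and protein
#' normalization for all PTM layers).
#'
#' @param truth `truth` element of [simulate_experiment()].
#' @param layer quantification layer.
#' @param timepoint time point label.
#' @return data.frame (`entity`, `true_log2fc`).
#' @export
true_log2fc <- function(truth, layer = QUANT_LAYERS, timepoint) {
  layer <- match.arg(layer)
  if (layer == "proteome") {
    data.frame(entity = truth$proteins$accession,
               true_log2fc = truth$proteins[[paste0("delta_", timepoint)]],
               stringsAsFactors = FALSE)
  } else if (layer == "phospho") {
    data.frame(entity = truth$phospho_sites$entity,
               true_log2fc =
                 truth$phospho_sites[[paste0("delta_", timepoint)]],
               stringsAsFactors = FALSE)
  } else {
    col <- paste0("true_log2fc_",
                  if (layer == "ox_all") "all" else "rev", "_", timepoint)
    data.frame(entity = truth$ox_sites$entity,
               true_log2fc = truth$ox_sites[[col]],
               stringsAsFactors = FALSE)
  }
}

#' Recovery metrics of a differential result against ground truth
#'
#' Per (layer, timepoint): estimation bias over all entities and over truly
#' affected entities, RMSE, sensitivity (true positive rate at the
#' significance call), and realized false discovery proportion.
#'
#' @param truth `truth` element of [simulate_experiment()].
#' @param res `DifferentialResult` rows (one or more layers/time points).
#' @return data.frame of recovery metrics.
#' @export
truth_report <- function(truth, res) {
  groups <- unique(res[c("layer", "timepoint")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    ly <- groups$layer[i]; tp <- groups$timepoint[i]
    g <- res[res$layer == ly & res$timepoint == tp, ]
    tt <- true_log2fc(truth, ly, tp)
    idx <- match(g$entity, tt$entity)
    if (anyNA(idx)) {
      stop("entities missing from ground truth for layer ", ly,
           call. = FALSE)
    }
    tv <- tt$true_log2fc[idx]
    err <- g$log2fc_mean - tv
    affected <- tv != 0
    n_sig <- sum(g$significant)
    data.frame(layer = ly, timepoint = tp, n_tested = nrow(g),
               n_affected = sum(affected),
               bias_all = mean(err),
               bias_affected = if (any(affected)) mean(err[affected])
                               else NA_real_,
               rmse = sqrt(mean(err^2)),
               sensitivity = if (any(affected))
                 mean(g$significant[affected]) else NA_real_,
               fdp = if (n_sig > 0) sum(g$significant & !affected) / n_sig
                     else 0,
               n_significant = n_sig, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
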