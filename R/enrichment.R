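# Hypergeometric over-representation analysis against gene-set collections,
# per layer and integratively across layers, with direction-of-regulation
# calls and cellular-compartment mapping.

#' Map entity keys to gene symbols
#'
#' Sites collapse to their parent protein's gene symbol; duplicates are
#' removed; accessions without a mapping entry are dropped (and counted).
#'
#' @param entities entity keys (accessions or `"<accession>_<site>"`).
#' @param mapping named character vector, accession -> gene symbol.
#' @return character vector of unique gene symbols; attribute `n_unmapped`
#'   counts dropped accessions.
#' @export
map_to_genes <- function(entities, mapping) {
  if (length(mapping) == 0) stop("empty accession-to-gene mapping",
                                 call. = FALSE)
  acc <- unique(parent_accession(entities))
  sym <- mapping[acc]
  n_unmapped <- sum(is.na(sym))
  if (n_unmapped > 0) {
    message("map_to_genes: dropped ", n_unmapped, " unmapped accession(s)")
  }
  out <- unique(unname(sym[!is.na(sym)]))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Direction of regulation from member fold changes
#'
#' The sign of the median log2 fold change over all proteins and sites
#' assigned to a pathway: `up` if the median is positive, `down` if
#' negative, `mixed-zero` if exactly zero.
#'
#' @param log2fc numeric vector of member log2 fold changes (length >= 1).
#' @return one of `"up"`, `"down"`, `"mixed-zero"`.
#' @export
direction_call <- function(log2fc) {
  log2fc <- log2fc[!is.na(log2fc)]
  if (length(log2fc) == 0) stop("no member fold changes", call. = FALSE)
  m <- stats::median(log2fc)
  if (m > 0) "up" else if (m < 0) "down" else "mixed-zero"
}

#' Over-representation analysis of a significant gene list
#'
#' One-sided hypergeometric upper-tail test per gene set: with N universe
#' genes of which K are in the set, and n significant genes, the p-value is
#' P(X >= k) for the observed overlap k. Only sets with at least one universe
#' member are tested; Benjamini-Hochberg adjustment is applied across all
#' tested sets of the collection; sets are flagged significant at
#' `fdr <= alpha`.
#'
#' @param significant character vector of significant gene symbols (must be a
#'   subset of `universe`).
#' @param universe character vector of background gene symbols (the reliably
#'   quantified genes of the analysis scope).
#' @param collection a `gene_set_collection`.
#' @param member_fc optional data.frame with columns `gene`, `log2fc` (one
#'   row per significant protein or site) used for direction calls.
#' @param alpha FDR threshold for the `significant` flag.
#' @return `EnrichmentResult` data.frame: `set_name`, `k`, `K`, `n`, `N`,
#'   `p`, `fdr`, `significant`, `direction`, `members`
#'   (semicolon-joined overlapping significant genes).
#' @export
enrich <- function(significant, universe, collection, member_fc = NULL,
                   alpha = 0.05) {
  significant <- unique(significant)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(significant %in% universe)) {
    stop("significant genes must be a subset of the universe", call. = FALSE)
  }
  n <- length(significant)
  N <- length(universe)
  rows <- lapply(names(collection$sets), function(nm) {
    members_u <- intersect(collection$sets[[nm]], universe)
    K <- length(members_u)
    if (K == 0) return(NULL)
    hits <- intersect(members_u, significant)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    dir <- NA_character_
    if (!is.null(member_fc) && k > 0) {
      fcs <- member_fc$log2fc[member_fc$gene %in% hits]
      if (length(fcs) > 0) dir <- direction_call(fcs)
    }
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               fdr = NA_real_, significant = FALSE, direction = dir,
               members = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    stop("no gene set overlaps the universe", call. = FALSE)
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr <= alpha
  res <- res[order(res$p, res$set_name), ]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  res
}

#' Integrative over-representation analysis across omics layers
#'
#' The significant list is the union over layers of the gene symbols of each
#' layer's significant entities; the universe is the union of the per-layer
#' quantified gene symbols. Member fold changes pool all significant proteins
#' and sites (site values after protein normalization), so PTM effects can
#' dominate the direction call.
#'
#' @param sig_by_layer named list, layer -> significant entity keys.
#' @param universe_by_layer named list, layer -> quantified entity keys.
#' @param collection a `gene_set_collection`.
#' @param mapping accession -> gene symbol named vector.
#' @param member_fc_by_layer optional named list of data.frames
#'   (`entity`, `log2fc`) of the significant entities per layer.
#' @param alpha FDR threshold.
#' @return `EnrichmentResult` data.frame as in [enrich()].
#' @export
integrative_enrich <- function(sig_by_layer, universe_by_layer, collection,
                               mapping, member_fc_by_layer = NULL,
                               alpha = 0.05) {
  if (length(universe_by_layer) < 2) {
    stop("integrative enrichment needs at least two layers", call. = FALSE)
  }
  sig <- unique(unlist(lapply(sig_by_layer, map_to_genes, mapping = mapping),
                       use.names = FALSE))
  uni <- unique(unlist(lapply(universe_by_layer, map_to_genes,
                              mapping = mapping), use.names = FALSE))
  member_fc <- NULL
  if (!is.null(member_fc_by_layer)) {
    member_fc <- do.call(rbind, lapply(member_fc_by_layer, function(d) {
      data.frame(gene = unname(mapping[parent_accession(d$entity)]),
                 log2fc = d$log2fc, stringsAsFactors = FALSE)
    }))
    member_fc <- member_fc[!is.na(member_fc$gene), ]
  }
  enrich(sig, uni, collection, member_fc = member_fc, alpha = alpha)
}

#' Map entities to cellular-compartment gene sets
#'
#' Annotates each entity with every GO cellular-component set containing its
#' gene; entities whose gene is in no set are labeled `"unmapped"`.
#'
#' @param entities entity keys.
#' @param go_cc a `gene_set_collection` of cellular-component sets.
#' @param mapping accession -> gene symbol named vector.
#' @return long data.frame (`entity`, `gene`, `compartment`).
#' @export
map_compartments <- function(entities, go_cc, mapping) {
  gene <- unname(mapping[parent_accession(entities)])
  rows <- lapply(seq_along(entities), function(i) {
    g <- gene[i]
    comp <- if (is.na(g)) character(0) else
      names(go_cc$sets)[vapply(go_cc$sets, function(s) g %in% s, TRUE)]
    if (length(comp) == 0) comp <- "unmapped"
    data.frame(entity = entities[i], gene = g, compartment = comp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
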