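# Cross-timepoint dynamics (Pearson correlation of mean log2 fold changes
# with its t-transform significance) and multiply-modified-protein overlap.

#' Correlate mean fold changes between two time points
#'
#' For entities quantified at both time points, the Pearson correlation of
#' the mean log2 fold changes, its two-sided significance from the t
#' transform t = r * sqrt((n - 2) / (1 - r^2)) with df = n - 2, and the
#' least-squares trendline. The `subset` distinguishes entities significant
#' at one or both time points from entities significant at neither.
#'
#' @param res_a,res_b `DifferentialResult` tables of the same layer at the
#'   two time points.
#' @param subset `"significant"` or `"not_affected"`.
#' @param rule significance at `"either"` (default) or `"both"` time points
#'   defines the significant subset.
#' @return one-row data.frame: `layer`, `subset`, `n`, `r`, `p`, `slope`,
#'   `intercept`, `computable`.
#' @export
correlate_timepoints <- function(res_a, res_b,
                                 subset = c("significant", "not_affected"),
                                 rule = c("either", "both")) {
  subset <- match.arg(subset)
  rule <- match.arg(rule)
  if (!identical(unique(res_a$layer), unique(res_b$layer))) {
    stop("results must be from the same layer", call. = FALSE)
  }
  m <- merge(res_a[c("entity", "log2fc_mean", "significant")],
             res_b[c("entity", "log2fc_mean", "significant")],
             by = "entity", suffixes = c("_a", "_b"))
  sig <- if (rule == "either") m$significant_a | m$significant_b
         else m$significant_a & m$significant_b
  keep <- if (subset == "significant") sig else !sig
  x <- m$log2fc_mean_a[keep]
  y <- m$log2fc_mean_b[keep]
  n <- length(x)
  base <- data.frame(layer = unique(res_a$layer), subset = subset, n = n,
                     r = NA_real_, p = NA_real_, slope = NA_real_,
                     intercept = NA_real_, computable = FALSE,
                     stringsAsFactors = FALSE)
  if (n < 3) return(base)
  r <- stats::cor(x, y)
  if (!is.finite(r)) return(base)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  slope <- stats::cov(x, y) / stats::var(x)
  base$r <- r; base$p <- p; base$slope <- slope
  base$intercept <- mean(y) - slope * mean(x)
  base$computable <- TRUE
  base
}

#' Overlap of proteins significant at protein, oxidation and phosphorylation level
#'
#' Collapses significant sites to their parent proteins and classifies every
#' protein significant in at least one layer into the seven Venn classes of
#' (protein level, oxidation, phosphorylation). Oxidation pools the overall
#' and reversible layers. A protein is "multiply modified" when it carries
#' both a significant oxidation site and a significant phosphorylation site.
#'
#' @param prot `DifferentialResult` of the proteome layer.
#' @param ox `DifferentialResult` rows of the oxidation layers (stack
#'   `ox_all` and `ox_rev` with `rbind`).
#' @param phos `DifferentialResult` of the phospho layer.
#' @return data.frame: `protein`, `sig_protein`, `sig_ox`, `sig_phospho`,
#'   `venn_class` (e.g. `"ox+phos"`), `multiply_modified`.
#' @export
overlap_multiply_modified <- function(prot, ox, phos) {
  sig_prot <- unique(prot$entity[prot$significant])
  sig_ox <- unique(parent_accession(ox$entity[ox$significant]))
  sig_phos <- unique(parent_accession(phos$entity[phos$significant]))
  all_prot <- sort(unique(c(sig_prot, sig_ox, sig_phos)))
  if (length(all_prot) == 0) {
    return(data.frame(protein = character(0), sig_protein = logical(0),
                      sig_ox = logical(0), sig_phospho = logical(0),
                      venn_class = character(0),
                      multiply_modified = logical(0),
                      stringsAsFactors = FALSE))
  }
  a <- all_prot %in% sig_prot
  b <- all_prot %in% sig_ox
  c_ <- all_prot %in% sig_phos
  venn <- mapply(function(pa, pb, pc) {
    paste(c("prot", "ox", "phos")[c(pa, pb, pc)], collapse = "+")
  }, a, b, c_)
  data.frame(protein = all_prot, sig_protein = a, sig_ox = b,
             sig_phospho = c_, venn_class = unname(venn),
             multiply_modified = b & c_, stringsAsFactors = FALSE)
}
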