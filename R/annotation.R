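# Join significant oxidation sites against a user-supplied table of known
# cysteine modifications and disulfide partners (an offline UniProtKB
# export or a synthetic stand-in).

#' Annotate oxidation sites with known modifications and disulfide partners
#'
#' Left-joins a differential result of an oxidation layer against a site
#' annotation table on (protein accession, site). Sites absent from the
#' table are marked as not previously described (`known_modified = FALSE`);
#' disulfide rows report the bonded partner cysteine. The join is lossless:
#' one output row per input row.
#'
#' @param res `DifferentialResult` of an oxidation layer (`ox_all`,
#'   `ox_rev`, or both stacked).
#' @param ann annotation table from [read_site_annotations()].
#' @return `res` with added columns `known_modified` and
#'   `disulfide_partner`.
#' @export
annotate_sites <- function(res, ann) {
  if (!all(res$layer %in% c("ox_all", "ox_rev"))) {
    stop("annotate_sites applies to oxidation layers only", call. = FALSE)
  }
  acc <- parent_accession(res$entity)
  site <- entity_site(res$entity)
  key <- paste(acc, site)
  ann_key <- paste(ann$protein_accession, ann$site)
  idx <- match(key, ann_key)
  res$known_modified <- !is.na(idx)
  partner <- rep(NA_character_, nrow(res))
  has <- !is.na(idx) & ann$annotation[idx] == "disulfide_partner"
  partner[has] <- ann$partner[idx[has]]
  res$disulfide_partner <- partner
  res
}
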