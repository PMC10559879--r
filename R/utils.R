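#' @keywords internal
"_PACKAGE"

# Valid modified residues: cysteine for oxidation, S/T/Y for phosphorylation,
# M for methionine oxidation (accepted on input, not simulated).
SITE_RESIDUES <- c("C", "S", "T", "Y", "M")

LAYERS <- c("proteome", "redoxome", "phospho")
QUANT_LAYERS <- c("proteome", "ox_all", "ox_rev", "phospho")

#' Parse a modification-site identifier
#'
#' A site identifier is a residue letter followed by a 1-based position on the
#' protein's canonical sequence, e.g. `"C105"` or `"S536"`.
#'
#' @param x character vector of site identifiers.
#' @return data.frame with columns `residue` and `position`.
#' @export
parse_site_id <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[CSTYM][0-9]+$", x)
  if (!all(ok)) {
    stop("unparseable site id(s): ", paste(x[!ok], collapse = ", "),
         call. = FALSE)
  }
  pos <- as.integer(sub("^[A-Z]", "", x))
  if (any(pos < 1L)) stop("site positions must be >= 1", call. = FALSE)
  data.frame(residue = substr(x, 1, 1), position = pos,
             stringsAsFactors = FALSE)
}

#' Render a site identifier from residue and position
#' @param residue residue letter.
#' @param position 1-based integer position.
#' @return character vector like `"C105"`.
#' @export
format_site_id <- function(residue, position) {
  stopifnot(all(residue %in% SITE_RESIDUES))
  paste0(residue, as.integer(position))
}

# Entity keys: a proteome entity is the bare accession; a PTM entity is
# "<accession>_<site>" (UniProt accessions never contain "_").
entity_key <- function(accession, site = NULL) {
  if (is.null(site)) accession else paste(accession, site, sep = "_")
}

#' Parent accession of an entity key
#' @param entity entity keys (accessions or `"<accession>_<site>"`).
#' @return character vector of accessions.
#' @export
parent_accession <- function(entity) {
  sub("_[CSTYM][0-9]+$", "", entity)
}

entity_site <- function(entity) {
  out <- rep(NA_character_, length(entity))
  has <- grepl("_[CSTYM][0-9]+$", entity)
  out[has] <- sub("^.*_", "", entity[has])
  out
}

# Global replicate index 1..(n_runs * reps_per_run) from (run, replicate).
global_replicate <- function(run, replicate, reps_per_run) {
  (as.integer(run) - 1L) * as.integer(reps_per_run) + as.integer(replicate)
}

sample_key <- function(replicate, timepoint, treatment) {
  sprintf("r%02d_%s_%s", as.integer(replicate), timepoint, treatment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
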