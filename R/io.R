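# Tabular I/O. All files are UTF-8 TSV, "." decimal point, no quoting.
# Numeric values are written with 15 significant digits so that
# read(write(x)) reproduces x well within 1e-9 relative.

#' Write a result or input table as TSV
#'
#' Deterministic column order (as given), tab separation, no quoting.
#' Numeric columns round-trip through [utils::read.delim()] within 1e-9
#' relative error.
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]]) && !is.integer(x[[j]])) {
      x[[j]] <- trimws(formatC(x[[j]], digits = 15, format = "g"))
      x[[j]][x[[j]] == "NA"] <- NA
    }
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "", encoding = "UTF-8")
}

#' Read a peptide-isoform quantification table
#'
#' One row per peptide isoform per TMT mix. Required columns: `mix_id`,
#' `protein_accession`, `peptide_sequence`, `sites` (semicolon-joined site
#' ids, empty for unmodified peptides), plus one intensity column per channel
#' of the layer's mixes. Blank intensity cells are missing values, which are
#' distinct from measured zeros.
#'
#' @param path TSV path.
#' @param design validated SampleDesign; used to check that every intensity
#'   column belongs to the design and every mix is known.
#' @param layer which design layer the table belongs to.
#' @return data.frame of peptide records with numeric channel columns.
#' @export
read_peptide_table <- function(path, design, layer = c("proteome",
                                                       "redoxome",
                                                       "phospho")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("peptide table not found: ", path,
                               call. = FALSE)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "", colClasses = "character",
                         encoding = "UTF-8")
  meta_cols <- c("mix_id", "protein_accession", "peptide_sequence", "sites")
  missing_cols <- setdiff(meta_cols, names(x))
  if (length(missing_cols) > 0) {
    stop("peptide table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$sites[is.na(x$sites)] <- ""
  des <- design[design$layer == layer, ]
  channels <- setdiff(names(x), meta_cols)
  unknown <- setdiff(channels, unique(des$channel_id))
  if (length(unknown) > 0) {
    stop("intensity column(s) with no design entry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_mix <- setdiff(unique(x$mix_id), unique(des$mix_id))
  if (length(unknown_mix) > 0) {
    stop("mix id(s) not in design: ", paste(unknown_mix, collapse = ", "),
         call. = FALSE)
  }
  validate_peptide_records(x, channels)
}

validate_peptide_records <- function(x, channels) {
  for (ch in channels) {
    v <- suppressWarnings(as.numeric(x[[ch]]))
    bad <- !is.na(x[[ch]]) & is.na(v)
    if (any(bad)) {
      stop("non-numeric intensity in column ", ch, ", row ",
           which(bad)[1], call. = FALSE)
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative intensity in column ", ch, ", row ",
           which(v < 0)[1], call. = FALSE)
    }
    x[[ch]] <- v
  }
  has_sites <- nzchar(x$sites)
  if (any(has_sites)) {
    for (i in which(has_sites)) {
      ids <- strsplit(x$sites[i], ";", fixed = TRUE)[[1]]
      res <- try(parse_site_id(ids), silent = TRUE)
      if (inherits(res, "try-error")) {
        stop("row ", i, ": ", attr(res, "condition")$message, call. = FALSE)
      }
    }
  }
  attr(x, "channels") <- channels
  x
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, fields are set name, description, then
#' tab-separated member gene symbols. Members are deduplicated; empty sets
#' are rejected.
#'
#' @param path GMT file.
#' @param name collection name (defaults to the file name).
#' @return a `gene_set_collection` list with elements `name` and `sets`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(ln, 1, 60),
                            call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("empty gene set: ", f[1], call. = FALSE)
    sets[[f[1]]] <- members
  }
  gene_set_collection(name, sets)
}

#' Construct a gene-set collection
#' @param name collection name.
#' @param sets named list of character vectors of gene symbols.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(name, sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(vapply(sets, length, 1L) == 0)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  structure(list(name = name, sets = sets), class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an accession-to-gene-symbol mapping
#' @param path two-column TSV (`protein_accession`, `gene_symbol`).
#' @return named character vector, accession -> symbol.
#' @export
read_mapping <- function(path) {
  x <- read_table(path)
  if (!all(c("protein_accession", "gene_symbol") %in% names(x))) {
    stop("mapping must have columns protein_accession, gene_symbol",
         call. = FALSE)
  }
  stats::setNames(as.character(x$gene_symbol), x$protein_accession)
}

#' Write an accession-to-gene-symbol mapping
#' @param mapping named character vector, accession -> symbol.
#' @param path output path.
#' @export
write_mapping <- function(mapping, path) {
  write_table(data.frame(protein_accession = names(mapping),
                         gene_symbol = unname(mapping),
                         stringsAsFactors = FALSE), path)
}

#' Read a site-annotation table
#'
#' Known cysteine modifications and disulfide partners, typically exported
#' from UniProtKB. Columns: `protein_accession`, `site`, `annotation`
#' (`known_modified` or `disulfide_partner`), `partner` (site id, required
#' for disulfide rows, empty otherwise).
#'
#' @param path TSV path.
#' @return validated annotation data.frame.
#' @export
read_site_annotations <- function(path) {
  x <- read_table(path)
  req <- c("protein_accession", "site", "annotation", "partner")
  if (!all(req %in% names(x))) {
    stop("annotation table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  x$partner <- as.character(x$partner)
  parse_site_id(x$site)
  bad_tok <- setdiff(unique(x$annotation),
                     c("known_modified", "disulfide_partner"))
  if (length(bad_tok) > 0) {
    stop("unknown annotation token(s): ", paste(bad_tok, collapse = ", "),
         call. = FALSE)
  }
  is_ss <- x$annotation == "disulfide_partner"
  if (any(is_ss & (is.na(x$partner) | !nzchar(x$partner)))) {
    stop("disulfide_partner rows must carry a partner site", call. = FALSE)
  }
  if (any(!is_ss & !is.na(x$partner) & nzchar(x$partner))) {
    stop("known_modified rows must not carry a partner site", call. = FALSE)
  }
  if (any(is_ss)) parse_site_id(x$partner[is_ss])
  x
}

#' Read a reporter-ion impurity matrix
#'
#' Square TSV with channel ids as row and column headers; entry (i, j) is the
#' fraction of channel j's true signal observed in channel i.
#'
#' @param path TSV path.
#' @return numeric matrix with channel dimnames, validated by
#'   [validate_impurity_matrix()].
#' @export
read_impurity_matrix <- function(path) {
  x <- utils::read.delim(path, sep = "\t", row.names = 1, check.names = FALSE)
  m <- as.matrix(x)
  validate_impurity_matrix(m)
}

#' Write a reporter-ion impurity matrix
#' @param m impurity matrix with channel dimnames.
#' @param path output path.
#' @export
write_impurity_matrix <- function(m, path) {
  df <- data.frame(channel = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}
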