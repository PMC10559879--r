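#' Build the default multiplexing design
#'
#' Constructs the sample design used throughout the pipeline: `n_runs` runs of
#' `reps_per_run` biological replicates each (12 replicates by default), two
#' time points, and paired treated/control samples inside every TMT mix so all
#' fold changes are mix-internal.
#'
#' Mixing differs by layer, mirroring the labeling chemistry:
#' \itemize{
#'   \item proteome: one 4-channel mix per replicate carrying
#'     (timepoint x treatment) for that replicate;
#'   \item redoxome: one 4-channel mix per (replicate, timepoint) carrying
#'     control/treated each at both label stages, TMT1 (free thiols, read out
#'     as overall oxidation after sign inversion) and TMT2 (reversibly
#'     oxidized thiols);
#'   \item phospho: one 16-channel mix per run carrying that run's four
#'     replicates at every (timepoint x treatment).
#' }
#'
#' @param n_runs number of runs.
#' @param reps_per_run biological replicates per run.
#' @param timepoints character vector of time point labels.
#' @param layers layers to include.
#' @return A `SampleDesign` data.frame with columns `layer`, `mix_id`,
#'   `channel_id`, `run`, `replicate`, `timepoint`, `treatment`,
#'   `label_stage`.
#' @export
default_design <- function(n_runs = 3L, reps_per_run = 4L,
                           timepoints = c("4h", "24h"),
                           layers = LAYERS) {
  stopifnot(n_runs >= 1, reps_per_run >= 1, length(timepoints) >= 1)
  layers <- match.arg(layers, LAYERS, several.ok = TRUE)
  treatments <- c("control", "treated")
  rows <- list()

  grid_rep <- expand.grid(replicate = seq_len(reps_per_run),
                          run = seq_len(n_runs),
                          KEEP.OUT.ATTRS = FALSE)
  grid_rep$grep <- global_replicate(grid_rep$run, grid_rep$replicate,
                                    reps_per_run)

  if ("proteome" %in% layers) {
    for (i in seq_len(nrow(grid_rep))) {
      combo <- expand.grid(treatment = treatments, timepoint = timepoints,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = "proteome",
        mix_id = sprintf("prot_r%02d", grid_rep$grep[i]),
        channel_id = sprintf("ch%02d", seq_len(nrow(combo))),
        run = grid_rep$run[i], replicate = grid_rep$replicate[i],
        timepoint = combo$timepoint, treatment = combo$treatment,
        label_stage = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if ("redoxome" %in% layers) {
    for (i in seq_len(nrow(grid_rep))) {
      for (tp in timepoints) {
        combo <- expand.grid(label_stage = c("TMT1", "TMT2"),
                             treatment = treatments,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          layer = "redoxome",
          mix_id = sprintf("redox_r%02d_%s", grid_rep$grep[i], tp),
          channel_id = sprintf("ch%02d", seq_len(nrow(combo))),
          run = grid_rep$run[i], replicate = grid_rep$replicate[i],
          timepoint = tp, treatment = combo$treatment,
          label_stage = combo$label_stage, stringsAsFactors = FALSE)
      }
    }
  }
  if ("phospho" %in% layers) {
    for (r in seq_len(n_runs)) {
      combo <- expand.grid(treatment = treatments, timepoint = timepoints,
                           replicate = seq_len(reps_per_run),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = "phospho",
        mix_id = sprintf("phos_run%d", r),
        channel_id = sprintf("ch%02d", seq_len(nrow(combo))),
        run = r, replicate = combo$replicate,
        timepoint = combo$timepoint, treatment = combo$treatment,
        label_stage = NA_character_, stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  attr(design, "reps_per_run") <- as.integer(reps_per_run)
  validate_design(design)
}

#' Validate a sample design
#'
#' Checks the structural invariants every downstream stage relies on:
#' unique (mix, channel) pairs, valid treatment/layer/label tokens, TMT1/TMT2
#' twin pairing of every redoxome sample within its mix, and the mix-internal
#' treated/control pairing at each time point.
#'
#' @param design a SampleDesign data.frame.
#' @return the design, invisibly augmented with a `replicate_global` column.
#' @export
validate_design <- function(design) {
  required <- c("layer", "mix_id", "channel_id", "run", "replicate",
                "timepoint", "treatment", "label_stage")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(design) == 0) stop("no design rows", call. = FALSE)

  bad_layer <- setdiff(unique(design$layer), LAYERS)
  if (length(bad_layer) > 0) {
    stop("unknown layer token(s): ", paste(bad_layer, collapse = ", "),
         call. = FALSE)
  }
  bad_trt <- setdiff(unique(design$treatment), c("treated", "control"))
  if (length(bad_trt) > 0) {
    stop("unknown treatment token(s): ", paste(bad_trt, collapse = ", "),
         call. = FALSE)
  }
  bad_stage <- setdiff(unique(design$label_stage[!is.na(design$label_stage)]),
                       c("TMT1", "TMT2"))
  if (length(bad_stage) > 0) {
    stop("unknown label_stage token(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }

  key <- paste(design$mix_id, design$channel_id)
  if (anyDuplicated(key)) {
    stop("duplicate (mix_id, channel_id) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }

  reps_per_run <- attr(design, "reps_per_run") %||% max(design$replicate)
  design$replicate_global <- global_replicate(design$run, design$replicate,
                                              reps_per_run)

  # Redoxome: each biological sample occurs exactly twice in its mix,
  # once per label stage.
  rx <- design[design$layer == "redoxome", ]
  if (nrow(rx) > 0) {
    if (anyNA(rx$label_stage)) {
      stop("redoxome rows must carry a TMT1/TMT2 label_stage", call. = FALSE)
    }
    samp <- paste(rx$mix_id, rx$replicate_global, rx$timepoint, rx$treatment)
    for (s in unique(samp)) {
      stages <- sort(rx$label_stage[samp == s])
      if (!identical(stages, c("TMT1", "TMT2"))) {
        stop("redoxome sample lacks its TMT1/TMT2 twin: ", s, call. = FALSE)
      }
    }
  }

  # Mix-internal treated/control pairing at each time point.
  for (mx in unique(design$mix_id)) {
    d <- design[design$mix_id == mx, ]
    for (tp in unique(d$timepoint)) {
      dt <- d[d$timepoint == tp, ]
      trt <- dt[dt$treatment == "treated",
                c("replicate_global", "label_stage")]
      ctl <- dt[dt$treatment == "control",
                c("replicate_global", "label_stage")]
      tkey <- sort(paste(trt$replicate_global, trt$label_stage))
      ckey <- sort(paste(ctl$replicate_global, ctl$label_stage))
      if (!identical(tkey, ckey)) {
        stop("mix ", mx, " lacks treated/control pairing at ", tp,
             call. = FALSE)
      }
    }
  }
  design
}

#' Read a sample design table
#'
#' Reads a tab-separated design file (one row per mix channel) and validates
#' it with [validate_design()].
#'
#' @param path path to a TSV file with the SampleDesign columns.
#' @return validated SampleDesign data.frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  design <- utils::read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  if (nrow(design) == 0) stop("no design rows", call. = FALSE)
  design$run <- as.integer(design$run)
  design$replicate <- as.integer(design$replicate)
  design$label_stage[design$label_stage %in% c("", "NA")] <- NA_character_
  validate_design(design)
}

#' Write a sample design table
#' @param design SampleDesign data.frame.
#' @param path output TSV path.
#' @export
write_design <- function(design, path) {
  cols <- c("layer", "mix_id", "channel_id", "run", "replicate",
            "timepoint", "treatment", "label_stage")
  write_table(design[cols], path)
}
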