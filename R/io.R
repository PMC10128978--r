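# Plain-text interchange: trace TSV, truth sidecar JSON, sample sheets.

#' Write traces to a tabular (TSV) file
#'
#' One row per sample point with columns `lane_id`, `gel_type`, `role`,
#' `case_id`, `migration`, `signal`.
#'
#' @param traces A `ce_trace` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "ce_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(lane_id = tr$lane_id, gel_type = tr$gel_type, role = tr$role,
               case_id = tr$case_id, migration = tr$migration,
               signal = tr$signal, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read traces from a tabular (TSV) file
#'
#' @param path File written by [write_traces()] (or any TSV with the same
#'   columns).
#' @return A named list of `ce_trace` objects (by lane id).
#' @export
read_traces <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "gel_type", "role", "migration", "signal")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trace file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"case_id" %in% names(df)) df$case_id <- NA_character_
  lanes <- split(df, df$lane_id)
  out <- lapply(lanes, function(sub) {
    sub <- sub[order(sub$migration), , drop = FALSE]
    new_trace(sub$lane_id[1], sub$gel_type[1], sub$role[1],
              sub$migration, pmax(sub$signal, 0), sub$case_id[1])
  })
  out[unique(df$lane_id)]
}

#' Write cohort ground truth to a JSON sidecar
#'
#' @param truths List of [case_truth()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truths, path) {
  recs <- lapply(truths, function(tr) {
    list(case_id = tr$case_id,
         unstable_markers = as.list(tr$unstable_markers),
         deletion_bp = as.list(tr$deletion_bp),
         tumor_fraction = tr$tumor_fraction,
         true_status = tr$true_status)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort ground-truth JSON sidecar
#'
#' @param path File written by [write_truth()].
#' @param panel Marker panel used to validate the records.
#' @return A list of `case_truth` objects.
#' @export
read_truth <- function(path, panel = marker_panel()) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    case_truth(r$case_id,
               unstable_markers = unlist(r$unstable_markers) %||% character(),
               deletion_bp = unlist(r$deletion_bp) %||% integer(),
               tumor_fraction = r$tumor_fraction, panel = panel)
  })
}

#' Read a tumor/normal sample sheet
#'
#' Required columns: `case_id`, `tumor_lane`, `normal_lane`. Optional:
#' `highres_tumor_lane`, `highres_normal_lane` (tier-2 lanes), the four IHC
#' columns `mlh1`, `msh2`, `msh6`, `pms2`, and any covariate columns.
#' Pairing is explicit here and never inferred from lane ids.
#'
#' @param path TSV file path.
#' @return A `data.frame`.
#' @export
read_samplesheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("case_id", "tumor_lane", "normal_lane")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop("sample sheet is empty")
  if (anyDuplicated(df$case_id)) stop("duplicate case_id in sample sheet")
  df
}
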