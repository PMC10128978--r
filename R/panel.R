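ANCHOR_SIZES <- c(low = 15, high = 1000)
CANON_LOGRATIO <- log(ANCHOR_SIZES[["high"]] / ANCHOR_SIZES[["low"]])
CANON_SPAN <- 100
ANCHOR_SIGMA_M <- 0.3

MARKER_NAMES <- c("BAT-25", "BAT-26", "NR-21", "NR-24", "NR-27")
STATUS_LEVELS <- c("MSS", "MSI-L", "MSI-H")

canon_migration <- function(size_bp) {
  CANON_SPAN * log(size_bp / ANCHOR_SIZES[["low"]]) / CANON_LOGRATIO
}

canon_size <- function(m) {
  ANCHOR_SIZES[["low"]] * exp(m * CANON_LOGRATIO / CANON_SPAN)
}

#' Default mononucleotide marker panel
#'
#' Specifications for the five quasi-monomorphic poly-A markers used for
#' MSI-PCR (BAT-25, BAT-26, NR-21, NR-24, NR-27). Each marker has a germline
#' product size and a half-open size window `[window_lo, window_hi)` within
#' which all of its PCR products (germline, deleted alleles, stutter) are
#' expected. Windows are pairwise disjoint and lie strictly between the 15
#' and 1000 bp alignment markers.
#'
#' The instability rule is relative to the paired normal lane, so the
#' absolute germline sizes are configuration, not biology; the defaults are
#' order-of-100 bp amplicons with >= 22 bp of deletion headroom inside each
#' window.
#'
#' @return A `data.frame` with columns `name`, `germline_size`, `window_lo`,
#'   `window_hi`, one row per marker, ordered by product size.
#' @export
marker_panel <- function() {
  panel <- data.frame(
    name = c("NR-21", "BAT-26", "BAT-25", "NR-24", "NR-27"),
    germline_size = c(100, 135, 170, 205, 240),
    window_lo = c(78, 110, 145, 180, 215),
    window_hi = c(108, 143, 178, 213, 248),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("name", "germline_size", "window_lo", "window_hi") %in% names(panel)))
  if (anyDuplicated(panel$name)) stop("duplicate marker names in panel")
  inside <- panel$germline_size > panel$window_lo & panel$germline_size < panel$window_hi
  if (!all(inside)) stop("germline_size must lie strictly inside each marker window")
  if (any(panel$window_lo <= ANCHOR_SIZES[["low"]]) ||
      any(panel$window_hi >= ANCHOR_SIZES[["high"]])) {
    stop("marker windows must lie strictly between the alignment-marker sizes")
  }
  ord <- order(panel$window_lo)
  lo <- panel$window_lo[ord]; hi <- panel$window_hi[ord]
  if (any(utils::head(hi, -1) > utils::tail(lo, -1))) {
    stop("marker windows must be pairwise disjoint")
  }
  invisible(panel)
}

marker_window <- function(panel, marker) {
  row <- panel[panel$name == marker, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown marker: ", marker)
  c(lo = row$window_lo, hi = row$window_hi)
}

#' Gel model for a capillary cartridge
#'
#' Describes the resolving power and noise of a gel type. The screening
#' cartridge resolves size differences of roughly 10-15 bp and the
#' high-resolution cartridge 1-3 bp. Two equal Gaussian bands of width
#' `peak_sigma_bp` become bimodal beyond `2 * peak_sigma_bp` of separation,
#' but the dip between them only becomes readable against the detection
#' prominence threshold at about `2.7 * peak_sigma_bp`, which is the
#' operational resolvability. The defaults (4.5 bp screening, 1.0 bp
#' high-resolution) place that at roughly 12 bp and 2-3 bp respectively.
#'
#' Stutter is modeled on the contraction side only: ladder peaks at
#' -1..-`stutter_steps` bp with geometrically decaying amplitude
#' (ratio `stutter_decay`).
#'
#' @param gel_type `"screening"` or `"highres"`.
#' @param peak_sigma_bp Gaussian peak width (sd, bp). Defaults to 4.5
#'   (screening) or 1.0 (highres).
#' @param noise_sd Additive Gaussian baseline noise (signal units).
#' @param stutter_decay Amplitude ratio between successive stutter steps,
#'   in `[0, 1)`.
#' @param stutter_steps Number of -1 bp stutter steps (non-negative integer).
#' @return An object of class `gel_model`.
#' @export
gel_model <- function(gel_type = c("screening", "highres"),
                      peak_sigma_bp = NULL,
                      noise_sd = 1,
                      stutter_decay = 0.5,
                      stutter_steps = 3L) {
  gel_type <- match.arg(gel_type)
  if (is.null(peak_sigma_bp)) {
    peak_sigma_bp <- if (gel_type == "screening") 4.5 else 1.0
  }
  stopifnot(is.numeric(peak_sigma_bp), length(peak_sigma_bp) == 1L, peak_sigma_bp > 0,
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
            is.numeric(stutter_decay), stutter_decay >= 0, stutter_decay < 1,
            stutter_steps >= 0)
  structure(
    list(gel_type = gel_type,
         peak_sigma_bp = peak_sigma_bp,
         noise_sd = noise_sd,
         stutter_decay = stutter_decay,
         stutter_steps = as.integer(stutter_steps)),
    class = "gel_model"
  )
}

#' @export
print.gel_model <- function(x, ...) {
  cat(sprintf("<gel_model: %s; sigma %.2f bp; noise sd %.2f; stutter %d x %.2f>\n",
              x$gel_type, x$peak_sigma_bp, x$noise_sd, x$stutter_steps, x$stutter_decay))
  invisible(x)
}

#' Per-lane affine migration distortion
#'
#' Lane-to-lane migration variability is modeled as an affine map
#' `m_lane = alpha * m_canonical + beta` applied on top of the canonical
#' log-linear size-to-migration map. Because the 15 and 1000 bp alignment
#' markers are co-distorted with the PCR products, two-anchor calibration
#' removes any affine distortion exactly.
#'
#' @param alpha Multiplicative stretch (positive).
#' @param beta Additive offset (migration units).
#' @return An object of class `lane_distortion`.
#' @export
lane_distortion <- function(alpha = 1, beta = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "lane_distortion")
}

#' Case ground truth for simulation
#'
#' Describes one simulated tumor/normal pair: which markers are unstable,
#' the deletion length of each unstable marker's somatic allele, and the
#' tumor-cell fraction of the tumor specimen. The Bethesda status is derived
#' from the number of unstable markers (0 MSS, 1 MSI-L, >= 2 MSI-H) and is
#' not independently settable.
#'
#' @param case_id Case identifier (string).
#' @param unstable_markers Character vector of unstable marker names
#'   (subset of the panel).
#' @param deletion_bp Named integer vector of deletion lengths (bp) for the
#'   unstable markers. Markers left out are sampled by [simulate_case()]
#'   from the configured deletion distribution.
#' @param tumor_fraction Tumor DNA fraction in `[0, 1]`.
#' @param panel Marker panel (see [marker_panel()]).
#' @return An object of class `case_truth`.
#' @export
case_truth <- function(case_id, unstable_markers = character(),
                       deletion_bp = integer(), tumor_fraction = 1,
                       panel = marker_panel()) {
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id))
  unstable_markers <- as.character(unstable_markers)
  if (!all(unstable_markers %in% panel$name)) {
    stop("unstable_markers must be a subset of the panel markers")
  }
  if (anyDuplicated(unstable_markers)) stop("duplicated unstable markers")
  stopifnot(is.numeric(tumor_fraction), length(tumor_fraction) == 1L,
            tumor_fraction >= 0, tumor_fraction <= 1)
  if (length(deletion_bp)) {
    if (is.null(names(deletion_bp)) || !all(names(deletion_bp) %in% unstable_markers)) {
      stop("deletion_bp must be named by unstable markers")
    }
    if (any(deletion_bp <= 0)) stop("deletion_bp must be positive")
  }
  n_unst <- length(unstable_markers)
  status <- if (n_unst == 0L) "MSS" else if (n_unst == 1L) "MSI-L" else "MSI-H"
  structure(
    list(case_id = case_id,
         unstable_markers = unstable_markers,
         deletion_bp = deletion_bp,
         tumor_fraction = tumor_fraction,
         true_status = status),
    class = "case_truth"
  )
}

#' @export
print.case_truth <- function(x, ...) {
  cat(sprintf("<case_truth %s: %s; f = %.3f; unstable: %s>\n",
              x$case_id, x$true_status, x$tumor_fraction,
              if (length(x$unstable_markers)) paste(x$unstable_markers, collapse = ", ")
              else "none"))
  invisible(x)
}
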