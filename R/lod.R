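# Limit-of-detection estimation from tumor-fraction dilution series.

#' Per-marker instability calls along a dilution series
#'
#' Sizes the shared normal lane and each titration lane and calls every
#' panel marker at each tumor fraction on the given gel (single-tier: the
#' point of the titration is to characterize one cartridge). Inconclusive
#' (smeared) markers count as not-unstable at that fraction, since no
#' instability can be read from the lane at that tier.
#'
#' @param series Output of [simulate_dilution_series()], or any list with a
#'   `normal` trace, a `tumor` list of traces and a `fractions` vector.
#' @param gel [gel_model()] the lanes were run on.
#' @param panel Marker panel.
#' @param params [caller_params()].
#' @return A `data.frame`: `marker`, `gel_type`, `fraction`, `unstable`,
#'   `inconclusive`, `excluded`.
#' @export
dilution_calls <- function(series, gel, panel = marker_panel(),
                           params = caller_params()) {
  sn <- size_trace(series$normal, gel = gel)
  if (!sn$qc$pass) stop("normal lane failed anchor QC")
  rows <- list()
  for (i in seq_along(series$fractions)) {
    st <- size_trace(series$tumor[[i]], gel = gel)
    if (!st$qc$pass) stop("dilution lane failed anchor QC at fraction ",
                          series$fractions[i])
    calls <- call_markers(st, sn, panel, gel, params)
    rows[[i]] <- data.frame(marker = calls$marker, gel_type = gel$gel_type,
                            fraction = series$fractions[i],
                            unstable = calls$unstable,
                            inconclusive = calls$inconclusive,
                            excluded = calls$excluded,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Estimate the limit of detection from a dilution series
#'
#' The LOD is the smallest tumor fraction at which the marker is called
#' unstable at that fraction *and at every larger fraction in the series*
#' (an unbroken unstable prefix anchored at pure tumor). A series unstable
#' at no fraction has no LOD (`NA`). Replicate flags at the same fraction
#' are summarized by the modal flag. The `monotone` field records whether
#' the flags are non-increasing as the fraction decreases; non-monotone
#' series are estimable (on the prefix) but flagged.
#'
#' @param series A `data.frame` with columns `fraction` and `unstable`
#'   (logical), optionally `marker` and `gel_type` (carried through).
#' @return An object of class `lod_result`: `marker`, `gel_type`,
#'   `lod_fraction` (or `NA`), `monotone`.
#' @export
estimate_lod <- function(series) {
  stopifnot(is.data.frame(series), all(c("fraction", "unstable") %in% names(series)))
  if (!nrow(series)) stop("series must be nonempty")
  marker <- if ("marker" %in% names(series)) unique(series$marker) else NA_character_
  gel_type <- if ("gel_type" %in% names(series)) unique(series$gel_type) else NA_character_
  if (length(marker) > 1L) stop("series must contain a single marker")

  # modal flag per fraction (replicate handling)
  agg <- stats::aggregate(unstable ~ fraction, data = series,
                          FUN = function(x) mean(x) >= 0.5)
  agg <- agg[order(-agg$fraction), , drop = FALSE]
  if (max(agg$fraction) != 1) {
    stop("dilution series must anchor at pure tumor (fraction 1.0)")
  }
  flags <- agg$unstable
  monotone <- all(diff(as.integer(flags)) <= 0)
  run <- which(!flags)
  prefix_len <- if (!length(run)) length(flags) else run[1L] - 1L
  lod <- if (prefix_len == 0L) NA_real_ else agg$fraction[prefix_len]
  structure(list(marker = marker, gel_type = gel_type,
                 lod_fraction = lod, monotone = monotone),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result %s (%s): LOD %s%s>\n", x$marker, x$gel_type,
              if (is.na(x$lod_fraction)) "none"
              else paste0(100 * x$lod_fraction, "%"),
              if (x$monotone) "" else "; non-monotone series"))
  invisible(x)
}

#' LOD table for all markers of a dilution-series call set
#'
#' @param calls Output of [dilution_calls()].
#' @return A `data.frame`: `marker`, `gel_type`, `lod_fraction`, `monotone`.
#' @export
lod_table <- function(calls) {
  out <- lapply(split(calls, calls$marker), function(sub) {
    r <- estimate_lod(sub)
    data.frame(marker = r$marker, gel_type = r$gel_type,
               lod_fraction = r$lod_fraction, monotone = r$monotone,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare screening and high-resolution LODs for a marker
#'
#' A missing LOD (never unstable) ranks worst. Lower fractions are better
#' (higher sensitivity).
#'
#' @param screening,highres `lod_result` objects for the same marker.
#' @return `"highres_better"`, `"equal"` or `"screening_better"`.
#' @export
compare_gels <- function(screening, highres) {
  stopifnot(inherits(screening, "lod_result"), inherits(highres, "lod_result"))
  if (!identical(screening$marker, highres$marker)) {
    stop("LOD results are for different markers: ",
         screening$marker, " vs ", highres$marker)
  }
  rank <- function(x) if (is.na(x$lod_fraction)) Inf else x$lod_fraction
  s <- rank(screening); h <- rank(highres)
  if (h < s) "highres_better" else if (h == s) "equal" else "screening_better"
}
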