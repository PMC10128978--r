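# Paired tumor/normal marker calling, Bethesda classification and the
# two-tier screening -> high-resolution workflow.

#' Caller thresholds
#'
#' @param shift_bp Minimum absolute major-band shift (bp, integer-rounded)
#'   called unstable; the assay rule is >= 3 bp.
#' @param sign_agnostic If `TRUE` (default) insertions and deletions both
#'   count toward the shift rule; set `FALSE` for deletion-only calling.
#' @param minor_rel Minimum amplitude of a tumor band, relative to the tumor
#'   major band, to be considered a minor band.
#' @param match_tol_bp Named vector (`screening`, `highres`): a tumor band
#'   whose rounded size is within this tolerance of any normal-lane band is
#'   not "new".
#' @param smear_widen Width multiple of the gel sigma above which the major
#'   band is a smear. The default 1.5 sits above the stutter-broadened
#'   single-allele bundle (about 1.37x under the default stutter model) and
#'   below the width of two merged alleles separated by the assay's >= 2
#'   sigma deletion spectrum (>= 1.55x).
#' @param smear_overlap_sigma A competing band within this many gel sigma of
#'   the major is "overlapping"; if such a band reaches
#'   `smear_dominance` of the major amplitude there is no dominant band and
#'   the marker is a smear.
#' @param smear_dominance See above.
#' @param min_conclusive Minimum number of conclusive markers required for a
#'   Bethesda status; below this the case is indeterminate.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(shift_bp = 3L, sign_agnostic = TRUE,
                          minor_rel = 0.10,
                          match_tol_bp = c(screening = 3, highres = 1),
                          smear_widen = 1.5, smear_overlap_sigma = 3,
                          smear_dominance = 0.5, min_conclusive = 4L) {
  stopifnot(shift_bp >= 1, minor_rel > 0, minor_rel < 1,
            all(c("screening", "highres") %in% names(match_tol_bp)))
  structure(list(shift_bp = as.integer(shift_bp), sign_agnostic = sign_agnostic,
                 minor_rel = minor_rel, match_tol_bp = match_tol_bp,
                 smear_widen = smear_widen,
                 smear_overlap_sigma = smear_overlap_sigma,
                 smear_dominance = smear_dominance,
                 min_conclusive = as.integer(min_conclusive)),
            class = "caller_params")
}

peaks_in_window <- function(sized_peaks, window) {
  sized_peaks[sized_peaks$size_bp >= window[["lo"]] &
                sized_peaks$size_bp < window[["hi"]], , drop = FALSE]
}

#' Major band of a marker
#'
#' The highest-amplitude peak within the marker's size window; ties are
#' broken toward the smaller size. Absence of any product in the window is
#' a PCR failure for the marker.
#'
#' @param sized_peaks Sized peak table ([size_peaks()]).
#' @param window Named numeric `c(lo, hi)` size window (half-open).
#' @return The major-band peak row.
#' @export
major_band <- function(sized_peaks, window) {
  inw <- peaks_in_window(sized_peaks, window)
  if (!nrow(inw)) {
    stop(structure(class = c("no_product", "error", "condition"),
                   list(message = "no PCR product in marker window",
                        call = sys.call())))
  }
  inw <- inw[order(-inw$amplitude, inw$size_bp), , drop = FALSE]
  inw[1L, , drop = FALSE]
}

#' Smear (inconclusive pattern) detection
#'
#' A marker is inconclusive at a tier when its banding cannot be read on
#' that gel: the major band is wider than `smear_widen` times the gel's
#' nominal sigma (unresolved mixture), or it carries a shoulder (a flank
#' component not explained by the gel's clean band shape), or an
#' overlapping band (within `smear_overlap_sigma` gel sigma of the major)
#' reaches `smear_dominance` of the major amplitude, so no dominant band
#' exists among mutually unresolved bands. Well-separated bands of similar
#' height are a readable two-allele pattern, not a smear.
#'
#' @param sized_peaks Sized peak table for one lane.
#' @param window Marker size window `c(lo, hi)`.
#' @param gel The lane's [gel_model()].
#' @param params [caller_params()].
#' @return `TRUE` if the marker is inconclusive at this tier.
#' @export
detect_smear <- function(sized_peaks, window, gel, params = caller_params()) {
  inw <- peaks_in_window(sized_peaks, window)
  if (!nrow(inw)) return(FALSE)  # handled as no_product upstream
  maj <- major_band(sized_peaks, window)
  if (maj$width_bp > params$smear_widen * gel$peak_sigma_bp) return(TRUE)
  if (isTRUE(maj$has_shoulder)) return(TRUE)  # unresolved component on a flank
  others <- inw[abs(inw$size_bp - maj$size_bp) > 1e-9, , drop = FALSE]
  if (!nrow(others)) return(FALSE)
  overlap <- abs(others$size_bp - maj$size_bp) < params$smear_overlap_sigma * gel$peak_sigma_bp
  any(overlap & others$amplitude >= params$smear_dominance * maj$amplitude)
}

#' Call one marker from paired tumor/normal sized peaks
#'
#' Applies the assay rule: a marker is unstable if the tumor major band is
#' shifted by `shift_bp` (>= 3 bp) or more relative to the normal major
#' band, or if the tumor shows new minor bands absent from the normal lane.
#' Sizes are rounded to integer bp before comparison, mirroring gel
#' readouts. A smeared tumor pattern makes the marker inconclusive at this
#' tier: `unstable` is forced `FALSE` and the decision is deferred to the
#' high-resolution tier. A missing product in either lane excludes the
#' marker (flag, not instability).
#'
#' @param tumor_peaks,normal_peaks Sized peak tables.
#' @param marker Marker name.
#' @param window Size window `c(lo, hi)`.
#' @param gel [gel_model()] of the tier the lanes were run on.
#' @param params [caller_params()].
#' @return A one-row `data.frame` (`marker_call`): `marker`,
#'   `normal_major_bp`, `tumor_major_bp`, `shift_bp`, `new_minor_bands`
#'   (list column), `n_new_minor`, `unstable`, `inconclusive`, `excluded`,
#'   `tier`.
#' @export
call_marker <- function(tumor_peaks, normal_peaks, marker, window, gel,
                        params = caller_params()) {
  tier <- gel$gel_type
  blank <- data.frame(marker = marker, normal_major_bp = NA_integer_,
                      tumor_major_bp = NA_integer_, shift_bp = NA_integer_,
                      n_new_minor = 0L, unstable = FALSE, inconclusive = FALSE,
                      excluded = FALSE, tier = tier, stringsAsFactors = FALSE)
  blank$new_minor_bands <- list(numeric())

  t_maj <- tryCatch(major_band(tumor_peaks, window), no_product = function(e) NULL)
  n_maj <- tryCatch(major_band(normal_peaks, window), no_product = function(e) NULL)
  if (is.null(t_maj) || is.null(n_maj)) {
    blank$excluded <- TRUE
    return(blank)
  }

  out <- blank
  out$normal_major_bp <- as.integer(round(n_maj$size_bp))
  out$tumor_major_bp <- as.integer(round(t_maj$size_bp))
  out$shift_bp <- out$tumor_major_bp - out$normal_major_bp

  tol <- params$match_tol_bp[[tier]]
  t_in <- peaks_in_window(tumor_peaks, window)
  n_in <- peaks_in_window(normal_peaks, window)
  cand <- t_in[t_in$amplitude >= params$minor_rel * t_maj$amplitude &
                 abs(t_in$size_bp - t_maj$size_bp) > 1e-9, , drop = FALSE]
  new_minor <- numeric()
  if (nrow(cand)) {
    n_sizes <- round(n_in$size_bp)
    is_new <- vapply(round(cand$size_bp), function(sz) {
      all(abs(sz - n_sizes) > tol)
    }, logical(1))
    new_minor <- round(cand$size_bp[is_new])
  }
  out$new_minor_bands <- list(new_minor)
  out$n_new_minor <- length(new_minor)

  out$inconclusive <- detect_smear(tumor_peaks, window, gel, params)
  if (out$inconclusive) {
    out$unstable <- FALSE  # undefined at this tier; status deferred
    return(out)
  }
  shift_hit <- if (params$sign_agnostic) abs(out$shift_bp) >= params$shift_bp
  else out$shift_bp <= -params$shift_bp
  out$unstable <- shift_hit || out$n_new_minor > 0L
  out
}

#' Call all panel markers for a tumor/normal lane pair
#'
#' @param tumor,normal `sized_lane` objects (anchor QC must have passed).
#' @param panel Marker panel.
#' @param gel [gel_model()] of the tier.
#' @param params [caller_params()].
#' @return A `data.frame` of marker calls, one row per panel marker.
#' @export
call_markers <- function(tumor, normal, panel = marker_panel(),
                         gel, params = caller_params()) {
  stopifnot(inherits(tumor, "sized_lane"), inherits(normal, "sized_lane"))
  if (!tumor$qc$pass || !normal$qc$pass) {
    stop("both lanes must pass anchor QC before marker calling")
  }
  calls <- lapply(panel$name, function(marker) {
    win <- marker_window(panel, marker)
    call_marker(tumor$peaks, normal$peaks, marker, win, gel, params)
  })
  do.call(rbind, calls)
}

#' Bethesda classification of a marker-call set
#'
#' MSI-H: instability at two or more of the five markers; MSI-L:
#' instability at exactly one locus; otherwise MSS. Order-invariant in the
#' markers. Any inconclusive call raises a `needs_escalation` error — the
#' sample must be re-run on the high-resolution gel first. Excluded
#' (no-product) markers reduce the conclusive count; fewer than
#' `min_conclusive` conclusive markers yields an indeterminate result.
#'
#' @param calls Marker-call `data.frame` (see [call_marker()]).
#' @param params [caller_params()].
#' @param case_id Optional case identifier carried into the result.
#' @param escalated Whether the high-resolution tier was used.
#' @return An object of class `sample_result`: `case_id`, `marker_calls`,
#'   `n_unstable`, `n_conclusive`, `status` (`MSS`/`MSI-L`/`MSI-H`/
#'   `Indeterminate`), `escalated`.
#' @export
classify_sample <- function(calls, params = caller_params(),
                            case_id = NA_character_, escalated = FALSE) {
  stopifnot(is.data.frame(calls))
  if (any(calls$inconclusive)) {
    stop(structure(class = c("needs_escalation", "error", "condition"),
                   list(message = paste0(
                     "inconclusive marker(s) at this tier: ",
                     paste(calls$marker[calls$inconclusive], collapse = ", ")),
                     call = sys.call())))
  }
  conclusive <- calls[!calls$excluded, , drop = FALSE]
  n_unstable <- sum(conclusive$unstable)
  status <- if (nrow(conclusive) < params$min_conclusive) {
    "Indeterminate"
  } else if (n_unstable == 0L) "MSS" else if (n_unstable == 1L) "MSI-L" else "MSI-H"
  structure(list(case_id = case_id, marker_calls = calls,
                 n_unstable = n_unstable, n_conclusive = nrow(conclusive),
                 status = status, escalated = escalated),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("<sample_result %s: %s (%d/%d markers unstable%s)>\n",
              x$case_id, x$status, x$n_unstable, x$n_conclusive,
              if (x$escalated) "; escalated" else ""))
  invisible(x)
}

#' Two-tier screening / high-resolution calling
#'
#' All markers are first called from the screening-gel lanes. Markers that
#' are conclusive there keep their screening calls and are never altered.
#' Markers that show an inconclusive smearing pattern are re-called from
#' high-resolution lanes obtained on demand from `highres_provider`; the
#' case is flagged `escalated` when any marker required the second tier. A
#' marker still inconclusive at high resolution (or an unavailable
#' provider) makes the case indeterminate — no status is forced.
#'
#' @param screening List with `ce_trace` elements `tumor` and `normal`
#'   (screening gel). Anchor QC must pass on both.
#' @param highres_provider `NULL`, or a zero-argument function returning a
#'   list with high-resolution `tumor` and `normal` traces.
#' @param panel Marker panel.
#' @param gels List with [gel_model()]s `screening` and `highres`.
#' @param params [caller_params()].
#' @param case_id Case identifier.
#' @param ... Passed to [size_trace()].
#' @return A `sample_result`.
#' @export
run_two_tier <- function(screening, highres_provider = NULL,
                         panel = marker_panel(),
                         gels = list(screening = gel_model("screening"),
                                     highres = gel_model("highres")),
                         params = caller_params(),
                         case_id = NA_character_, ...) {
  st <- size_trace(screening$tumor, gel = gels$screening, ...)
  sn <- size_trace(screening$normal, gel = gels$screening, ...)
  if (!st$qc$pass || !sn$qc$pass) {
    stop("screening lanes failed anchor QC (",
         paste(stats::na.omit(c(st$qc$reason, sn$qc$reason)), collapse = ", "),
         ")")
  }
  calls <- call_markers(st, sn, panel, gels$screening, params)
  escalated <- any(calls$inconclusive)
  if (escalated) {
    if (is.null(highres_provider)) {
      res <- classify_marker_set_indeterminate(calls, params, case_id, TRUE)
      return(res)
    }
    hr <- highres_provider()
    ht <- size_trace(hr$tumor, gel = gels$highres, ...)
    hn <- size_trace(hr$normal, gel = gels$highres, ...)
    if (!ht$qc$pass || !hn$qc$pass) {
      return(classify_marker_set_indeterminate(calls, params, case_id, TRUE))
    }
    for (marker in calls$marker[calls$inconclusive]) {
      win <- marker_window(panel, marker)
      recall <- call_marker(ht$peaks, hn$peaks, marker, win, gels$highres, params)
      calls[calls$marker == marker, setdiff(names(calls), "new_minor_bands")] <-
        recall[, setdiff(names(recall), "new_minor_bands")]
      calls$new_minor_bands[calls$marker == marker] <- recall$new_minor_bands
    }
    if (any(calls$inconclusive)) {
      return(classify_marker_set_indeterminate(calls, params, case_id, TRUE))
    }
  }
  classify_sample(calls, params, case_id = case_id, escalated = escalated)
}

classify_marker_set_indeterminate <- function(calls, params, case_id, escalated) {
  structure(list(case_id = case_id, marker_calls = calls,
                 n_unstable = NA_integer_,
                 n_conclusive = sum(!calls$excluded & !calls$inconclusive),
                 status = "Indeterminate", escalated = escalated),
            class = "sample_result")
}
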