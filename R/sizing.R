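# Peak detection, alignment-marker QC and two-anchor size calibration.

# Gaussian apex refinement: least-squares quadratic fit of log-signal over
# the contiguous region above half maximum. Bands are Gaussian on the size
# axis, so the fit is done in provisional (canonical) size coordinates,
# where the log of a clean band is globally quadratic; the fit is then
# exact for a clean band and noise-averaging otherwise. Returns the apex
# (in migration units), fitted amplitude, and fitted sigma (provisional
# size units), or NULL when the fit is not concave.
gaussian_refine <- function(m, s, i, lb, rb) {
  lo <- i
  while (lo > lb && s[lo - 1L] >= 0.5 * s[i] && s[lo - 1L] <= s[i]) lo <- lo - 1L
  hi <- i
  while (hi < rb && s[hi + 1L] >= 0.5 * s[i] && s[hi + 1L] <= s[i]) hi <- hi + 1L
  idx <- lo:hi
  idx <- idx[s[idx] > 0]
  if (length(idx) < 3L) return(NULL)
  x <- canon_size(m[idx]) - canon_size(m[i])
  co <- tryCatch(stats::lm.fit(cbind(1, x, x^2), log(s[idx]))$coefficients,
                 error = function(e) NULL)
  if (is.null(co) || anyNA(co) || co[3] >= 0) return(NULL)
  apex_x <- -co[2] / (2 * co[3])
  # refuse fits whose vertex escapes the fitted region
  if (apex_x < x[1] || apex_x > x[length(x)]) return(NULL)
  list(apex = canon_migration(canon_size(m[i]) + apex_x),
       amp = exp(co[1] - co[2]^2 / (4 * co[3])),
       sigma_x = sqrt(-1 / (2 * co[3])))
}

# Reference stutter-bundle band shape for a gel: the superposition of the
# parent band and its -1 bp stutter ladder, tabulated on a fine size-offset
# grid and normalized to apex height 1 at offset 0. Used as the expected
# shape of a clean single-allele band when judging shoulders.
bundle_shape <- function(gel) {
  if (gel$stutter_steps == 0L || gel$stutter_decay == 0) return(NULL)
  sig <- gel$peak_sigma_bp
  u <- seq(-(gel$stutter_steps + 5 * sig), 5 * sig, by = sig / 100)
  h <- rowSums(vapply(0:gel$stutter_steps, function(k) {
    gel$stutter_decay^k * exp(-(u + k)^2 / (2 * sig^2))
  }, numeric(length(u))))
  i_max <- which.max(h)
  u <- u - u[i_max]              # apex at offset 0
  h <- h / h[i_max]
  # FWHM of the clean bundle (size units), for scale matching
  above <- which(h >= 0.5)
  fwhm <- u[above[length(above)]] - u[above[1]]
  list(u = u, h = h, fwhm = fwhm, sigma_equiv = fwhm / (2 * sqrt(2 * log(2))))
}

# Half-maximum crossing on one side of an apex, bounded so the search never
# runs into a neighboring peak. Returns the interpolated migration position,
# or the bound itself when the signal does not fall below half within it.
half_crossing <- function(m, s, apex_idx, half, bound_idx, step) {
  j <- apex_idx
  repeat {
    nxt <- j + step
    if ((step < 0 && nxt < bound_idx) || (step > 0 && nxt > bound_idx)) {
      return(m[j])
    }
    if (s[nxt] <= half) {
      # linear interpolation between j and nxt
      frac <- (s[j] - half) / (s[j] - s[nxt])
      return(m[j] + frac * (m[nxt] - m[j]))
    }
    if (s[nxt] > s[apex_idx]) return(m[nxt])  # entered a taller neighbor
    j <- nxt
  }
}

peak_prominence <- function(s, i) {
  n <- length(s)
  minL <- s[i]; j <- i
  while (j > 1L) {
    j <- j - 1L
    if (s[j] > s[i]) break
    if (s[j] < minL) minL <- s[j]
  }
  if (j == 1L && s[1] <= s[i]) minL <- min(minL, s[1])
  minR <- s[i]; j <- i
  while (j < n) {
    j <- j + 1L
    if (s[j] > s[i]) break
    if (s[j] < minR) minR <- s[j]
  }
  s[i] - max(minL, minR)
}

#' Detect peaks in an electropherogram trace
#'
#' Local maxima exceeding a prominence threshold (a fraction of the lane
#' maximum) are retained, de-duplicated within a minimum separation, apex-
#' refined by log-quadratic interpolation, and annotated with width and a
#' shoulder flag. The shoulder criterion compares the signal within twice
#' the peak's width of the apex against the Gaussian implied by the apex
#' and the measured full width at half maximum; a residual exceeding 10% of
#' the amplitude (and clearly above the lane's noise floor) marks a
#' shoulder. Sizes are not assigned here; see [size_peaks()].
#'
#' @param trace A `ce_trace`.
#' @param min_prominence Prominence threshold as a fraction of the lane
#'   maximum (default 0.05: below this, bands are unreadable on either gel).
#' @param min_separation Minimum separation between retained peaks, in bp
#'   on the canonical size axis; defaults to one gel sigma.
#' @param gel Gel model used for the separation default.
#' @param shoulder_tol Residual fraction of amplitude flagged as a shoulder.
#' @return A `data.frame` of peaks sorted by migration: `migration_pos`,
#'   `amplitude`, `prominence`, `fwhm_m` (full width at half maximum,
#'   migration units), `has_shoulder`. Empty for an all-zero signal.
#' @export
detect_peaks <- function(trace, min_prominence = 0.05, min_separation = NULL,
                         gel = gel_model(trace$gel_type),
                         shoulder_tol = 0.10) {
  stopifnot(inherits(trace, "ce_trace"))
  m <- trace$migration
  s <- trace$signal
  n <- length(s)
  empty <- data.frame(migration_pos = numeric(), amplitude = numeric(),
                      prominence = numeric(), fwhm_m = numeric(),
                      has_shoulder = logical())
  if (n < 3L || max(s) <= 0) return(empty)
  if (is.null(min_separation)) min_separation <- gel$peak_sigma_bp

  cand <- which(s[2:(n - 1L)] > s[1:(n - 2L)] & s[2:(n - 1L)] >= s[3:n]) + 1L
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(s, i), numeric(1))
  keep <- prom >= min_prominence * max(s)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)

  # merge peaks closer than min_separation (canonical bp): keep the taller
  sz <- canon_size(m[cand])
  ord <- order(sz)
  cand <- cand[ord]; prom <- prom[ord]; sz <- sz[ord]
  repeat {
    if (length(cand) < 2L) break
    gaps <- diff(sz)
    tight <- which(gaps < min_separation)
    if (!length(tight)) break
    j <- tight[1L]
    drop <- if (s[cand[j]] >= s[cand[j + 1L]]) j + 1L else j
    cand <- cand[-drop]; prom <- prom[-drop]; sz <- sz[-drop]
  }

  noise_floor <- stats::mad(diff(s)) / sqrt(2)
  shape <- bundle_shape(gel)
  x <- canon_size(m)  # provisional size axis for band-shape geometry
  k <- length(cand)
  res <- data.frame(migration_pos = numeric(k), amplitude = s[cand],
                    prominence = prom, fwhm_m = numeric(k),
                    has_shoulder = logical(k))

  # Per-peak band model: either a plain Gaussian at the measured width or
  # the gel's stutter-bundle shape scale-matched to it, whichever fits the
  # peak's core better. Shoulders are then judged against the *sum* of all
  # peak models, so a well-resolved neighbor is explained while a hidden
  # allele riding on a flank is not.
  apex_m <- amp <- fwhm_v <- numeric(k)
  lb_v <- rb_v <- integer(k)
  models <- matrix(0, nrow = n, ncol = k)
  core <- vector("list", k)
  for (j in seq_len(k)) {
    i <- cand[j]
    lb <- if (j > 1L) floor((cand[j - 1L] + i) / 2) else 1L
    rb <- if (j < k) ceiling((i + cand[j + 1L]) / 2) else n
    half <- s[i] / 2
    left <- half_crossing(m, s, i, half, lb, -1L)
    right <- half_crossing(m, s, i, half, rb, 1L)
    fwhm <- max(right - left, m[2] - m[1])
    fit <- gaussian_refine(m, s, i, lb, rb)
    apex_m[j] <- if (is.null(fit)) m[i] else fit$apex
    amp[j] <- if (is.null(fit)) s[i] else fit$amp
    fwhm_v[j] <- fwhm
    lb_v[j] <- lb; rb_v[j] <- rb

    apex_x <- canon_size(apex_m[j])
    fwhm_x <- canon_size(apex_m[j] + fwhm / 2) - canon_size(apex_m[j] - fwhm / 2)
    g1 <- exp(-(x - apex_x)^2 / (2 * (fwhm_x / (2 * sqrt(2 * log(2))))^2))
    core_j <- which(abs(m - apex_m[j]) <= fwhm & seq_len(n) >= lb & seq_len(n) <= rb)
    core[[j]] <- core_j
    model_j <- g1
    if (!is.null(shape)) {
      tau <- fwhm_x / shape$fwhm
      g2 <- stats::approx(shape$u, shape$h, xout = (x - apex_x) / tau,
                          yleft = 0, yright = 0)$y
      r1 <- max(abs(s[core_j] - amp[j] * g1[core_j]))
      r2 <- max(abs(s[core_j] - amp[j] * g2[core_j]))
      if (r2 < r1) model_j <- g2
    }
    models[, j] <- model_j
  }

  # two rounds of joint amplitude refit against the residual of the others
  for (iter in 1:2) {
    for (j in seq_len(k)) {
      others <- if (k > 1L) models[, -j, drop = FALSE] %*% amp[-j] else 0
      cj <- core[[j]]
      denom <- sum(models[cj, j]^2)
      if (denom > 0) amp[j] <- max(0, sum((s[cj] - others[cj]) * models[cj, j]) / denom)
    }
  }

  # residuals are judged after a short moving average: a real flank
  # component is as wide as a band and survives, point noise does not
  total <- as.numeric(models %*% amp)
  rsm <- abs(s - total)
  kern <- 9L
  rsm <- as.numeric(stats::filter(rsm, rep(1 / kern, kern), sides = 2))
  for (j in seq_len(k)) {
    win <- which(abs(m - apex_m[j]) <= 2 * fwhm_v[j] &
                   seq_len(n) >= lb_v[j] & seq_len(n) <= rb_v[j])
    resid <- max(rsm[win], na.rm = TRUE)
    res$has_shoulder[j] <- resid > max(shoulder_tol * amp[j], 4 * noise_floor)
  }
  res$migration_pos <- apex_m
  res$fwhm_m <- fwhm_v
  res[order(res$migration_pos), , drop = FALSE]
}

default_anchor_windows <- function(trace, frac = 0.22) {
  span <- diff(range(trace$migration))
  list(low = c(min(trace$migration), min(trace$migration) + frac * span),
       high = c(max(trace$migration) - frac * span, max(trace$migration)))
}

#' Alignment-marker quality control
#'
#' Each lane must show each DNA alignment marker (15 and 1000 bp) as a
#' single peak with no shoulder. The verdict is `pass` only when exactly
#' one peak lies in each anchor search window and neither is shouldered;
#' otherwise the lane is flagged with a reason (`missing_anchor`,
#' `multiple_anchor_peaks` or `anchor_shoulder`) and must not be sized.
#'
#' @param peaks Peak table from [detect_peaks()].
#' @param trace The lane's `ce_trace` (used for the default search windows,
#'   the leading and trailing 22% of the migration range).
#' @param windows Optional list with numeric ranges `low` and `high`.
#' @return An object of class `anchor_qc`: list with `pass`, `reason`
#'   (`NA` if passing) and the two anchor peak rows.
#' @export
check_alignment_markers <- function(peaks, trace, windows = NULL) {
  if (is.null(windows)) windows <- default_anchor_windows(trace)
  in_low <- peaks$migration_pos >= windows$low[1] & peaks$migration_pos <= windows$low[2]
  in_high <- peaks$migration_pos >= windows$high[1] & peaks$migration_pos <= windows$high[2]
  verdict <- function(pass, reason = NA_character_, low = NULL, high = NULL) {
    structure(list(pass = pass, reason = reason,
                   anchor_low = low, anchor_high = high, windows = windows),
              class = "anchor_qc")
  }
  if (sum(in_low) == 0L || sum(in_high) == 0L) {
    return(verdict(FALSE, "missing_anchor"))
  }
  if (sum(in_low) > 1L || sum(in_high) > 1L) {
    return(verdict(FALSE, "multiple_anchor_peaks"))
  }
  low <- peaks[in_low, , drop = FALSE]
  high <- peaks[in_high, , drop = FALSE]
  if (low$has_shoulder || high$has_shoulder) {
    return(verdict(FALSE, "anchor_shoulder", low, high))
  }
  verdict(TRUE, NA_character_, low, high)
}

#' @export
print.anchor_qc <- function(x, ...) {
  if (x$pass) cat("<anchor_qc: pass>\n")
  else cat(sprintf("<anchor_qc: FAIL (%s)>\n", x$reason))
  invisible(x)
}

#' Two-anchor log-linear calibration model
#'
#' The classic DNA mobility approximation: fragment size is log-linear in
#' migration, `size(m) = exp(a + b * m)`, with `a` and `b` solved exactly
#' from the 15 and 1000 bp alignment-marker positions. Interpolates both
#' anchors exactly and is strictly monotone.
#'
#' @param m_low,m_high Migration positions of the 15 and 1000 bp anchors.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(m_low, m_high) {
  stopifnot(is.numeric(m_low), is.numeric(m_high),
            length(m_low) == 1L, length(m_high) == 1L)
  if (!is.finite(m_low) || !is.finite(m_high) || m_low == m_high) {
    stop("degenerate anchors: anchor positions must differ")
  }
  b <- CANON_LOGRATIO / (m_high - m_low)
  a <- log(ANCHOR_SIZES[["low"]]) - b * m_low
  structure(list(a = a, b = b, m_low = m_low, m_high = m_high),
            class = "calibration_model")
}

#' Fit the size calibration from an anchor QC verdict
#'
#' Refuses to calibrate lanes that failed alignment-marker QC: no sized
#' output exists for such lanes.
#'
#' @param qc An `anchor_qc` from [check_alignment_markers()].
#' @return A [calibration_model()].
#' @export
fit_calibration <- function(qc) {
  stopifnot(inherits(qc, "anchor_qc"))
  if (!isTRUE(qc$pass)) {
    stop("anchor QC failed (", qc$reason, "): lane is unusable for sizing")
  }
  calibration_model(qc$anchor_low$migration_pos, qc$anchor_high$migration_pos)
}

#' Evaluate a calibration model at migration positions
#'
#' @param model A [calibration_model()].
#' @param m Migration position(s).
#' @return Fragment size(s) in bp.
#' @export
size_at <- function(model, m) {
  stopifnot(inherits(model, "calibration_model"))
  exp(model$a + model$b * m)
}

#' Assign calibrated sizes to detected peaks
#'
#' Adds `size_bp` (reported to 0.1 bp precision downstream; stored at full
#' precision), `width_bp` (Gaussian-equivalent sd on the size axis) and an
#' `out_of_range` flag for peaks beyond the anchor span (sizes there are
#' extrapolated). Ordering by migration equals ordering by size.
#'
#' @param peaks Peak table from [detect_peaks()].
#' @param model A [calibration_model()].
#' @return The peak table with `size_bp`, `width_bp`, `out_of_range` added.
#' @export
size_peaks <- function(peaks, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (!nrow(peaks)) {
    peaks$size_bp <- numeric(0)
    peaks$width_bp <- numeric(0)
    peaks$out_of_range <- logical(0)
    return(peaks)
  }
  peaks$size_bp <- size_at(model, peaks$migration_pos)
  fwhm_bp <- size_at(model, peaks$migration_pos + peaks$fwhm_m / 2) -
    size_at(model, peaks$migration_pos - peaks$fwhm_m / 2)
  peaks$width_bp <- fwhm_bp / (2 * sqrt(2 * log(2)))
  lo <- min(model$m_low, model$m_high)
  hi <- max(model$m_low, model$m_high)
  peaks$out_of_range <- peaks$migration_pos < lo | peaks$migration_pos > hi
  peaks[order(peaks$migration_pos), , drop = FALSE]
}

#' Detect, QC and size a lane in one step
#'
#' Convenience wrapper chaining [detect_peaks()],
#' [check_alignment_markers()], [fit_calibration()] and [size_peaks()].
#'
#' @param trace A `ce_trace`.
#' @param ... Passed to [detect_peaks()].
#' @return An object of class `sized_lane`: list with `lane_id`, `gel_type`,
#'   `qc`, and (when QC passes) `model` and the sized `peaks` table.
#' @export
size_trace <- function(trace, ...) {
  peaks <- detect_peaks(trace, ...)
  qc <- check_alignment_markers(peaks, trace)
  out <- list(lane_id = trace$lane_id, gel_type = trace$gel_type, qc = qc,
              model = NULL, peaks = NULL)
  if (qc$pass) {
    out$model <- fit_calibration(qc)
    out$peaks <- size_peaks(peaks, out$model)
  }
  structure(out, class = "sized_lane")
}

#' @export
print.sized_lane <- function(x, ...) {
  if (x$qc$pass) {
    cat(sprintf("<sized_lane %s (%s): %d peaks>\n", x$lane_id, x$gel_type,
                nrow(x$peaks)))
  } else {
    cat(sprintf("<sized_lane %s (%s): QC FAIL (%s)>\n", x$lane_id, x$gel_type,
                x$qc$reason))
  }
  invisible(x)
}
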