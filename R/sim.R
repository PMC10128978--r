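# Electropherogram simulator: seeded synthetic lanes for the paired
# tumor/normal MSI-PCR experiments (cohorts and tumor-fraction titrations).

#' Derive a stable per-stream RNG seed
#'
#' Each simulated lane draws its noise from an independent stream keyed by
#' `(seed, id)`, so adding lanes to a run never perturbs existing ones. The
#' key is a 31-bit polynomial rolling hash of the id combined with the
#' top-level seed; it is stable across R versions and platforms.
#'
#' @param seed Top-level integer seed.
#' @param id Stream identifier (string).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(id), length(id) == 1L)
  mod <- 2147483647
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% mod
  as.integer((h + (abs(seed) %% mod) * 48271) %% mod)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Map a fragment size to a migration position
#'
#' The canonical migration axis is the exact inverse of the two-anchor
#' log-linear calibration: the 15 bp alignment marker sits at position 0 and
#' the 1000 bp marker at position 100, with `m = 100 * log(s/15)/log(1000/15)`
#' in between. A per-lane affine distortion is applied on top
#' (see [lane_distortion()]).
#'
#' @param size_bp Fragment size in bp, in `[1, 1200]`.
#' @param distortion A [lane_distortion()] object.
#' @return Migration position(s), strictly increasing in `size_bp`.
#' @export
size_to_migration <- function(size_bp, distortion = lane_distortion()) {
  stopifnot(inherits(distortion, "lane_distortion"))
  if (any(!is.finite(size_bp)) || any(size_bp <= 0)) {
    stop("size_bp must be positive")
  }
  if (any(size_bp < 1) || any(size_bp > 1200)) {
    stop("size_bp must lie in [1, 1200]")
  }
  distortion$alpha * canon_migration(size_bp) + distortion$beta
}

migration_grid <- function(from = -8, to = 106, by = 0.02) {
  seq(from, to, by = by)
}

new_trace <- function(lane_id, gel_type, role, migration, signal, case_id = NA_character_) {
  stopifnot(length(migration) == length(signal), all(diff(migration) > 0),
            all(signal >= 0))
  structure(
    list(lane_id = lane_id, gel_type = gel_type, role = role,
         migration = migration, signal = signal, case_id = case_id),
    class = "ce_trace"
  )
}

#' @export
print.ce_trace <- function(x, ...) {
  cat(sprintf("<ce_trace %s: %s %s lane, %d points, max signal %.1f>\n",
              x$lane_id, x$gel_type, x$role, length(x$migration), max(x$signal)))
  invisible(x)
}

#' Simulate one electrophoresis lane
#'
#' Renders a lane as signal over a fixed migration grid: one Gaussian band
#' (width `gel$peak_sigma_bp` in size units) per allele, a -1 bp stutter
#' ladder with geometrically decaying amplitude, sharp 15 and 1000 bp
#' alignment-marker bands, and additive Gaussian baseline noise drawn from
#' the lane's own seeded stream. Peak height is `amp_scale * amount`, so the
#' expected total area of a marker's peak family is proportional to the
#' total template amount and invariant in the tumor fraction.
#'
#' @param alleles Named list (by marker) of data.frames with columns `size`
#'   and `amount`; amounts per marker must sum to 1 and all sizes must lie
#'   inside the marker's window.
#' @param gel A [gel_model()].
#' @param panel Marker panel.
#' @param distortion A [lane_distortion()].
#' @param lane_id,role,case_id Lane metadata.
#' @param seed Top-level seed; the lane stream is `derive_seed(seed, lane_id)`.
#' @param amp_scale Peak height per unit template amount.
#' @param anchor_height Height of the alignment-marker bands.
#' @param grid Migration grid (shared by all lanes of a run).
#' @return A `ce_trace` object.
#' @export
simulate_lane <- function(alleles, gel, panel = marker_panel(),
                          distortion = lane_distortion(),
                          lane_id = "lane", role = "normal",
                          case_id = NA_character_, seed = 1,
                          amp_scale = 80, anchor_height = 100,
                          grid = migration_grid()) {
  stopifnot(inherits(gel, "gel_model"), inherits(distortion, "lane_distortion"))
  validate_panel(panel)
  if (!all(names(alleles) %in% panel$name)) {
    stop("alleles named for markers not in panel: ",
         paste(setdiff(names(alleles), panel$name), collapse = ", "))
  }

  # true size at each grid point under this lane's distortion
  s_at <- canon_size((grid - distortion$beta) / distortion$alpha)
  signal <- numeric(length(grid))

  for (marker in names(alleles)) {
    al <- alleles[[marker]]
    stopifnot(is.data.frame(al), all(c("size", "amount") %in% names(al)))
    al <- al[al$amount > 0, , drop = FALSE]
    if (!nrow(al)) next
    if (abs(sum(al$amount) - 1) > 1e-6) {
      stop("allele amounts for ", marker, " must sum to 1")
    }
    win <- marker_window(panel, marker)
    if (any(al$size < win[["lo"]] | al$size >= win[["hi"]])) {
      stop("allele size outside window for marker ", marker)
    }
    for (i in seq_len(nrow(al))) {
      for (k in 0:gel$stutter_steps) {
        h <- amp_scale * al$amount[i] * gel$stutter_decay^k
        if (h < 1e-9) break
        pos <- al$size[i] - k
        signal <- signal + h * exp(-(s_at - pos)^2 / (2 * gel$peak_sigma_bp^2))
      }
    }
  }

  # alignment markers: sharp bands, Gaussian on the migration axis
  m_anchor <- distortion$alpha * c(0, CANON_SPAN) + distortion$beta
  for (ma in m_anchor) {
    signal <- signal + anchor_height * exp(-(grid - ma)^2 / (2 * ANCHOR_SIGMA_M^2))
  }

  if (gel$noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, lane_id),
                       stats::rnorm(length(grid), 0, gel$noise_sd))
    signal <- signal + noise
  }
  new_trace(lane_id, gel$gel_type, role, grid, pmax(signal, 0), case_id)
}

germline_alleles <- function(panel) {
  al <- lapply(seq_len(nrow(panel)), function(i) {
    data.frame(size = panel$germline_size[i], amount = 1)
  })
  names(al) <- panel$name
  al
}

tumor_alleles <- function(truth, panel) {
  f <- truth$tumor_fraction
  al <- germline_alleles(panel)
  for (marker in truth$unstable_markers) {
    germ <- panel$germline_size[panel$name == marker]
    del <- truth$deletion_bp[[marker]]
    al[[marker]] <- data.frame(size = c(germ, germ - del), amount = c(1 - f, f))
  }
  al
}

sample_distortion <- function(seed, id, alpha_range = c(0.97, 1.03),
                              beta_range = c(-1, 1)) {
  with_seed(derive_seed(seed, paste0(id, "/dist")), {
    lane_distortion(alpha = stats::runif(1, alpha_range[1], alpha_range[2]),
                    beta = stats::runif(1, beta_range[1], beta_range[2]))
  })
}

#' Simulate a paired tumor/normal case
#'
#' The normal lane carries germline alleles only. For each unstable marker
#' the tumor lane carries a mixture of `(1 - f)` germline and `f` deleted
#' allele at `germline - deletion_bp`, where `f` is the tumor fraction.
#' Deletion lengths not given in the truth are drawn from a discrete uniform
#' distribution on `deletion_range` (default 11-16 bp: unstable
#' mononucleotide alleles in this assay shift predominantly by more than
#' 10 bp). Each lane gets its own seeded noise stream and, optionally, its
#' own random affine migration distortion.
#'
#' @param truth A [case_truth()].
#' @param gel A [gel_model()].
#' @param panel Marker panel.
#' @param seed Top-level seed.
#' @param distort If `TRUE`, draw a per-lane affine distortion; if a list
#'   with elements `normal` and `tumor` of class `lane_distortion`, use
#'   those; if `FALSE`, identity.
#' @param deletion_range Integer range for sampled deletion lengths (bp).
#' @param ... Passed to [simulate_lane()].
#' @return A list with elements `truth`, `normal` and `tumor` (`ce_trace`s).
#' @export
simulate_case <- function(truth, gel, panel = marker_panel(), seed = 1,
                          distort = TRUE, deletion_range = c(11L, 16L), ...) {
  stopifnot(inherits(truth, "case_truth"))
  missing_del <- setdiff(truth$unstable_markers, names(truth$deletion_bp))
  if (length(missing_del)) {
    drawn <- with_seed(derive_seed(seed, paste0(truth$case_id, "/del")), {
      stats::runif(length(missing_del))
    })
    del <- deletion_range[1] + floor(drawn * (deletion_range[2] - deletion_range[1] + 1L))
    names(del) <- missing_del
    truth$deletion_bp <- c(truth$deletion_bp, del)
  }
  ids <- paste0(truth$case_id, "/", gel$gel_type, c("/N", "/T"))
  dist_n <- dist_t <- lane_distortion()
  if (isTRUE(distort)) {
    dist_n <- sample_distortion(seed, ids[1])
    dist_t <- sample_distortion(seed, ids[2])
  } else if (is.list(distort)) {
    dist_n <- distort$normal
    dist_t <- distort$tumor
  }
  normal <- simulate_lane(germline_alleles(panel), gel, panel, dist_n,
                          lane_id = ids[1], role = "normal",
                          case_id = truth$case_id, seed = seed, ...)
  tumor <- simulate_lane(tumor_alleles(truth, panel), gel, panel, dist_t,
                         lane_id = ids[2], role = "tumor",
                         case_id = truth$case_id, seed = seed, ...)
  list(truth = truth, normal = normal, tumor = tumor)
}

#' Simulate a tumor-fraction dilution series
#'
#' Emulates the titration experiment in which MSI-positive DNA is mixed
#' with normal DNA at fractions 100/50/20/10/7.5/5/2.5% and each mixture is
#' run as its own lane against a shared normal background.
#'
#' @param marker_deletions Named integer vector: deletion length (bp) per
#'   marker for the MSI-positive template. Defaults to one 11-16 bp deletion
#'   per panel marker.
#' @param fractions Tumor-DNA fractions in `(0, 1]`, distinct; default is
#'   the seven-point series above.
#' @param gel,panel,seed,distort,... As in [simulate_case()].
#' @param series_id Identifier prefix for the lanes.
#' @return A list with `normal` (a `ce_trace`), `tumor` (list of `ce_trace`s
#'   in the order of `fractions`), `fractions` and `marker_deletions`.
#' @export
simulate_dilution_series <- function(marker_deletions = NULL,
                                     fractions = c(1, 0.5, 0.2, 0.1, 0.075, 0.05, 0.025),
                                     gel = gel_model("screening"),
                                     panel = marker_panel(), seed = 1,
                                     distort = FALSE, series_id = "dilution", ...) {
  if (!length(fractions)) stop("fractions must be nonempty")
  stopifnot(all(fractions > 0), all(fractions <= 1))
  if (anyDuplicated(fractions)) stop("fractions must be distinct")
  if (is.null(marker_deletions)) {
    marker_deletions <- c("NR-21" = 12L, "BAT-26" = 15L, "BAT-25" = 14L,
                          "NR-24" = 13L, "NR-27" = 16L)
  }
  stopifnot(!is.null(names(marker_deletions)),
            all(names(marker_deletions) %in% panel$name))

  dist_n <- if (isTRUE(distort)) sample_distortion(seed, paste0(series_id, "/N")) else lane_distortion()
  normal <- simulate_lane(germline_alleles(panel), gel, panel, dist_n,
                          lane_id = paste0(series_id, "/", gel$gel_type, "/N"),
                          role = "normal", case_id = series_id, seed = seed, ...)
  tumor <- lapply(fractions, function(f) {
    truth <- case_truth(series_id, unstable_markers = names(marker_deletions),
                        deletion_bp = marker_deletions, tumor_fraction = f,
                        panel = panel)
    id <- paste0(series_id, "/", gel$gel_type, "/f", format(f, trim = TRUE))
    dist_t <- if (isTRUE(distort)) sample_distortion(seed, id) else lane_distortion()
    simulate_lane(tumor_alleles(truth, panel), gel, panel, dist_t,
                  lane_id = id, role = "dilution", case_id = series_id,
                  seed = seed, ...)
  })
  list(normal = normal, tumor = tumor, fractions = fractions,
       marker_deletions = marker_deletions)
}

default_ihc_error <- function() {
  list(n_preserved_to_loss = 0L, n_loss_to_preserved = 0L)
}

msih_ihc_row <- function(case_id) {
  data.frame(case_id = case_id, mlh1 = "loss", msh2 = "preserved",
             msh6 = "preserved", pms2 = "loss", stringsAsFactors = FALSE)
}

preserved_ihc_row <- function(case_id) {
  data.frame(case_id = case_id, mlh1 = "preserved", msh2 = "preserved",
             msh6 = "preserved", pms2 = "preserved", stringsAsFactors = FALSE)
}

#' Simulate a tumor/normal cohort with IHC labels
#'
#' Draws case truths (MSI-H with probability `msi_h_prevalence`, otherwise
#' MSI-L with probability `msi_l_prevalence`, otherwise MSS), simulates the
#' paired screening-gel lanes for each case, and attaches per-protein MMR
#' IHC labels. IHC is generated as MLH1/PMS2 loss for MSI-H truth and
#' all-preserved otherwise, then perturbed according to `ihc_error`:
#' `n_preserved_to_loss` non-MSI-H cases are switched to isolated MSH6 loss
#' (the MSH6 discordance mode, in which mismatch-repair loss produces no
#' marker shift), and `n_loss_to_preserved` MSI-H cases are switched to
#' all-preserved.
#'
#' @param n Number of cases.
#' @param msi_h_prevalence,msi_l_prevalence Truth status probabilities.
#' @param gel Gel model for the simulated lanes (screening by default).
#' @param panel Marker panel.
#' @param tumor_fraction_range Range of the per-case tumor fraction
#'   (uniform draw); default 0.3-0.9, typical of macrodissected surgical
#'   CRC specimens.
#' @param n_unstable_range Range of the number of unstable markers for
#'   MSI-H cases (uniform over 2..5 by default).
#' @param ihc_error List with counts `n_preserved_to_loss` and
#'   `n_loss_to_preserved` (see above).
#' @param seed Top-level seed; all case and lane streams derive from it.
#' @param ... Passed to [simulate_case()].
#' @return An object of class `msi_cohort`: a list with `cases` (each a
#'   list `truth`, `normal`, `tumor`, `ihc`), plus `panel`, `gel`, `seed`.
#' @export
simulate_cohort <- function(n, msi_h_prevalence = 40 / 336,
                            msi_l_prevalence = 0.03,
                            gel = gel_model("screening"),
                            panel = marker_panel(),
                            tumor_fraction_range = c(0.3, 0.9),
                            n_unstable_range = c(2L, 5L),
                            ihc_error = default_ihc_error(),
                            seed = 1, ...) {
  stopifnot(n >= 1, msi_h_prevalence >= 0, msi_h_prevalence <= 1,
            msi_l_prevalence >= 0, msi_h_prevalence + msi_l_prevalence <= 1)
  ids <- sprintf("case%03d", seq_len(n))

  # each case's truth comes from its own id-keyed stream, so growing the
  # cohort never perturbs existing cases
  truths <- lapply(seq_len(n), function(i) {
    with_seed(derive_seed(seed, paste0("truth/", ids[i])), {
      u <- stats::runif(1)
      status <- if (u < msi_h_prevalence) "MSI-H"
      else if (u < msi_h_prevalence + msi_l_prevalence) "MSI-L" else "MSS"
      k <- switch(status,
                  "MSS" = 0L,
                  "MSI-L" = 1L,
                  "MSI-H" = sample(seq(n_unstable_range[1], n_unstable_range[2]), 1L))
      markers <- if (k > 0) sample(panel$name, k) else character()
      f <- stats::runif(1, tumor_fraction_range[1], tumor_fraction_range[2])
      case_truth(ids[i], unstable_markers = markers, tumor_fraction = f,
                 panel = panel)
    })
  })

  ihc <- do.call(rbind, lapply(truths, function(tr) {
    if (tr$true_status == "MSI-H") msih_ihc_row(tr$case_id) else preserved_ihc_row(tr$case_id)
  }))

  # seeded IHC perturbation: MSH6 discordance mode + missed-loss mode
  with_seed(derive_seed(seed, "cohort/ihc"), {
    not_h <- which(vapply(truths, function(tr) tr$true_status != "MSI-H", logical(1)))
    is_h <- setdiff(seq_len(n), not_h)
    k1 <- min(ihc_error$n_preserved_to_loss %||% 0L, length(not_h))
    k2 <- min(ihc_error$n_loss_to_preserved %||% 0L, length(is_h))
    if (k1 > 0) {
      flip <- sample(not_h, k1)
      ihc[flip, c("mlh1", "msh2", "pms2")] <- "preserved"
      ihc[flip, "msh6"] <- "loss"
    }
    if (k2 > 0) {
      flip <- sample(is_h, k2)
      ihc[flip, c("mlh1", "msh2", "msh6", "pms2")] <- "preserved"
    }
  })

  cases <- lapply(seq_len(n), function(i) {
    sim <- simulate_case(truths[[i]], gel, panel, seed = seed, ...)
    sim$ihc <- ihc[i, , drop = FALSE]
    sim
  })
  structure(list(cases = cases, panel = panel, gel = gel, seed = seed),
            class = "msi_cohort")
}

#' @export
print.msi_cohort <- function(x, ...) {
  status <- vapply(x$cases, function(cs) cs$truth$true_status, character(1))
  cat(sprintf("<msi_cohort: %d cases (%d MSI-H, %d MSI-L, %d MSS); %s gel; seed %d>\n",
              length(x$cases), sum(status == "MSI-H"), sum(status == "MSI-L"),
              sum(status == "MSS"), x$gel$gel_type, x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
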