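# End-to-end orchestration: config, cohort analysis, reports.

#' Default run configuration
#'
#' A nested list mirroring the YAML config layout: top-level `seed`, gel
#' model parameters per tier, caller thresholds, and the simulate-mode
#' block (cohort size, prevalences, tumor-fraction range, IHC error
#' counts, dilution fractions).
#'
#' @return A list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    gels = list(
      screening = list(peak_sigma_bp = 4.5, noise_sd = 1,
                       stutter_decay = 0.5, stutter_steps = 3L),
      highres = list(peak_sigma_bp = 1.0, noise_sd = 1,
                     stutter_decay = 0.5, stutter_steps = 3L)
    ),
    caller = list(shift_bp = 3L, sign_agnostic = TRUE, minor_rel = 0.10,
                  match_tol_screening = 3, match_tol_highres = 1,
                  smear_widen = 1.5, smear_overlap_sigma = 3,
                  smear_dominance = 0.5, min_conclusive = 4L),
    simulate = list(n_cases = 40L, msi_h_prevalence = 40 / 336,
                    msi_l_prevalence = 0.03,
                    tumor_fraction_range = c(0.3, 0.9),
                    ihc_error = list(n_preserved_to_loss = 0L,
                                     n_loss_to_preserved = 0L),
                    dilution = TRUE,
                    fractions = c(1, 0.5, 0.2, 0.1, 0.075, 0.05, 0.025)),
    analyze = list(traces = NULL, samplesheet = NULL)
  ), class = "run_config")
}

config_error <- function(msg) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a YAML run configuration
#'
#' Unspecified fields fall back to [default_config()]. Validation failures
#' abort before any output is produced.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) config_error("config file is not a YAML mapping")
    cfg <- structure(merge_config(unclass(cfg), user), class = "run_config")
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    config_error("seed must be a single integer")
  }
  if (cfg$caller$shift_bp < 1) config_error("caller$shift_bp must be >= 1")
  if (cfg$gels$screening$peak_sigma_bp <= cfg$gels$highres$peak_sigma_bp) {
    config_error("screening gel sigma must exceed high-resolution gel sigma")
  }
  fr <- cfg$simulate$fractions
  if (!length(fr) || any(fr <= 0) || any(fr > 1) || anyDuplicated(fr)) {
    config_error("simulate$fractions must be distinct values in (0, 1]")
  }
  invisible(cfg)
}

config_gels <- function(cfg) {
  list(
    screening = gel_model("screening",
                          peak_sigma_bp = cfg$gels$screening$peak_sigma_bp,
                          noise_sd = cfg$gels$screening$noise_sd,
                          stutter_decay = cfg$gels$screening$stutter_decay,
                          stutter_steps = cfg$gels$screening$stutter_steps),
    highres = gel_model("highres",
                        peak_sigma_bp = cfg$gels$highres$peak_sigma_bp,
                        noise_sd = cfg$gels$highres$noise_sd,
                        stutter_decay = cfg$gels$highres$stutter_decay,
                        stutter_steps = cfg$gels$highres$stutter_steps)
  )
}

config_params <- function(cfg) {
  caller_params(shift_bp = cfg$caller$shift_bp,
                sign_agnostic = cfg$caller$sign_agnostic,
                minor_rel = cfg$caller$minor_rel,
                match_tol_bp = c(screening = cfg$caller$match_tol_screening,
                                 highres = cfg$caller$match_tol_highres),
                smear_widen = cfg$caller$smear_widen,
                smear_overlap_sigma = cfg$caller$smear_overlap_sigma,
                smear_dominance = cfg$caller$smear_dominance,
                min_conclusive = cfg$caller$min_conclusive)
}

#' Analyze a simulated cohort with the two-tier workflow
#'
#' Runs every case's screening pair through [run_two_tier()]; inconclusive
#' markers trigger on-demand simulation of the case's high-resolution
#' lanes (seeded deterministically from the cohort seed).
#'
#' @param cohort An `msi_cohort` from [simulate_cohort()].
#' @param gels List of [gel_model()]s (`screening`, `highres`).
#' @param params [caller_params()].
#' @return A list: `results` (`data.frame` of case_id, status, n_unstable,
#'   escalated, true_status), `sample_results` (the full objects).
#' @export
analyze_cohort <- function(cohort,
                           gels = list(screening = cohort$gel,
                                       highres = gel_model("highres",
                                                           noise_sd = cohort$gel$noise_sd)),
                           params = caller_params()) {
  stopifnot(inherits(cohort, "msi_cohort"))
  sample_results <- lapply(cohort$cases, function(cs) {
    provider <- function() {
      hr <- simulate_case(cs$truth, gels$highres, cohort$panel,
                          seed = cohort$seed)
      list(tumor = hr$tumor, normal = hr$normal)
    }
    run_two_tier(list(tumor = cs$tumor, normal = cs$normal),
                 highres_provider = provider, panel = cohort$panel,
                 gels = gels, params = params, case_id = cs$truth$case_id)
  })
  results <- do.call(rbind, lapply(seq_along(sample_results), function(i) {
    sr <- sample_results[[i]]
    data.frame(case_id = sr$case_id, status = sr$status,
               n_unstable = sr$n_unstable, escalated = sr$escalated,
               true_status = cohort$cases[[i]]$truth$true_status,
               stringsAsFactors = FALSE)
  }))
  list(results = results, sample_results = sample_results)
}

#' Tier-resolution summary of a cohort run
#'
#' @param results Cohort results `data.frame` with an `escalated` column
#'   (and optionally `status`).
#' @return A list: `n`, `n_tier1`, `n_escalated`, `n_indeterminate`,
#'   `pct_tier1`, `pct_escalated` (percentages to 1 decimal).
#' @export
tier_summary <- function(results) {
  stopifnot(is.data.frame(results), "escalated" %in% names(results))
  n <- nrow(results)
  if (!n) stop("empty results")
  n_esc <- sum(results$escalated)
  n_ind <- if ("status" %in% names(results)) {
    sum(results$status == "Indeterminate")
  } else 0L
  list(n = n, n_tier1 = n - n_esc, n_escalated = n_esc,
       n_indeterminate = n_ind,
       pct_tier1 = as_percent((n - n_esc) / n),
       pct_escalated = as_percent(n_esc / n))
}

#' Analyze user-provided traces against a sample sheet
#'
#' Pairs tumor and normal screening lanes per the sample sheet and runs
#' the two-tier caller; high-resolution lanes (columns
#' `highres_tumor_lane`/`highres_normal_lane`) are consumed on demand.
#' Lanes failing anchor QC make their case indeterminate and are listed.
#'
#' @param traces Named list of `ce_trace` objects (see [read_traces()]).
#' @param samplesheet `data.frame` from [read_samplesheet()].
#' @param panel,gels,params As in [analyze_cohort()].
#' @return A list: `results` `data.frame`, `sample_results`, `qc_failures`
#'   (character vector of lane ids).
#' @export
analyze_traces <- function(traces, samplesheet, panel = marker_panel(),
                           gels = list(screening = gel_model("screening"),
                                       highres = gel_model("highres")),
                           params = caller_params()) {
  qc_failures <- character()
  sample_results <- list()
  for (i in seq_len(nrow(samplesheet))) {
    row <- samplesheet[i, , drop = FALSE]
    lanes <- c(row$tumor_lane, row$normal_lane)
    if (!all(lanes %in% names(traces))) {
      stop("sample sheet references missing lane(s): ",
           paste(setdiff(lanes, names(traces)), collapse = ", "))
    }
    provider <- NULL
    hr_cols <- c("highres_tumor_lane", "highres_normal_lane")
    if (all(hr_cols %in% names(row)) && !anyNA(row[, hr_cols]) &&
        all(nzchar(unlist(row[, hr_cols])))) {
      hr_t <- row$highres_tumor_lane; hr_n <- row$highres_normal_lane
      if (all(c(hr_t, hr_n) %in% names(traces))) {
        provider <- function() list(tumor = traces[[hr_t]], normal = traces[[hr_n]])
      }
    }
    sr <- tryCatch(
      run_two_tier(list(tumor = traces[[row$tumor_lane]],
                        normal = traces[[row$normal_lane]]),
                   highres_provider = provider, panel = panel, gels = gels,
                   params = params, case_id = row$case_id),
      error = function(e) {
        qc_failures <<- c(qc_failures, lanes)
        structure(list(case_id = row$case_id, marker_calls = NULL,
                       n_unstable = NA_integer_, n_conclusive = 0L,
                       status = "Indeterminate", escalated = FALSE),
                  class = "sample_result")
      })
    sample_results[[i]] <- sr
  }
  results <- do.call(rbind, lapply(sample_results, function(sr) {
    data.frame(case_id = sr$case_id, status = sr$status,
               n_unstable = sr$n_unstable, escalated = sr$escalated,
               stringsAsFactors = FALSE)
  }))
  list(results = results, sample_results = sample_results,
       qc_failures = unique(qc_failures))
}

write_peak_tables <- function(sized_lanes, path) {
  rows <- lapply(sized_lanes, function(sl) {
    if (is.null(sl$peaks) || !nrow(sl$peaks)) return(NULL)
    cbind(data.frame(lane_id = sl$lane_id, stringsAsFactors = FALSE),
          sl$peaks[, c("migration_pos", "size_bp", "amplitude", "width_bp",
                       "has_shoulder", "out_of_range")])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_case_calls <- function(sample_results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sr in sample_results) {
    calls <- sr$marker_calls
    rec <- list(case_id = sr$case_id, status = sr$status,
                n_unstable = sr$n_unstable, escalated = sr$escalated,
                marker_calls = if (is.null(calls)) list() else calls)
    jsonlite::write_json(rec, file.path(dir, paste0(sr$case_id, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(dir)
}

#' Run the full pipeline
#'
#' In `simulate` mode, generates a seeded cohort (and optionally a
#' dilution series on both gels), then analyzes it end to end; in
#' `analyze` mode, consumes user trace TSVs and a sample sheet. Always
#' writes: a cohort status TSV, per-case call JSONs, per-lane peak tables,
#' an LOD TSV (when dilution lanes are present), a concordance JSON (when
#' IHC labels are present) and a run log with the config hash and seed.
#' Re-running with the same config byte-for-byte reproduces all outputs.
#'
#' @param config A `run_config` (see [read_config()]).
#' @param mode `"simulate"` or `"analyze"`.
#' @param out_dir Output directory (created if needed).
#' @return A summary list: `results`, `tier`, `concordance` (or `NULL`),
#'   `lod` (or `NULL`), `qc_failures`, `out_dir`.
#' @export
run_pipeline <- function(config = default_config(),
                         mode = c("simulate", "analyze"), out_dir) {
  mode <- match.arg(mode)
  validate_config(config)
  gels <- config_gels(config)
  params <- config_params(config)
  seed <- as.integer(config$seed)

  concordance <- NULL
  lod <- NULL
  qc_failures <- character()

  if (mode == "simulate") {
    sim <- config$simulate
    cohort <- simulate_cohort(n = sim$n_cases,
                              msi_h_prevalence = sim$msi_h_prevalence,
                              msi_l_prevalence = sim$msi_l_prevalence,
                              gel = gels$screening,
                              tumor_fraction_range = sim$tumor_fraction_range,
                              ihc_error = sim$ihc_error, seed = seed)
    an <- analyze_cohort(cohort, gels = gels, params = params)
    results <- an$results
    sample_results <- an$sample_results

    ihc <- do.call(rbind, lapply(cohort$cases, `[[`, "ihc"))
    status <- stats::setNames(results$status, results$case_id)
    callable <- status != "Indeterminate"
    concordance <- concordance_report(status[callable],
                                      ihc[match(names(status)[callable],
                                                ihc$case_id), , drop = FALSE])
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_traces(unlist(lapply(cohort$cases,
                               function(cs) list(cs$normal, cs$tumor)),
                        recursive = FALSE),
                 file.path(out_dir, "traces.tsv"))
    write_truth(lapply(cohort$cases, `[[`, "truth"),
                file.path(out_dir, "truth.json"))

    if (isTRUE(sim$dilution)) {
      lod_rows <- lapply(gels, function(gel) {
        series <- simulate_dilution_series(fractions = sim$fractions,
                                           gel = gel, seed = seed)
        lod_table(dilution_calls(series, gel, params = params))
      })
      lod <- do.call(rbind, lod_rows)
      rownames(lod) <- NULL
    }
  } else {
    if (is.null(config$analyze$traces) || is.null(config$analyze$samplesheet)) {
      config_error("analyze mode requires analyze$traces and analyze$samplesheet")
    }
    sheet <- read_samplesheet(config$analyze$samplesheet)
    traces <- read_traces(config$analyze$traces)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    an <- analyze_traces(traces, sheet, gels = gels, params = params)
    results <- an$results
    sample_results <- an$sample_results
    qc_failures <- an$qc_failures
    if (all(IHC_PROTEINS %in% names(sheet))) {
      status <- stats::setNames(results$status, results$case_id)
      callable <- status != "Indeterminate"
      concordance <- concordance_report(
        status[callable],
        sheet[match(names(status)[callable], sheet$case_id),
              c("case_id", IHC_PROTEINS), drop = FALSE])
    }
  }

  utils::write.table(results, file.path(out_dir, "cohort_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_case_calls(sample_results, file.path(out_dir, "calls"))
  if (!is.null(lod)) {
    utils::write.table(lod, file.path(out_dir, "lod.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tier <- tier_summary(results)
  if (!is.null(concordance)) {
    jsonlite::write_json(
      list(table = unclass(concordance$table), n = concordance$n,
           concordant = concordance$concordant, percent = concordance$percent,
           discordant_cases = concordance$discordant_cases),
      file.path(out_dir, "concordance.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  log_lines <- c(
    sprintf("msipcr run (%s mode)", mode),
    sprintf("seed: %d", seed),
    sprintf("config md5: %s", cfg_hash),
    sprintf("cases: %d; tier-1 resolved: %d (%.1f%%); escalated: %d",
            tier$n, tier$n_tier1, tier$pct_tier1, tier$n_escalated),
    if (length(qc_failures)) {
      sprintf("anchor-QC failed lanes (excluded): %s",
              paste(qc_failures, collapse = ", "))
    } else "anchor-QC failed lanes: none"
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  list(results = results, tier = tier, concordance = concordance, lod = lod,
       qc_failures = qc_failures, out_dir = out_dir)
}
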