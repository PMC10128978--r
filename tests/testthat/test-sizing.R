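panel <- marker_panel()
g_scr0 <- gel_model("screening", noise_sd = 0, stutter_steps = 0)

test_that("detect_peaks handles degenerate and clean inputs", {
  tr <- simulate_lane(germline_alleles(panel), g_scr0, panel, seed = 1)
  tr$signal <- rep(0, length(tr$signal))
  expect_identical(nrow(detect_peaks(tr, gel = g_scr0)), 0L)

  tr <- simulate_lane(germline_alleles(panel), g_scr0, panel, seed = 1)
  pk <- detect_peaks(tr, gel = g_scr0)
  expect_identical(nrow(pk), 7L)
  expect_false(any(pk$has_shoulder))
  expect_true(all(diff(pk$migration_pos) > 0))
})

test_that("a hidden minor allele flags a shoulder on the merged band", {
  # 0.7/0.3 mixture 14 bp apart: unimodal against the detection threshold,
  # but the flank is not explained by a clean band shape
  al <- germline_alleles(panel)
  al[["BAT-26"]] <- data.frame(size = c(135, 121), amount = c(0.7, 0.3))
  tr <- simulate_lane(al, g_scr0, panel, seed = 1)
  pk <- detect_peaks(tr, gel = g_scr0)
  sizes <- msipcr:::canon_size(pk$migration_pos)
  inw <- sizes >= 110 & sizes < 143
  expect_identical(sum(inw), 1L)
  expect_true(pk$has_shoulder[inw])
  # isolated single-allele markers in the same lane stay clean
  iso <- sizes >= 145 & sizes < 248
  expect_false(any(pk$has_shoulder[iso]))
})

test_that("alignment-marker QC passes clean lanes and names its failures", {
  tr <- simulate_lane(germline_alleles(panel), g_scr0, panel, seed = 1)
  qc <- check_alignment_markers(detect_peaks(tr, gel = g_scr0), tr)
  expect_true(qc$pass)

  dup <- simulate_lane(germline_alleles(panel), g_scr0, panel, seed = 1)
  dup$signal <- dup$signal + 100 * exp(-(dup$migration - 10)^2 / (2 * 0.3^2))
  qc <- check_alignment_markers(detect_peaks(dup, gel = g_scr0), dup)
  expect_false(qc$pass)
  expect_identical(qc$reason, "multiple_anchor_peaks")

  missing <- simulate_lane(germline_alleles(panel), g_scr0, panel, seed = 1,
                           anchor_height = 0)
  qc <- check_alignment_markers(detect_peaks(missing, gel = g_scr0), missing)
  expect_false(qc$pass)
  expect_identical(qc$reason, "missing_anchor")

  sh <- simulate_lane(germline_alleles(panel), g_scr0, panel, seed = 1)
  sh$signal <- sh$signal + 60 * exp(-(sh$migration - 100.8)^2 / (2 * 0.3^2))
  qc <- check_alignment_markers(detect_peaks(sh, gel = g_scr0), sh)
  expect_false(qc$pass)
  expect_identical(qc$reason, "anchor_shoulder")
  expect_error(fit_calibration(qc), "unusable")
})

test_that("two-anchor calibration interpolates exactly and is log-linear", {
  model <- calibration_model(100, 900)
  expect_equal(size_at(model, 100), 15)
  expect_equal(size_at(model, 900), 1000)
  expect_equal(size_at(model, 500), sqrt(15 * 1000), tolerance = 1e-12)
  expect_error(calibration_model(250, 250), "degenerate")
})

test_that("size_peaks populates sizes, widths and range flags", {
  model <- calibration_model(0, 100)
  empty <- detect_peaks(structure(list(lane_id = "x", gel_type = "screening",
                                       role = "normal",
                                       migration = c(0, 1, 2),
                                       signal = c(0, 0, 0),
                                       case_id = NA_character_),
                                  class = "ce_trace"))
  sized <- size_peaks(empty, model)
  expect_identical(nrow(sized), 0L)
  expect_true(all(c("size_bp", "width_bp", "out_of_range") %in% names(sized)))

  pk <- data.frame(migration_pos = c(-2, 50, 102), amplitude = c(5, 10, 5),
                   prominence = c(5, 10, 5), fwhm_m = c(0.5, 1, 0.5),
                   has_shoulder = FALSE)
  sized <- size_peaks(pk, model)
  expect_identical(sized$out_of_range, c(TRUE, FALSE, TRUE))
  expect_equal(sized$size_bp[2], sqrt(15 * 1000), tolerance = 1e-9)
  expect_identical(order(sized$migration_pos), order(sized$size_bp))
})

test_that("noise-free sizes round-trip within 0.1 bp under any distortion", {
  for (gt in c("screening", "highres")) {
    gel <- gel_model(gt, noise_sd = 0, stutter_steps = 0)
    for (dist in list(lane_distortion(), lane_distortion(1.03, -0.8),
                      lane_distortion(0.97, 0.9))) {
      tr <- simulate_lane(germline_alleles(panel), gel, panel,
                          distortion = dist, seed = 1)
      sl <- size_trace(tr, gel = gel)
      expect_true(sl$qc$pass)
      got <- sl$peaks$size_bp[!sl$peaks$out_of_range &
                                sl$peaks$size_bp > 20 & sl$peaks$size_bp < 900]
      expect_equal(sort(got), sort(panel$germline_size), tolerance = 0.1 / 100)
      expect_lt(max(abs(sort(got) - sort(panel$germline_size))), 0.1)
      # the anchors themselves size to 15 and 1000
      expect_equal(min(sl$peaks$size_bp), 15, tolerance = 1e-6)
      expect_equal(max(sl$peaks$size_bp), 1000, tolerance = 1e-6)
    }
  }
})

test_that("no sized output exists for lanes failing anchor QC", {
  tr <- simulate_lane(germline_alleles(panel), g_scr0, panel, seed = 1,
                      anchor_height = 0)
  sl <- size_trace(tr, gel = g_scr0)
  expect_false(sl$qc$pass)
  expect_null(sl$peaks)
  expect_null(sl$model)
})
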