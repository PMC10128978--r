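test_that("size_to_migration places the anchors and the log-linear midpoint", {
  expect_equal(size_to_migration(15), 0)
  expect_equal(size_to_migration(1000), 100)
  # geometric mean of the anchors maps to the midpoint of their positions
  expect_equal(size_to_migration(sqrt(15 * 1000)), 50, tolerance = 1e-12)
  sizes <- seq(2, 1100, length.out = 200)
  expect_true(all(diff(size_to_migration(sizes)) > 0))
  expect_error(size_to_migration(-3), "positive")
  expect_error(size_to_migration(0.5), "1, 1200")
  # distorted anchors are recovered by the affine map
  d <- lane_distortion(1.02, -0.7)
  expect_equal(size_to_migration(15, d), -0.7 + 0)
  expect_equal(size_to_migration(1000, d), 1.02 * 100 - 0.7)
})

test_that("a clean single-allele lane shows 5 marker bands plus 2 anchors", {
  panel <- marker_panel()
  for (gt in c("screening", "highres")) {
    gel <- gel_model(gt, noise_sd = 0, stutter_steps = 0)
    tr <- simulate_lane(germline_alleles(panel), gel, panel, seed = 1)
    pk <- detect_peaks(tr, gel = gel)
    expect_identical(nrow(pk), 7L)
    expect_false(any(pk$has_shoulder))
  }
})

test_that("identical seeds and arguments give bit-identical traces", {
  panel <- marker_panel()
  gel <- gel_model("screening")
  a <- simulate_lane(germline_alleles(panel), gel, panel, seed = 7, lane_id = "L1")
  b <- simulate_lane(germline_alleles(panel), gel, panel, seed = 7, lane_id = "L1")
  expect_identical(a, b)
  # a different lane id draws from its own stream
  c <- simulate_lane(germline_alleles(panel), gel, panel, seed = 7, lane_id = "L2")
  expect_false(identical(a$signal, c$signal))
  expect_true(derive_seed(7, "L1") != derive_seed(7, "L2"))
  expect_true(derive_seed(7, "L1") >= 0 && derive_seed(7, "L1") < 2^31)
})

test_that("a 12 bp deletion at equal mixture is bimodal on the screening gel", {
  panel <- marker_panel()
  gel <- gel_model("screening", noise_sd = 0, stutter_steps = 0)
  # peak-separation oracle on the analytic mixture: 12 bp > 2 sigma
  expect_identical(mix_modes(c(135, 123), c(0.5, 0.5), gel$peak_sigma_bp), 2L)
  al <- germline_alleles(panel)
  al[["BAT-26"]] <- data.frame(size = c(135, 123), amount = c(0.5, 0.5))
  tr <- simulate_lane(al, gel, panel, seed = 1)
  pk <- detect_peaks(tr, gel = gel)
  sizes <- msipcr:::canon_size(pk$migration_pos)
  expect_identical(sum(sizes >= 110 & sizes < 143), 2L)
})

test_that("lane construction rejects invalid allele maps", {
  panel <- marker_panel()
  gel <- gel_model("screening")
  al <- germline_alleles(panel)
  al[["BAT-26"]] <- data.frame(size = 150, amount = 1)  # outside [110, 143)
  expect_error(simulate_lane(al, gel, panel, seed = 1), "outside window")
  al[["BAT-26"]] <- data.frame(size = c(135, 123), amount = c(0.5, 0.4))
  expect_error(simulate_lane(al, gel, panel, seed = 1), "sum to 1")
})

test_that("marker peak-family area is invariant in the tumor fraction", {
  panel <- marker_panel()
  # high-resolution gel: both allele bundles fit entirely inside the window
  gel <- gel_model("highres", noise_sd = 0)
  area <- function(f) {
    truth <- case_truth("a", "BAT-26", c("BAT-26" = 14L), f)
    tr <- simulate_lane(msipcr:::tumor_alleles(truth, panel), gel, panel, seed = 1)
    s <- msipcr:::canon_size(tr$migration)
    keep <- s >= 110 & s < 143
    sum(tr$signal[keep] * c(diff(s[keep]), 0))  # integral on the size axis
  }
  expect_equal(area(0.3), area(0.7), tolerance = 1e-6)
  expect_equal(area(0.2), area(1.0), tolerance = 1e-6)
})

test_that("case simulation honors the truth model", {
  panel <- marker_panel()
  gel <- gel_model("highres", noise_sd = 0)
  # MSS: tumor and normal carry identical expected peak sets
  mss <- simulate_case(case_truth("m1"), gel, panel, seed = 2)
  st <- size_trace(mss$tumor, gel = gel)
  sn <- size_trace(mss$normal, gel = gel)
  expect_identical(nrow(st$peaks), nrow(sn$peaks))
  expect_equal(st$peaks$size_bp, sn$peaks$size_bp, tolerance = 0.1)
  # two unstable markers at f = 1, no noise: downstream call is MSI-H
  truth <- case_truth("m2", c("BAT-26", "NR-24"),
                      c("BAT-26" = 15L, "NR-24" = 13L), 1)
  sim <- simulate_case(truth, gel, panel, seed = 2)
  calls <- call_markers(size_trace(sim$tumor, gel = gel),
                        size_trace(sim$normal, gel = gel), panel, gel)
  expect_identical(classify_sample(calls)$status, "MSI-H")
  # one unstable marker at f = 1: MSI-L
  truth <- case_truth("m3", "NR-27", c("NR-27" = 14L), 1)
  sim <- simulate_case(truth, gel, panel, seed = 2)
  calls <- call_markers(size_trace(sim$tumor, gel = gel),
                        size_trace(sim$normal, gel = gel), panel, gel)
  expect_identical(classify_sample(calls)$status, "MSI-L")
})

test_that("dilution series has the expected structure", {
  gel <- gel_model("highres", noise_sd = 0)
  ser <- simulate_dilution_series(gel = gel, seed = 1)
  expect_identical(length(ser$tumor), 7L)
  expect_identical(ser$fractions, c(1, 0.5, 0.2, 0.1, 0.075, 0.05, 0.025))
  expect_s3_class(ser$normal, "ce_trace")
  expect_error(simulate_dilution_series(fractions = numeric(), gel = gel),
               "nonempty")
  expect_error(simulate_dilution_series(fractions = c(0.5, 0.5), gel = gel),
               "distinct")
  # a single-point series at f = 1 equals the pure-tumor case lane
  dels <- c("BAT-26" = 15L)
  one <- simulate_dilution_series(dels, fractions = 1, gel = gel, seed = 1)
  truth <- case_truth("dilution", "BAT-26", dels, 1)
  ref <- simulate_lane(msipcr:::tumor_alleles(truth, marker_panel()), gel,
                       seed = 1)
  expect_equal(one$tumor[[1]]$signal, ref$signal)
})

test_that("a 2.5% minor allele sits below the caller's minor-band threshold", {
  gel <- gel_model("highres", noise_sd = 0)
  ser <- simulate_dilution_series(gel = gel, seed = 1)
  calls <- dilution_calls(ser, gel)
  # 0.025/0.975 < 10% relative amplitude: no marker can be called unstable
  expect_true(all(!calls$unstable[calls$fraction == 0.025]))
  expect_true(all(calls$unstable[calls$fraction == 1]))
})

test_that("cohort truths, IHC labels and prefix stability behave", {
  co <- simulate_cohort(30, msi_h_prevalence = 0, msi_l_prevalence = 0.2,
                        seed = 4)
  status <- vapply(co$cases, function(cs) cs$truth$true_status, character(1))
  expect_true(all(status %in% c("MSS", "MSI-L")))

  co <- simulate_cohort(40, msi_h_prevalence = 0.3, seed = 5,
                        ihc_error = list(n_preserved_to_loss = 4L,
                                         n_loss_to_preserved = 1L))
  ihc <- do.call(rbind, lapply(co$cases, `[[`, "ihc"))
  truth_h <- vapply(co$cases, function(cs) cs$truth$true_status == "MSI-H",
                    logical(1))
  dich <- dichotomize_ihc(ihc)
  # exactly 4 non-MSI-H flipped to (isolated MSH6) loss, 1 MSI-H to preserved
  expect_identical(sum(dich == "Loss" & !truth_h), 4L)
  expect_true(all(ihc$msh6[dich == "Loss" & !truth_h] == "loss"))
  expect_true(all(ihc$mlh1[dich == "Loss" & !truth_h] == "preserved"))
  expect_identical(sum(dich == "Preserved" & truth_h), 1L)

  # extending the cohort never perturbs existing cases
  a <- simulate_cohort(3, seed = 11)
  b <- simulate_cohort(5, seed = 11)
  for (i in 1:3) {
    expect_identical(a$cases[[i]]$truth, b$cases[[i]]$truth)
    expect_identical(a$cases[[i]]$tumor$signal, b$cases[[i]]$tumor$signal)
  }
})
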