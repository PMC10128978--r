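win <- c(lo = 105, hi = 143)
g_hr <- gel_model("highres")

test_that("major_band takes the tallest peak, ties toward smaller size", {
  one <- peak_row(120, 10)
  expect_equal(major_band(one, win)$size_bp, 120)
  two <- peak_table(peak_row(120, 10), peak_row(112, 30))
  expect_equal(major_band(two, win)$size_bp, 112)
  tie <- peak_table(peak_row(112, 30), peak_row(120, 30))
  expect_equal(major_band(tie, win)$size_bp, 112)
  expect_error(major_band(peak_row(200, 10), win), class = "no_product")
})

test_that("smear detection follows the width, shoulder and dominance rules", {
  sharp <- peak_row(120, 50, width_bp = 1.0)
  expect_false(detect_smear(sharp, win, g_hr))
  broad <- peak_row(120, 50, width_bp = 1.6)  # > 1.5 x gel sigma
  expect_true(detect_smear(broad, win, g_hr))
  shouldered <- peak_row(120, 50, width_bp = 1.0, has_shoulder = TRUE)
  expect_true(detect_smear(shouldered, win, g_hr))
  # overlapping near-equal bands: no dominant band
  overlap <- peak_table(peak_row(120, 50), peak_row(122, 40))
  expect_true(detect_smear(overlap, win, g_hr))
  # well-separated near-equal bands are a readable two-allele pattern
  resolved <- peak_table(peak_row(120, 50), peak_row(131, 40))
  expect_false(detect_smear(resolved, win, g_hr))
  # empty window is no_product upstream, not a smear
  expect_false(detect_smear(peak_row(200, 10), win, g_hr))
})

test_that("the 3 bp shift rule holds across the whole truth table", {
  normal <- peak_row(120, 50)
  for (d in -5:5) {
    tumor <- peak_row(120 + d, 50)
    call <- call_marker(tumor, normal, "M", win, g_hr)
    expect_identical(call$shift_bp, d)
    expect_identical(call$unstable, abs(d) >= 3,
                     info = sprintf("shift %d bp", d))
  }
})

test_that("a new minor band alone marks a marker unstable", {
  normal <- peak_row(120, 50)
  # stable major plus a 20% minor at 109: unstable with no shift
  tumor <- peak_table(peak_row(120, 50), peak_row(109, 10))
  call <- call_marker(tumor, normal, "M", win, g_hr)
  expect_identical(call$shift_bp, 0L)
  expect_true(call$unstable)
  expect_identical(call$new_minor_bands[[1]], 109)
  # a minor matching a normal band within tolerance is not new
  normal2 <- peak_table(peak_row(120, 50), peak_row(109.6, 5))
  call <- call_marker(tumor, normal2, "M", win, g_hr)
  expect_false(call$unstable)
  # below the 10% relative amplitude threshold it is not a band
  faint <- peak_table(peak_row(120, 50), peak_row(109, 4))
  call <- call_marker(faint, normal, "M", win, g_hr)
  expect_false(call$unstable)
})

test_that("deletion-only calling can be configured", {
  normal <- peak_row(120, 50)
  p <- caller_params(sign_agnostic = FALSE)
  ins <- call_marker(peak_row(123, 50), normal, "M", win, g_hr, p)
  del <- call_marker(peak_row(117, 50), normal, "M", win, g_hr, p)
  expect_false(ins$unstable)
  expect_true(del$unstable)
})

test_that("missing product excludes a marker instead of calling it", {
  normal <- peak_row(120, 50)
  call <- call_marker(peak_row(300, 50), normal, "M", win, g_hr)
  expect_true(call$excluded)
  expect_false(call$unstable)
})

test_that("an inconclusive tumor pattern defers the marker", {
  normal <- peak_row(120, 50)
  smeared <- peak_row(117, 50, width_bp = 1.8)
  call <- call_marker(smeared, normal, "M", win, g_hr)
  expect_true(call$inconclusive)
  expect_false(call$unstable)  # undefined at this tier, forced false
})

test_that("Bethesda classification maps 0/1/>=2 and ignores marker order", {
  for (k in 0:5) {
    calls <- call_set(c(rep(TRUE, k), rep(FALSE, 5 - k)))
    want <- if (k == 0) "MSS" else if (k == 1) "MSI-L" else "MSI-H"
    expect_identical(classify_sample(calls)$status, want)
    shuffled <- calls[sample(nrow(calls)), ]
    expect_identical(classify_sample(shuffled)$status, want)
  }
  expect_error(classify_sample(call_set(c(TRUE, FALSE, FALSE, FALSE, FALSE),
                                        inconclusive = c(FALSE, TRUE, FALSE,
                                                         FALSE, FALSE))),
               class = "needs_escalation")
})

test_that("marker dropout lowers the conclusive count, not the call", {
  # one marker failed, four conclusive with one unstable: still MSI-L
  calls <- call_set(c(TRUE, FALSE, FALSE, FALSE, FALSE),
                    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  res <- classify_sample(calls)
  expect_identical(res$status, "MSI-L")
  expect_identical(res$n_conclusive, 4L)
  # two dropouts leave too few markers for a status
  calls <- call_set(c(TRUE, FALSE, FALSE, FALSE, FALSE),
                    excluded = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(classify_sample(calls)$status, "Indeterminate")
})

test_that("two-tier workflow escalates smears and preserves tier-1 calls", {
  panel <- marker_panel()
  gels <- list(screening = gel_model("screening"), highres = gel_model("highres"))
  truth <- case_truth("tt1", c("BAT-26", "NR-21"),
                      c("BAT-26" = 15L, "NR-21" = 12L), 0.5)
  sc <- simulate_case(truth, gels$screening, panel, seed = 21)
  provider_calls <- 0L
  provider <- function() {
    provider_calls <<- provider_calls + 1L
    hr <- simulate_case(truth, gels$highres, panel, seed = 21)
    list(tumor = hr$tumor, normal = hr$normal)
  }
  # screening-tier calls, for comparison with the merged result
  st <- size_trace(sc$tumor, gel = gels$screening)
  sn <- size_trace(sc$normal, gel = gels$screening)
  tier1 <- call_markers(st, sn, panel, gels$screening)
  expect_true(any(tier1$inconclusive))

  res <- run_two_tier(list(tumor = sc$tumor, normal = sc$normal), provider,
                      panel, gels, case_id = "tt1")
  expect_identical(res$status, "MSI-H")
  expect_true(res$escalated)
  expect_identical(provider_calls, 1L)
  # escalation monotonicity: conclusive screening calls are never altered
  kept <- tier1$marker[!tier1$inconclusive]
  for (mk in kept) {
    a <- tier1[tier1$marker == mk, c("shift_bp", "unstable", "tier")]
    b <- res$marker_calls[res$marker_calls$marker == mk,
                          c("shift_bp", "unstable", "tier")]
    expect_identical(a, b, info = mk)
  }
  expect_true(all(res$marker_calls$tier[res$marker_calls$marker %in% kept] ==
                    "screening"))

  # a case conclusive at screening is never escalated
  mss <- simulate_case(case_truth("tt2"), gels$screening, panel, seed = 22)
  res2 <- run_two_tier(list(tumor = mss$tumor, normal = mss$normal), provider,
                       panel, gels, case_id = "tt2")
  expect_false(res2$escalated)
  expect_identical(res2$status, "MSS")

  # no high-resolution lanes available: indeterminate, not a forced status
  res3 <- run_two_tier(list(tumor = sc$tumor, normal = sc$normal), NULL,
                       panel, gels, case_id = "tt3")
  expect_identical(res3$status, "Indeterminate")
})
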