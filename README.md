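# msipcr

Microsatellite instability (MSI) calling from non-labeled
capillary-electrophoresis fragment analysis, for molecular-pathology
pipelines that score colorectal (and other) tumors on the five-marker
mononucleotide panel **BAT-25, BAT-26, NR-21, NR-24, NR-27** against a
matched normal specimen.

MSI — somatic length change at short tandem repeats caused by deficient
DNA mismatch repair (dMMR) — is the primary predictive biomarker for
PD-1/PD-L1 immunotherapy response. This package implements the complete
computational side of a non-fluorescent capillary workflow:

* **Sizing.** Each lane co-injects 15 and 1000 bp alignment markers.
  After a single-peak/no-shoulder QC on both anchors, fragment size is
  calibrated log-linearly, `size(m) = exp(a + b·m)`, with `a, b` solved
  exactly from the two anchor positions (so the anchors' midpoint maps
  to `√(15·1000) ≈ 122.47` bp, and any affine lane distortion cancels).
* **Marker calls.** A marker is *unstable* if the tumor's major band is
  shifted **≥ 3 bp** from the normal's major band, or if the tumor shows
  **new minor bands** absent from the normal lane (sizes compared at
  integer bp).
* **Bethesda classification.** Unstable markers `k`: `k = 0` → MSS,
  `k = 1` → MSI-L, `k ≥ 2` → MSI-H.
* **Two-tier workflow.** Calls are made on a screening gel (~10–15 bp
  resolution); markers with inconclusive smearing patterns are re-called
  from a high-resolution gel (~1–3 bp). Conclusive screening calls are
  never altered by escalation.
* **Validation machinery.** A fully seeded electropherogram simulator
  (stutter ladders, lane distortion, tumor-fraction mixing, cohorts with
  MMR-IHC labels), limit-of-detection estimation from dilution series
  (100/50/20/10/7.5/5/2.5% tumor DNA), and MSI-PCR × IHC concordance
  reporting with Fisher's exact association tests.

## Worked example

Simulate a paired case whose truth is MSI-H (15 bp deletion at BAT-26,
13 bp at NR-24, 60% tumor fraction), then run it through the two-tier
caller. At 60% tumor content the screening gel cannot resolve the
germline/deleted mixtures, so those two markers escalate and resolve at
high resolution:

```r
library(msipcr)
panel <- marker_panel()
gels <- list(screening = gel_model("screening"), highres = gel_model("highres"))

truth <- case_truth("case01", unstable_markers = c("BAT-26", "NR-24"),
                    deletion_bp = c("BAT-26" = 15L, "NR-24" = 13L),
                    tumor_fraction = 0.6)
sim <- simulate_case(truth, gels$screening, seed = 42)
provider <- function() {
  hr <- simulate_case(truth, gels$highres, seed = 42)
  list(tumor = hr$tumor, normal = hr$normal)
}
res <- run_two_tier(list(tumor = sim$tumor, normal = sim$normal),
                    provider, panel, gels, case_id = "case01")
res
#> <sample_result case01: MSI-H (2/5 markers unstable; escalated)>
res$marker_calls[, c("marker", "normal_major_bp", "tumor_major_bp",
                     "shift_bp", "unstable", "inconclusive", "tier")]
#>   marker normal_major_bp tumor_major_bp shift_bp unstable inconclusive      tier
#> 1  NR-21              99             99        0    FALSE        FALSE screening
#> 2 BAT-26             134            119      -15     TRUE        FALSE   highres
#> 3 BAT-25             169            169        0    FALSE        FALSE screening
#> 4  NR-24             204            191      -13     TRUE        FALSE   highres
#> 5  NR-27             239            239        0    FALSE        FALSE screening
```

The three stable markers were conclusive at tier 1 and keep their
screening calls; the −15 and −13 bp major-band shifts trip the ≥ 3 bp
rule, two unstable markers make the case MSI-H, and `escalated` records
that the high-resolution gel was needed. (Major-band sizes are reported
at integer bp; the ~1 bp offset from the configured 100/135/170/205/240
germline sizes is the stutter ladder pulling the band apex down, and
cancels in the tumor−normal comparison.)

Concordance with MMR immunohistochemistry uses the dichotomies
MSI-H vs MSS+MSI-L and any-protein loss vs preserved:

```r
tab <- build_contingency(
  status = setNames(c("MSS", "MSS", "MSI-H"), c("a", "b", "c")),
  ihc    = setNames(c("Preserved", "Preserved", "Loss"), c("a", "b", "c")))
percent_concordance(tab)
#> [1] 100
```

`run_pipeline()` drives everything from a YAML config (simulate or
analyze mode) and writes peak tables, per-case call JSONs, a cohort
status TSV, LOD and concordance reports, and a seeded run log;
`inst/scripts/msicall` is a thin command-line front end with
`simulate` / `analyze` / `lod` / `concordance` verbs.

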