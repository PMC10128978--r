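---
title: "MSI calling from non-labeled capillary electrophoresis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSI calling from non-labeled capillary electrophoresis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msipcr)
```

## The assay and its computational model

Microsatellite instability (MSI) in colorectal carcinoma is scored by
comparing the lengths of PCR products at five quasi-monomorphic poly-A
mononucleotide loci (BAT-25, BAT-26, NR-21, NR-24, NR-27) between a
tumor specimen and matched non-tumorous tissue. In the non-labeled
capillary-electrophoresis version of the assay, each lane co-injects two
alignment markers of known size (15 and 1000 bp). A product is read from
the electropherogram as a band (peak); its size comes from calibrating
the lane's migration axis against the two anchors.

The decision rules implemented here are:

* **Marker instability.** A marker is unstable when the tumor's major
  band is shifted by **3 bp or more** relative to the normal's major
  band, or when the tumor shows **new minor bands** absent from the
  normal lane. Both signs of shift count by default (`sign_agnostic`
  in `caller_params()`), since unstable poly-A alleles are compared as
  shifts; deletion-only calling is one switch away.
* **Bethesda classification.** Instability at two or more of the five
  markers is MSI-H; at exactly one locus, MSI-L; otherwise MSS.
* **Two-tier workflow.** Lanes are first run on a screening cartridge
  (resolution on the order of 10-15 bp). Markers whose tumor pattern is
  an inconclusive smear at that resolution are re-run on a
  high-resolution cartridge (1-3 bp); conclusive screening calls are
  never altered by the second tier. A marker still unreadable at high
  resolution leaves the case indeterminate rather than forcing a status.
* **Anchor QC.** Each alignment marker must appear as a single peak
  with no shoulder; lanes failing this are excluded from sizing
  entirely.

## Size calibration

Fragment mobility is modeled log-linearly: `size(m) = exp(a + b * m)`.
With two anchors the model is exactly identified, interpolates 15 and
1000 bp without error, and maps the midpoint of the anchor positions to
`sqrt(15 * 1000) = 122.47` bp. Because any per-lane affine migration
distortion moves both anchors together with the products, calibrated
sizes are invariant to it — this is the computational content of
"alignment of the size markers precedes size determination".

Peak apexes are refined by a least-squares quadratic fit of log-signal
over the half-maximum region, done in size coordinates where the log of
a clean Gaussian band is globally quadratic; the fit is exact for a
clean band and noise-averaging otherwise. Round-trip accuracy on
noise-free simulated lanes is well under 0.1 bp. Sizes are reported to
0.1 bp; all shift and band-matching comparisons round to integer bp
first, mirroring gel readouts.

## Peak detection and the shoulder criterion

Local maxima are retained when their topographic prominence exceeds 5%
of the lane maximum (below that, a band is not readable on either
cartridge) and when separated by at least one gel sigma.

"Shoulder" is not quantified in laboratory practice; this package
operationalizes it as a **band-shape residual**: each retained peak is
modeled either as a plain Gaussian at its measured width or as the
gel's clean stutter-bundle shape scale-matched to it (whichever fits
the peak core better), amplitudes are refit jointly, and a peak is
shouldered when the signal within twice its width deviates from the
*sum of all peak models* by more than 10% of its amplitude (after a
short moving average, and never below the lane's noise floor). A
well-resolved neighbor is therefore explained away, while a hidden
allele riding on a flank is not. Two caveats follow from the geometry:

* a secondary component closer than about one sigma is mathematically
  indistinguishable from a clean band (at 0.5 sigma separation the
  mixture differs from a fitted Gaussian by less than 0.1% of
  amplitude), so no detector can flag it — the criterion starts
  resolving hidden components from roughly 1.5-2 sigma outward;
* an unexplained band lying *between* two markers can flag both
  neighbors. This is conservative: both markers escalate to the
  high-resolution tier, where the pattern resolves.

## Smear (inconclusive pattern) detection

A marker is inconclusive at a tier when its banding cannot be read on
that gel. Three triggers, all on the tumor lane:

1. **Width.** The major band's Gaussian-equivalent sigma exceeds
   `smear_widen` (default 1.5) times the gel's nominal sigma. The
   factor is an analytic choice: a clean single-allele band broadened
   by the default stutter ladder measures about 1.37 sigma, while two
   merged alleles separated by the assay's deletion spectrum (11 bp and
   up, at least 2 sigma on the screening gel) measure at least
   1.55 sigma. A factor of 2 would never fire — the widest possible
   unresolved equal mixture measures 1.72 sigma at exactly 2 sigma
   separation.
2. **Shoulder.** The major band carries a band-shape residual (above):
   a component is present that this gel cannot resolve.
3. **No dominant band among overlapping bands.** A competing band
   within 3 gel sigma of the major reaching half its amplitude. The
   dominance test is deliberately restricted to *overlapping* bands:
   two strong, well-separated bands are the classic readable two-allele
   MSI pattern, not a smear.

Inconclusive markers carry no instability verdict at that tier
(`unstable` is forced false) and are the unit of escalation.

## The simulator

`simulate_lane()` renders a lane on a fixed migration grid as a sum of
Gaussian bands (in size units), plus the two sharp alignment-marker
bands, plus seeded white noise; `simulate_case()`,
`simulate_dilution_series()` and `simulate_cohort()` compose lanes into
the study's experimental designs. What it emulates, and the defaults:

* **Migration physics.** Size-to-migration is the exact inverse of the
  log-linear calibration (anchors at canonical positions 0 and 100),
  composed with a per-lane affine distortion (stretch 0.97-1.03,
  offset ±1 by default in cohort simulation). Chosen because two-anchor
  calibration then has an exact inverse; no electro-osmotic drift
  beyond affine is modeled.
* **Marker sizes.** The assay's rules are entirely relative to the
  paired normal, so germline amplicon sizes are configuration:
  NR-21 100, BAT-26 135, BAT-25 170, NR-24 205, NR-27 240 bp, in
  disjoint windows with at least 22 bp of deletion headroom.
* **Gel resolution.** Screening sigma 4.5 bp, high-resolution sigma
  1.0 bp. Two equal bands become bimodal beyond 2 sigma, but against
  the 5% prominence threshold the dip is only *detectable* from about
  2.7 sigma — operationally ~12 bp and ~2-3 bp, matching the two
  cartridges' nominal 10-15 bp and 1-3 bp resolutions.
* **Unstable alleles.** A deleted allele at `germline - deletion`,
  mixed with the germline allele at the tumor fraction. Deletions
  default to discrete-uniform 11-16 bp, honoring the observation that
  unstable mononucleotide markers shift predominantly by more than ten
  base pairs; boundary behavior down to 3 bp is testable by
  configuration.
* **Stutter.** Contraction-side only: -1 bp steps, geometric decay 0.5,
  3 steps (poly-A PCR stutter is predominantly contraction). On the
  high-resolution gel the ladder merges into a characteristically
  asymmetric bundle ~1.3-1.4 sigma wide; the band-shape model above
  knows this shape.
* **Amplitudes.** Band height is proportional to template amount
  (80 units per unit amount; anchors at 100), so the expected area of a
  marker's peak family is invariant in the tumor fraction. Baseline
  noise sd is 1 — about 1% of a full-strength band.
* **Cohorts.** MSI-H prevalence defaults to 40/336 (the studied
  cohort's rate), MSI-L to 3%; MSI-H cases draw 2-5 unstable markers.
  Tumor fraction is uniform on 0.3-0.9, a realistic cellularity range
  for macrodissected surgical colorectal specimens. IHC labels are
  MLH1/PMS2 loss for MSI-H truth and all-preserved otherwise, with an
  error model that can switch a configured number of non-MSI-H cases to
  isolated MSH6 loss (the discordance mode in which mismatch-repair
  loss produces no marker shift) and MSI-H cases to all-preserved.
* **Determinism.** Every lane (and every case truth) draws from its own
  stream keyed by `(seed, id)` via a stable 31-bit hash, so adding
  lanes or extending a cohort never perturbs existing ones, and
  identical seeds give bit-identical traces.

### What the simulator does not capture

No PCR chemistry, fluorescence, or instrument drift beyond the affine
term; no FFPE artifacts (fragmentation, deamination); no allele
dropout model beyond "no product in window"; quasi-monomorphic
germline variation is ignored (every subject shares the configured
germline sizes). Passing recovery tests on these simulations therefore
demonstrates that the *decision logic* is correct under the stated
signal model — not that the thresholds are optimal for any particular
instrument's noise.

One consequence worth stating plainly: in this signal model a
sub-clonal unstable allele on the screening gel appears as a flank
component of the germline band, which the smear rules classify as
inconclusive rather than as a readable new band. Simulated screening
lanes therefore resolve cleanly only for near-pure tumors (or MSS
cases), and simulated screening-tier LODs sit at the top of the
dilution series, while the physical assay read faint separate bands at
the screening tier down to 5-10% tumor DNA. The high-resolution LOD in
the simulation is governed by the 10% minor-band amplitude threshold
(unstable iff `f/(1-f) >= 0.1`, i.e. ~10%). The LOD machinery itself
(`estimate_lod()`: the smallest fraction with an unbroken unstable
prefix anchored at pure tumor; modal flags over replicates;
non-monotone series flagged) is independent of these amplitudes, and
the ordering "high-resolution LOD at least as sensitive as screening"
holds marker-by-marker across seeds.

## Calling thresholds

| Parameter | Default | Meaning |
|---|---|---|
| `shift_bp` | 3 | minimum absolute major-band shift (bp, integer-rounded) |
| `minor_rel` | 0.10 | minor band's minimum amplitude relative to tumor major |
| `match_tol_bp` | 3 (screening), 1 (highres) | rounding tolerance for matching a tumor band to a normal band |
| `smear_widen` | 1.5 | width multiple of gel sigma flagged as smear |
| `smear_overlap_sigma` | 3 | bands within this many sigma "overlap" |
| `smear_dominance` | 0.5 | overlapping band amplitude ratio voiding dominance |
| `min_conclusive` | 4 | minimum conclusive markers for a Bethesda status |

The shift threshold is the assay's published rule; the minor-band
amplitude and matching tolerances are this package's defaults (no
numeric criterion is published), and marker dropout below four
conclusive markers yields an indeterminate case rather than a guess.

## Statistics

The 2x2 MSI-PCR (MSI-H vs MSS+MSI-L) by IHC (any-protein loss vs
preserved) table is summarized as percent concordance at one decimal.
Association tests are two-sided Fisher's exact tests
(`stats::fisher.test`; degenerate margins return p = 1 by convention)
with significance labeled at p < 0.001. For covariates with more than
two levels the exact test generalizes in the usual conditional way,
falling back to a seeded Monte-Carlo estimate when enumeration is
infeasible. Percentages are reported under both denominator
conventions — the full column n and the known-status n — because
published cohort tables commonly mix the two; `cohort_table()` exposes
both rather than guessing. All percentages round half-away-from-zero
at one decimal; note that a ratio like 303/336 (90.18%) prints as 90.2
under this convention.

## Problem sizes used in validation

The test suite and the acceptance script validate at: 200-336 simulated
cases per cohort (status recovery at least 95% required, 100% required
in the noise-free pure-tumor condition), 7-point dilution series
(100/50/20/10/7.5/5/2.5% tumor DNA) per gel over multiple seeds, and
exhaustive Fisher-oracle comparison over all 2x2 tables with n up to 40
(via their symmetry-canonical representatives). These sizes were chosen
as the smallest that exercise every decision path of the workflow while
keeping the full validation run in the minutes range.

## Known limitations

* Unpaired (tumor-only) calling is out of scope: the rule set is
  defined against the matched normal.
* The smear and shoulder criteria are this package's operationalization
  of a visual laboratory judgment; their thresholds are analytic, not
  fitted to instrument data.
* Simulated screening-tier sensitivity understates the physical assay
  (see above); absolute LOD percentages from simulation should not be
  quoted as assay performance.
* IHC enters only as categorical preserved/loss labels; image analysis
  and pathologist concordance are out of computational scope.
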