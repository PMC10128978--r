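# Shared fixtures and independent oracles for the test suite.

# Mode count of an analytic Gaussian-mixture profile (peak-separation
# oracle, independent of the package's detection path).
mix_modes <- function(sizes, amps, sigma) {
  x <- seq(min(sizes) - 4 * sigma, max(sizes) + 4 * sigma, by = 0.001)
  y <- rep(0, length(x))
  for (i in seq_along(sizes)) {
    y <- y + amps[i] * exp(-(x - sizes[i])^2 / (2 * sigma^2))
  }
  sum(diff(sign(diff(y))) == -2)
}

# Brute-force two-sided Fisher p: exhaustive enumeration of all tables with
# the observed margins, hypergeometric pmf from log-binomial coefficients.
fisher_oracle <- function(tab) {
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  p <- exp(lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1))
  pobs <- p[xs == a]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# One row of a sized-peak table, for direct caller-level tests.
peak_row <- function(size_bp, amplitude, width_bp = 1, has_shoulder = FALSE) {
  data.frame(migration_pos = msipcr:::canon_migration(size_bp),
             amplitude = amplitude, prominence = amplitude,
             fwhm_m = 0.5, has_shoulder = has_shoulder,
             size_bp = size_bp, width_bp = width_bp, out_of_range = FALSE)
}

peak_table <- function(...) do.call(rbind, list(...))

# Minimal conclusive marker-call set for classification tests.
call_set <- function(unstable, inconclusive = rep(FALSE, length(unstable)),
                     excluded = rep(FALSE, length(unstable))) {
  data.frame(marker = paste0("M", seq_along(unstable)),
             unstable = unstable, inconclusive = inconclusive,
             excluded = excluded, stringsAsFactors = FALSE)
}

# Case-level data reproducing the published cohort's covariate counts
# (40 MSI-H / 296 MSS+MSI-L; proximal-colon 27|86, distal 13|210; BRAF
# wild-type 28|134, mutant 12|10, unknown 0|152; male 19|171).
table1_cases <- function() {
  status <- c(rep("MSI-H", 40), rep("MSS", 296))
  location <- c(rep("proximal", 27), rep("distal", 13),
                rep("proximal", 86), rep("distal", 210))
  braf <- c(rep("wild", 28), rep("mutant", 12),
            rep("wild", 134), rep("mutant", 10), rep(NA_character_, 152))
  gender <- c(rep("male", 19), rep("female", 21),
              rep("male", 171), rep("female", 125))
  data.frame(case_id = sprintf("c%03d", seq_along(status)), status = status,
             location = location, braf = braf, gender = gender,
             stringsAsFactors = FALSE)
}

# MSI-PCR statuses and IHC dichotomies reproducing the published 2x2
# agreement counts: 292 MSS+MSI-L/Preserved, 4 MSS+MSI-L/Loss,
# 1 MSI-H/Preserved, 39 MSI-H/Loss.
table2_cases <- function() {
  status <- c(rep("MSS", 289), rep("MSI-L", 3),   # concordant not-MSI-H
              rep("MSS", 3), "MSI-L",             # MSH6-loss discordant
              "MSI-H",                            # preserved discordant
              rep("MSI-H", 39))
  ihc <- c(rep("Preserved", 292), rep("Loss", 4), "Preserved", rep("Loss", 39))
  names(status) <- names(ihc) <- sprintf("c%03d", seq_along(status))
  list(status = status, ihc = ihc)
}

germline_alleles <- msipcr:::germline_alleles
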