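# MSI-PCR vs MMR-IHC concordance and cohort association statistics.

IHC_PROTEINS <- c("mlh1", "msh2", "msh6", "pms2")

#' Round a proportion to a percentage
#'
#' One convention throughout the package: `round(100 * x, digits)` with
#' round-half-away-from-zero at the reporting precision (1 decimal by
#' default).
#'
#' @param x Proportion(s) in `[0, 1]`.
#' @param digits Decimal places.
#' @return Percentage(s).
#' @export
as_percent <- function(x, digits = 1) {
  z <- 100 * x * 10^digits
  sign(z) * floor(abs(z) + 0.5) / 10^digits
}

#' Dichotomize a per-protein MMR IHC result
#'
#' The IHC readout enters the analysis as categorical labels only:
#' `"loss"` (absent nuclear staining in tumor cells) or `"preserved"` per
#' protein. The sample-level dichotomy is `Loss` if any of MLH1, MSH2,
#' MSH6 or PMS2 is lost, else `Preserved`. Monotone: adding a loss never
#' flips `Loss` back to `Preserved`.
#'
#' @param ihc A `data.frame` with columns `mlh1`, `msh2`, `msh6`, `pms2`
#'   (values `"preserved"`/`"loss"`); one row per case.
#' @return Character vector `"Preserved"`/`"Loss"`, one per row.
#' @export
dichotomize_ihc <- function(ihc) {
  stopifnot(is.data.frame(ihc))
  missing_cols <- setdiff(IHC_PROTEINS, names(ihc))
  if (length(missing_cols)) {
    stop("missing IHC protein column(s): ", paste(missing_cols, collapse = ", "))
  }
  vals <- as.matrix(ihc[, IHC_PROTEINS, drop = FALSE])
  if (any(is.na(vals)) || !all(vals %in% c("preserved", "loss"))) {
    stop("IHC values must be 'preserved' or 'loss' for all four proteins")
  }
  ifelse(apply(vals == "loss", 1L, any), "Loss", "Preserved")
}

#' Build the MSI-PCR x IHC 2x2 contingency table
#'
#' Rows are the MSI-PCR dichotomy (`MSS+MSI-L` vs `MSI-H`), columns the
#' IHC dichotomy (`Preserved` vs `Loss`). Inputs are matched by case id;
#' a case present in only one input is an error (listing the unmatched
#' ids).
#'
#' @param status Character vector of MSI-PCR statuses
#'   (`MSS`/`MSI-L`/`MSI-H`), named by case id (or unnamed, positionally
#'   matched to `ihc`).
#' @param ihc Character vector `"Preserved"`/`"Loss"`, named like `status`.
#' @return A 2x2 integer matrix of class `contingency_table`.
#' @export
build_contingency <- function(status, ihc) {
  if (!is.null(names(status)) || !is.null(names(ihc))) {
    if (is.null(names(status)) || is.null(names(ihc))) {
      stop("either both or neither of status and ihc must be named by case id")
    }
    only_s <- setdiff(names(status), names(ihc))
    only_i <- setdiff(names(ihc), names(status))
    if (length(only_s) || length(only_i)) {
      stop("case sets differ; unmatched ids: ",
           paste(c(only_s, only_i), collapse = ", "))
    }
    ihc <- ihc[names(status)]
  } else if (length(status) != length(ihc)) {
    stop("status and ihc must have equal length")
  }
  ok_status <- status %in% STATUS_LEVELS
  if (!all(ok_status)) stop("invalid MSI status value(s)")
  if (!all(ihc %in% c("Preserved", "Loss"))) stop("invalid IHC dichotomy value(s)")
  row <- factor(ifelse(status == "MSI-H", "MSI-H", "MSS+MSI-L"),
                levels = c("MSS+MSI-L", "MSI-H"))
  col <- factor(ihc, levels = c("Preserved", "Loss"))
  tab <- table(row, col)
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(MSI_PCR = c("MSS+MSI-L", "MSI-H"),
                              MMR_IHC = c("Preserved", "Loss")))
  structure(m, class = c("contingency_table", "matrix", "array"))
}

#' Percent concordance of a 2x2 MSI-PCR x IHC table
#'
#' Concordant cases are `MSS+MSI-L & Preserved` plus `MSI-H & Loss`;
#' the percentage is reported to 1 decimal.
#'
#' @param tab 2x2 table (rows `MSS+MSI-L`/`MSI-H`, columns
#'   `Preserved`/`Loss`).
#' @return Percent concordance (numeric scalar).
#' @export
percent_concordance <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  n <- sum(tab)
  if (n == 0) stop("empty table: n = 0")
  as_percent((tab[1, 1] + tab[2, 2]) / n)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities no larger
#' than that of the observed table (the classic conditional test, via
#' [stats::fisher.test()]). A table with any zero margin carries no
#' information about association: p = 1 by convention, flagged degenerate.
#' Significance is labeled at the two-sided threshold p < 0.001.
#'
#' @param tab 2x2 matrix (or vector of 4 counts, filled by row).
#' @return A list: `p_value`, `degenerate`, `significant`.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, nrow = 2, byrow = TRUE)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0),
            all(abs(tab - round(tab)) < 1e-9))
  tab <- round(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_value = 1, degenerate = TRUE, significant = FALSE))
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  p <- min(p, 1)
  list(p_value = p, degenerate = FALSE, significant = p < 0.001)
}

#' Full concordance report
#'
#' @param status Named character vector of MSI-PCR statuses by case id.
#' @param ihc Either a per-protein IHC `data.frame` with a `case_id` column
#'   (dichotomized internally) or a named `"Preserved"`/`"Loss"` vector.
#' @return An object of class `concordance_report`: `table`, `n`,
#'   `concordant`, `percent`, `fisher` and `discordant_cases`
#'   (a `data.frame` with per-case detail).
#' @export
concordance_report <- function(status, ihc) {
  if (is.data.frame(ihc)) {
    stopifnot("case_id" %in% names(ihc))
    dich <- stats::setNames(dichotomize_ihc(ihc), ihc$case_id)
  } else {
    dich <- ihc
  }
  tab <- build_contingency(status, dich)
  if (!is.null(names(status))) dich <- dich[names(status)]
  agree <- (status == "MSI-H") == (dich == "Loss")
  disc <- data.frame(case_id = if (!is.null(names(status))) names(status)[!agree]
                     else which(!agree),
                     msi_pcr = unname(status[!agree]),
                     ihc = unname(dich[!agree]),
                     stringsAsFactors = FALSE)
  structure(list(table = tab, n = sum(tab),
                 concordant = sum(tab[1, 1] + tab[2, 2]),
                 percent = percent_concordance(tab),
                 fisher = fisher_exact(unclass(tab)),
                 discordant_cases = disc),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report: %.1f%% (%d/%d)>\n",
              x$percent, x$concordant, x$n))
  print(unclass(x$table))
  invisible(x)
}

#' Clinicopathologic association table
#'
#' For each categorical covariate, tabulates MSI-H vs MSS+MSI-L counts per
#' level with percentages under both denominator conventions (`pct_column`:
#' the full column n including unknowns; `pct_known`: cases with known
#' status for that covariate) and a Fisher's exact p-value on the non-NA
#' 2xk subtable (exact where enumerable, otherwise a seeded Monte-Carlo
#' estimate). `NA` covariate values are reported as their own row and
#' never enter the test.
#'
#' @param data A `data.frame` with a status column plus covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param status_col Name of the MSI status column (`MSS`/`MSI-L`/`MSI-H`).
#' @param seed Seed for Monte-Carlo p-values on large tables.
#' @return A `data.frame`: `covariate`, `level`, `n_msih`, `pct_msih_column`,
#'   `pct_msih_known`, `n_other`, `pct_other_column`, `pct_other_known`,
#'   `p_value` (repeated within covariate; `NA` for single-level
#'   covariates).
#' @export
cohort_table <- function(data, covariates, status_col = "status", seed = 1) {
  stopifnot(is.data.frame(data), status_col %in% names(data),
            all(covariates %in% names(data)))
  status <- data[[status_col]]
  if (!all(status %in% STATUS_LEVELS)) stop("invalid MSI status value(s)")
  is_h <- status == "MSI-H"
  n_h <- sum(is_h); n_o <- sum(!is_h)

  out <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    if (is.numeric(x) && !is.factor(x)) {
      stop("covariate '", cv, "' is not categorical")
    }
    x <- as.character(x)
    levs <- unique(x[!is.na(x)])
    known_h <- sum(is_h & !is.na(x)); known_o <- sum(!is_h & !is.na(x))
    p <- NA_real_
    if (length(levs) >= 2L) {
      sub <- table(factor(x[!is.na(x)], levels = levs), is_h[!is.na(x)])
      p <- tryCatch(
        stats::fisher.test(sub, workspace = 2e7)$p.value,
        error = function(e) with_seed(derive_seed(seed, paste0("fisher/", cv)), {
          stats::fisher.test(sub, simulate.p.value = TRUE, B = 1e5)$p.value
        }))
    }
    rows <- lapply(c(levs, if (anyNA(x)) NA_character_), function(lv) {
      sel <- if (is.na(lv)) is.na(x) else !is.na(x) & x == lv
      nh <- sum(sel & is_h); no <- sum(sel & !is_h)
      data.frame(covariate = cv, level = if (is.na(lv)) "NA" else lv,
                 n_msih = nh,
                 pct_msih_column = if (n_h) as_percent(nh / n_h) else NA_real_,
                 pct_msih_known = if (!is.na(lv) && known_h) as_percent(nh / known_h) else NA_real_,
                 n_other = no,
                 pct_other_column = if (n_o) as_percent(no / n_o) else NA_real_,
                 pct_other_known = if (!is.na(lv) && known_o) as_percent(no / known_o) else NA_real_,
                 p_value = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
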