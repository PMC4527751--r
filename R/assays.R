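#' Fit a glycine standard curve
#'
#' Ordinary least-squares line `A420 = slope * concentration + intercept`
#' through at least three standards with distinct concentrations. Standards
#' and samples are assumed to be processed under the same dilution scheme,
#' so dilution factors cancel in the curve.
#'
#' @param conc_uM standard concentrations, uM.
#' @param A420 measured absorbances at 420 nm.
#' @return An object of class `standard_curve` with `slope` (OD/uM),
#'   `intercept` (OD) and `r_squared`.
#' @export
fit_standard_curve <- function(conc_uM, A420) {
  .check_finite(conc_uM, "conc_uM")
  .check_finite(A420, "A420")
  if (length(conc_uM) != length(A420)) {
    stop("'conc_uM' and 'A420' must have equal length", call. = FALSE)
  }
  if (length(unique(conc_uM)) < 3L) {
    stop("need at least 3 distinct standard concentrations", call. = FALSE)
  }
  fit <- stats::lm(A420 ~ conc_uM)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("standard curve has non-positive slope", call. = FALSE)
  }
  tss <- sum((A420 - mean(A420))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "standard_curve")
}

#' Percent modification of primary amines (TNBSA assay)
#'
#' Converts a sample absorbance to a free-amine molarity via the standard
#' curve, divides by the protein molarity to get free amines per molecule,
#' and expresses the loss against the total reactive amines of the protein:
#' `pct_modified = 100 * (1 - n_free / n_total)`. The default denominator,
#' 83, counts the 59 lysine and 24 arginine residues of human serum albumin
#' (the alpha-amino terminus is excluded). Results outside `[0, 100]` are
#' clipped with `flagged = TRUE`.
#'
#' @param A420 sample absorbance at 420 nm.
#' @param curve a [fit_standard_curve()] result.
#' @param protein_ug_per_ml protein concentration of the reacted sample,
#'   ug/ml.
#' @param n_total total reactive primary amines per protein molecule.
#' @param molar_mass protein molar mass, g/mol (HSA default 66472).
#' @return A list of class `amine_result` with `n_free`, `pct_modified` and
#'   `flagged`.
#' @export
pct_modification <- function(A420, curve, protein_ug_per_ml = 100,
                             n_total = 83, molar_mass = 66472) {
  stopifnot(inherits(curve, "standard_curve"))
  .check_scalar(A420, "A420")
  .check_scalar(protein_ug_per_ml, "protein_ug_per_ml", lower = 0,
                strict_lower = TRUE)
  .check_scalar(n_total, "n_total", lower = 0, strict_lower = TRUE)
  amine_uM <- (A420 - curve$intercept) / curve$slope
  protein_uM <- protein_ug_per_ml / molar_mass * 1000
  n_free <- amine_uM / protein_uM
  amine_pct(n_free, n_total)
}

#' @rdname pct_modification
#' @param n_free free primary amines per protein molecule (bypasses the
#'   absorbance conversion).
#' @export
amine_pct <- function(n_free, n_total = 83) {
  .check_scalar(n_free, "n_free")
  pct <- 100 * (1 - n_free / n_total)
  flagged <- FALSE
  if (pct < 0 || pct > 100) {
    flagged <- TRUE
    pct <- min(max(pct, 0), 100)
  }
  structure(list(n_free = n_free, pct_modified = pct, flagged = flagged),
            class = "amine_result")
}

#' @export
print.amine_result <- function(x, ...) {
  cat(sprintf("<amine_result> %.2f free amines -> %.1f%% modified%s\n",
              x$n_free, x$pct_modified, if (x$flagged) " [clipped]" else ""))
  invisible(x)
}

#' Relative qPCR expression with multiple reference genes
#'
#' Per-gene relative quantities are `RQ = E ^ (Cq_calibrator - Cq)` with the
#' gene-specific amplification efficiency `E` (2 for perfect doubling). Each
#' sample's normalization factor is the geometric mean of its
#' reference-gene relative quantities, and the normalized relative quantity
#' is `NRQ = RQ / NF`. With the default calibrator (the per-gene mean Cq
#' across samples), changing the calibrator only rescales a gene's NRQs by
#' one global factor. NRQs are invariant to per-sample global Cq shifts,
#' which the normalization factor absorbs.
#'
#' @param table data frame with columns `gene`, `sample`, `Cq`,
#'   `is_reference`, optionally `condition` and `efficiency` (default 2).
#' @param calibrator sample name used as calibrator, or `NULL` for the
#'   per-gene mean Cq.
#' @return The input table with columns `RQ`, `NF` and `NRQ` appended.
#' @export
qpcr_relative_expression <- function(table, calibrator = NULL) {
  need <- c("gene", "sample", "Cq", "is_reference")
  if (!all(need %in% names(table))) {
    stop("Cq table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(table$efficiency)) table$efficiency <- 2
  if (any(!is.finite(table$Cq)) || any(table$Cq <= 0) || any(table$Cq >= 50)) {
    stop("Cq values must lie in (0, 50)", call. = FALSE)
  }
  if (any(table$efficiency <= 1 | table$efficiency > 2)) {
    stop("amplification efficiencies must lie in (1, 2]", call. = FALSE)
  }
  refs <- unique(table$gene[table$is_reference])
  if (length(refs) == 0L) stop("no reference gene flagged", call. = FALSE)
  if (length(refs) == 1L) {
    warning("only one reference gene; at least two are recommended",
            call. = FALSE)
  }
  samples <- unique(table$sample)
  ref_tab <- table[table$is_reference, ]
  have <- table(factor(ref_tab$gene, refs), factor(ref_tab$sample, samples))
  if (any(have == 0L)) {
    stop("missing Cq for a reference gene in at least one sample",
         call. = FALSE)
  }

  cq_cal <- if (is.null(calibrator)) {
    tapply(table$Cq, table$gene, mean)
  } else {
    if (!calibrator %in% samples) stop("calibrator sample not in table",
                                       call. = FALSE)
    cal_rows <- table[table$sample == calibrator, ]
    stats::setNames(cal_rows$Cq, cal_rows$gene)[unique(table$gene)]
  }
  table$RQ <- as.numeric(table$efficiency ^
    (unname(cq_cal[as.character(table$gene)]) - table$Cq))
  nf <- tapply(seq_len(nrow(table)), table$sample, function(i) {
    r <- table[i, ]
    exp(mean(log(r$RQ[r$is_reference])))
  })
  table$NF <- as.numeric(nf[as.character(table$sample)])
  table$NRQ <- table$RQ / table$NF
  table
}

#' Loading-control-normalized immunoblot quantification
#'
#' Divides each lane's target band intensity by its loading-control
#' intensity, then expresses the ratios as percent of the series maximum.
#'
#' @param target band intensities of the protein of interest, one per lane.
#' @param loading loading-control band intensities (> 0), one per lane.
#' @param lane optional lane labels.
#' @return A data frame with `lane`, `ratio` and `pct_of_max`.
#' @export
blot_normalize <- function(target, loading, lane = seq_along(target)) {
  .check_finite(target, "target")
  .check_finite(loading, "loading")
  if (length(target) != length(loading)) {
    stop("'target' and 'loading' must have equal length", call. = FALSE)
  }
  if (any(loading <= 0)) stop("loading intensities must be > 0", call. = FALSE)
  ratio <- target / loading
  if (all(ratio == 0)) stop("all band ratios are zero", call. = FALSE)
  data.frame(lane = lane, ratio = ratio,
             pct_of_max = 100 * ratio / max(ratio))
}
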