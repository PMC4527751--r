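#' Generate a synthetic Cq table with known fold changes
#'
#' Builds a two-condition qPCR experiment: target genes change by the given
#' fold between `control` and `treated`, the reference genes (three stable
#' housekeeping genes by default) stay constant up to noise. A fold change
#' `f` for a gene with efficiency `E` is encoded as a Cq decrease of
#' `log(f) / log(E)` cycles in the treated samples, so with `E = 2` a
#' two-fold change is exactly one cycle.
#'
#' @param fold_changes named numeric vector of fold changes for the target
#'   genes (treated vs control).
#' @param n_samples samples per condition.
#' @param efficiencies named amplification efficiencies in `(1, 2]`;
#'   unnamed genes default to 2.
#' @param noise_sd Gaussian Cq noise, cycles.
#' @param reference_genes names of the stable reference genes (at least one
#'   must be given).
#' @param base_cq named baseline Cq per gene, or `NULL` for an automatic
#'   spread starting at 18 cycles.
#' @param seed integer RNG seed or `NULL`.
#' @return A data frame with columns `gene`, `sample`, `condition`, `Cq`,
#'   `efficiency`, `is_reference`, carrying the fold changes as a `truth`
#'   attribute.
#' @export
generate_qpcr_table <- function(fold_changes, n_samples = 12L,
                                efficiencies = NULL, noise_sd = 0,
                                reference_genes = c("Tubb5", "Rpl19", "Pum1"),
                                base_cq = NULL, seed = NULL) {
  .check_finite(fold_changes, "fold_changes")
  if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes)))) {
    stop("'fold_changes' must be named by gene", call. = FALSE)
  }
  if (any(fold_changes <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (length(reference_genes) == 0L) {
    stop("missing reference gene flag: supply at least one reference gene",
         call. = FALSE)
  }
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("'n_samples' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  genes <- c(names(fold_changes), reference_genes)
  eff <- stats::setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiencies)) {
    if (any(efficiencies <= 1 | efficiencies > 2)) {
      stop("efficiencies must lie in (1, 2]", call. = FALSE)
    }
    eff[names(efficiencies)] <- efficiencies
  }
  if (is.null(base_cq)) {
    base_cq <- stats::setNames(18 + seq_along(genes), genes)
  }

  conditions <- rep(c("control", "treated"), each = n_samples)
  sample_ids <- sprintf("%s_%02d", conditions, rep(seq_len(n_samples), 2))
  tab <- expand.grid(gene = genes, idx = seq_along(sample_ids),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$sample <- sample_ids[tab$idx]
  tab$condition <- conditions[tab$idx]
  tab$idx <- NULL
  fold <- stats::setNames(c(fold_changes, rep(1, length(reference_genes))),
                          genes)
  shift <- ifelse(tab$condition == "treated",
                  log(fold[tab$gene]) / log(eff[tab$gene]), 0)
  tab$Cq <- unname(base_cq[tab$gene] - shift)
  if (noise_sd > 0) tab$Cq <- tab$Cq + rnorm(nrow(tab), 0, noise_sd)
  tab$efficiency <- unname(eff[tab$gene])
  tab$is_reference <- tab$gene %in% reference_genes
  attr(tab, "truth") <- list(fold_changes = fold_changes)
  tab
}
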