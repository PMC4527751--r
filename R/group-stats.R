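#' Dunn's rank-based multiple-comparison test
#'
#' Pairwise z statistics on mean ranks with tie correction, the standard
#' post hoc companion of the Kruskal-Wallis test:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`.
#'
#' @param values numeric response vector.
#' @param group grouping factor (or coercible).
#' @param p_adjust p-value adjustment method (see [stats::p.adjust()]).
#' @return Data frame with one row per pair: `comparison`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(values, group, p_adjust = "bonferroni") {
  group <- factor(group)
  .check_finite(values, "values")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, group, mean)
  n <- tapply(r, group, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  pval <- 2 * stats::pnorm(-abs(z))
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " - "),
             z = as.numeric(z), p_value = pval,
             p_adjusted = stats::p.adjust(pval, p_adjust))
}

#' Normality-gated multi-group comparison
#'
#' Orchestrates the standard decision tree: every group is tested for
#' normality with the Shapiro-Wilk test; if all pass (p > `alpha`), a
#' one-way ANOVA is run with the configured parametric post hoc (Dunnett
#' versus a control group via \pkg{multcomp}, or Bonferroni-adjusted
#' pairwise t tests); otherwise a Kruskal-Wallis rank ANOVA is run with
#' Dunn's post hoc. Groups on which the normality test is degenerate
#' (e.g. constant values) force the non-parametric branch and are flagged.
#' All underlying tests are delegated to standard routines; this function
#' only records which branch ran and assembles the report.
#'
#' @param values numeric response vector.
#' @param group grouping factor (or coercible), at least two groups of at
#'   least three values each.
#' @param alpha significance level for both the gate and the report.
#' @param posthoc `"auto"` (Dunnett/Dunn depending on branch and control),
#'   `"dunnett"`, `"bonferroni"` or `"dunn"`.
#' @param control control-group label for Dunnett contrasts; defaults to the
#'   first factor level.
#' @return A list of class `group_comparison`: `branch` (`"parametric"` or
#'   `"nonparametric"`), `normality` (per-group p-values), `degenerate`
#'   (flag), `omnibus` (`method`, `statistic`, `p_value`), `posthoc` (data
#'   frame), `summary` (mean +/- SEM per group, via [summarize_groups()]).
#' @examples
#' set.seed(1)
#' compare_groups(c(rnorm(10), rnorm(10, 5)), rep(c("ctl", "trt"), each = 10))
#' @export
compare_groups <- function(values, group, alpha = 0.05,
                           posthoc = c("auto", "dunnett", "bonferroni", "dunn"),
                           control = NULL) {
  posthoc <- match.arg(posthoc)
  group <- factor(group)
  .check_finite(values, "values")
  if (length(values) != length(group)) {
    stop("'values' and 'group' must have equal length", call. = FALSE)
  }
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 3L)) stop("every group needs n >= 3", call. = FALSE)
  if (!is.null(control)) group <- stats::relevel(group, control)

  sw <- vapply(levels(group), function(g) {
    x <- values[group == g]
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  degenerate <- any(is.na(sw))
  parametric <- !degenerate && all(sw > alpha)

  if (parametric) {
    fit <- stats::aov(values ~ group)
    an <- summary(fit)[[1]]
    omnibus <- list(method = "one-way ANOVA", statistic = an$`F value`[1],
                    p_value = an$`Pr(>F)`[1])
    ph <- if (posthoc %in% c("auto", "dunnett")) {
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
      s <- summary(gl)
      data.frame(comparison = names(s$test$coefficients),
                 estimate = as.numeric(s$test$coefficients),
                 p_adjusted = as.numeric(s$test$pvalues),
                 row.names = NULL)
    } else {
      pt <- stats::pairwise.t.test(values, group, p.adjust.method = "bonferroni")
      m <- pt$p.value
      idx <- which(!is.na(m), arr.ind = TRUE)
      data.frame(comparison = paste(rownames(m)[idx[, 1]],
                                    colnames(m)[idx[, 2]], sep = " - "),
                 estimate = NA_real_, p_adjusted = m[idx], row.names = NULL)
    }
    branch <- "parametric"
  } else {
    kt <- stats::kruskal.test(values, group)
    omnibus <- list(method = "Kruskal-Wallis rank ANOVA",
                    statistic = unname(kt$statistic), p_value = kt$p.value)
    ph <- dunn_test(values, group)
    branch <- "nonparametric"
  }

  structure(list(branch = branch, normality = sw, degenerate = degenerate,
                 omnibus = omnibus, posthoc = ph, alpha = alpha,
                 summary = summarize_groups(values, group)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s branch; %s: stat = %.4g, p = %.4g\n",
              x$branch, x$omnibus$method, x$omnibus$statistic,
              x$omnibus$p_value))
  if (x$degenerate) cat("  note: degenerate normality test in >=1 group\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
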