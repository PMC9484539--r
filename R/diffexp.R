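# Negative-binomial differential expression (Wald test on a two-group NB
# GLM with per-feature method-of-moments dispersion) plus dysregulation
# calling at strict printed thresholds.
#
# The Wald statistic is referred to a t distribution with n - 2 df rather
# than a normal: with the dispersion estimated from the same few samples,
# the normal reference is visibly anticonservative at cohort sizes of
# eight pairs, while the residual-df t reference holds nominal level.

#' Negative-binomial Wald test for two-group differential expression
#'
#' For each feature a NB GLM with log link, a group indicator and
#' log(size factor) offset is fit by IRLS at a fixed per-feature
#' dispersion, estimated by method of moments on normalized counts
#' (pooled within-group variance; floored at `1e-8`). The reported p-value
#' is a Wald test of the group coefficient against a t reference with
#' `n - 2` degrees of freedom (the small-sample-calibrated choice when the
#' dispersion is itself estimated); `log2fc` is tumor over normal on the
#' normalized scale. All-zero features are flagged degenerate with
#' `log2fc = 0`, `p = 1`.
#'
#' @param x Raw-count `ExpressionMatrix`.
#' @param condition Factor/character per sample with exactly two levels;
#'   by default taken from `sample_meta$condition`.
#' @param reference Level treated as baseline (default `"normal"` when
#'   present, otherwise the first level).
#' @param factors Size factors; default [size_factors()] of `x`.
#' @return `data.frame(feature_id, base_mean, log2fc, se, stat, p,
#'   degenerate)` in feature order.
#' @export
nb_wald_test <- function(x, condition = x$sample_meta$condition,
                         reference = NULL, factors = size_factors(x)) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$transformed) stop("nb_wald_test expects raw counts")
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(lev) != 2L) stop("condition must have exactly two levels")
  if (is.null(reference))
    reference <- if ("normal" %in% lev) "normal" else lev[1L]
  if (!reference %in% lev) stop("unknown reference level: ", reference)
  other <- setdiff(lev, reference)
  if (min(table(condition)) < 2L) stop("need >= 2 samples per group")
  grp <- factor(condition, levels = c(reference, other))
  counts <- x$values
  norm <- sweep(counts, 2L, factors, `/`)
  off <- log(factors)

  n_feat <- nrow(counts)
  res <- data.frame(feature_id = rownames(counts), base_mean = rowMeans(norm),
                    log2fc = 0, se = NA_real_, stat = 0, p = 1,
                    degenerate = FALSE)
  g1 <- grp == reference
  g2 <- !g1
  for (i in seq_len(n_feat)) {
    y <- counts[i, ]
    if (all(y == 0)) { res$degenerate[i] <- TRUE; next }
    m <- mean(norm[i, ])
    v <- (sum((norm[i, g1] - mean(norm[i, g1]))^2) +
          sum((norm[i, g2] - mean(norm[i, g2]))^2)) / (length(y) - 2L)
    alpha <- max((v - m) / m^2, 1e-8)
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        y ~ grp + offset(off),
        family = MASS::negative.binomial(theta = 1 / alpha))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { res$degenerate[i] <- TRUE; next }
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2L) { res$degenerate[i] <- TRUE; next }
    beta <- cf[2L, 1L]
    se <- cf[2L, 2L]
    res$log2fc[i] <- beta / log(2)
    res$se[i] <- se / log(2)
    z <- beta / se
    res$stat[i] <- z
    res$p[i] <- 2 * stats::pt(-abs(z), df = length(y) - 2L)
  }
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call dysregulated features at strict thresholds
#'
#' A feature is `up` iff `padj < padj_cut` and `log2fc > log2(fc_cut)`,
#' `down` iff `padj < padj_cut` and `log2fc < -log2(fc_cut)`; all
#' inequalities strict.
#'
#' @param results Output of [nb_wald_test()]; a `padj` column is added via
#'   [adjust_bh()] if absent.
#' @param padj_cut Adjusted-p cut (0.1 for tumor-vs-normal, 0.25 for
#'   subclass contrasts by default convention).
#' @param fc_cut Linear fold-change cut (> 1).
#' @return `results` with `padj` and `direction`
#'   (`"up"`/`"down"`/`"ns"`) columns.
#' @export
call_dysregulated <- function(results, padj_cut = 0.1, fc_cut = 2) {
  stopifnot(is.data.frame(results), fc_cut > 1)
  if (!"padj" %in% names(results)) results$padj <- adjust_bh(results$p)
  lcut <- log2(fc_cut)
  results$direction <- ifelse(
    results$padj < padj_cut & results$log2fc > lcut, "up",
    ifelse(results$padj < padj_cut & results$log2fc < -lcut, "down", "ns"))
  results
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Mid-rank tie handling, normal approximation for larger samples and the
#' exact distribution when free of ties and small (the base R convention).
#' Used for two-group comparisons on supplied expression vectors, e.g.
#' exosome tumor-versus-healthy contrasts.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping of `values`.
#' @return Two-sided p-value.
#' @export
wilcoxon_two_group <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("need exactly two groups")
  a <- values[groups == lev[1L]]
  b <- values[groups == lev[2L]]
  if (!length(a) || !length(b)) stop("a group is empty")
  suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
}
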