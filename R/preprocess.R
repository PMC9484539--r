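# Expression filtering, size-factor normalization, log transform.

#' Filter features by expression prevalence
#'
#' Keeps features whose raw count strictly exceeds `min_count` in at least
#' `ceiling(min_sample_frac * n_samples)` samples. Feature order is
#' preserved and the operation is idempotent.
#'
#' @param x Raw-count `ExpressionMatrix`.
#' @param min_count Count that must be exceeded (strict `>`).
#' @param min_sample_frac Required fraction of samples, rounded up to a
#'   whole number of samples.
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_expressed <- function(x, min_count = 5, min_sample_frac = 0.2) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$transformed) stop("filter_expressed expects raw counts")
  if (nrow(x$values) == 0L || ncol(x$values) == 0L)
    stop("empty expression matrix")
  need <- ceiling(min_sample_frac * ncol(x$values))
  keep <- rowSums(x$values > min_count) >= need
  subset_expression(x, features = which(keep))
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median, over features with
#' all-positive counts, of the ratio of the sample's count to the feature's
#' geometric mean across samples. This is the standard count-normalization
#' used for negative-binomial RNA-seq models.
#'
#' @param x Raw-count `ExpressionMatrix` with at least two samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$transformed) stop("size_factors expects raw counts")
  counts <- x$values
  if (ncol(counts) < 2L) stop("need at least two samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in every sample; ",
         "consider adding a pseudocount upstream")
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2L, function(col) exp(stats::median(col - loggeo)))
  names(sf) <- colnames(counts)
  sf
}

#' Shifted-log transform of normalized counts
#'
#' Computes `log2(count / size_factor + pseudocount)` per cell. A simple
#' variance-compressing monotone transform of library-size-normalized
#' counts; downstream correlation and clustering stages only require
#' monotonicity and an approximately stabilized scale.
#'
#' @param x Raw-count `ExpressionMatrix`.
#' @param factors Positive per-sample size factors (defaults to
#'   [size_factors()] of `x`).
#' @param pseudocount Added inside the log; count 0 maps to
#'   `log2(pseudocount)`.
#' @return A transformed `ExpressionMatrix` (`transformed = TRUE`).
#' @export
transform_counts <- function(x, factors = size_factors(x), pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$transformed) stop("matrix already transformed")
  if (length(factors) != ncol(x$values))
    stop("one size factor per sample required")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  vals <- log2(sweep(x$values, 2L, factors, `/`) + pseudocount)
  ExpressionMatrix(vals, x$feature_meta, x$sample_meta, transformed = TRUE)
}
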