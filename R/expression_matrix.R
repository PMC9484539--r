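# ExpressionMatrix: the feature-by-sample container every stage consumes.

#' Construct an ExpressionMatrix
#'
#' Bundles a feature-by-sample numeric matrix with feature and sample
#' metadata. Raw count matrices (the input to filtering, normalization and
#' differential expression) must be non-negative integers; transformed
#' matrices (log2 scale, see [transform_counts()]) are flagged by
#' `transformed = TRUE`.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row
#'   names are feature IDs, column names sample IDs; both must be unique.
#' @param feature_meta `data.frame` with at least a `feature_id` column
#'   matching `rownames(values)`; typically also `biotype` (one of
#'   `"mRNA"`, `"lncRNA"`, `"circRNA"`, `"miRNA"`) and optional coordinates.
#'   If `NULL`, a minimal frame is built from the row names.
#' @param sample_meta `data.frame` with at least a `sample_id` column
#'   matching `colnames(values)`; typically also `condition`
#'   (`"tumor"`/`"normal"`), `pair_id`, and optional subclass/survival
#'   columns. If `NULL`, built from the column names.
#' @param transformed Logical; `FALSE` for raw counts.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `feature_meta`, `sample_meta`, `transformed`.
#' @export
ExpressionMatrix <- function(values, feature_meta = NULL, sample_meta = NULL,
                             transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0L)
      stop("'values' must have feature row names")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0L)
      stop("'values' must have sample column names")
    colnames(values) <- character(0)
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("'values' contains NA")
  if (any(values < 0)) stop("'values' contains negative entries")
  if (!transformed && any(values != floor(values)))
    stop("raw counts must be integers; use transformed = TRUE for log-scale values")

  if (is.null(feature_meta))
    feature_meta <- data.frame(feature_id = rownames(values))
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = colnames(values))
  stopifnot(is.data.frame(feature_meta), is.data.frame(sample_meta))
  if (!"feature_id" %in% names(feature_meta))
    stop("feature_meta needs a 'feature_id' column")
  if (!"sample_id" %in% names(sample_meta))
    stop("sample_meta needs a 'sample_id' column")

  missing_f <- setdiff(rownames(values), feature_meta$feature_id)
  if (length(missing_f))
    stop("features absent from feature_meta: ", paste(utils::head(missing_f, 5), collapse = ", "))
  missing_s <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing_s))
    stop("samples absent from sample_meta: ", paste(missing_s, collapse = ", "))

  # align metadata to matrix order
  feature_meta <- feature_meta[match(rownames(values), feature_meta$feature_id), , drop = FALSE]
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(feature_meta) <- NULL
  rownames(sample_meta) <- NULL

  structure(
    list(values = values, feature_meta = feature_meta,
         sample_meta = sample_meta, transformed = isTRUE(transformed)),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "transformed" else "raw counts"))
  if ("biotype" %in% names(x$feature_meta)) {
    tab <- table(x$feature_meta$biotype)
    cat("  biotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if ("condition" %in% names(x$sample_meta)) {
    tab <- table(x$sample_meta$condition)
    cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by feature and/or sample
#'
#' @param x An `ExpressionMatrix`.
#' @param features,samples Character IDs, logical masks or integer indices;
#'   `NULL` keeps everything.
#' @return The subsetted `ExpressionMatrix`.
#' @export
subset_expression <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  fi <- if (is.null(features)) seq_len(nrow(x$values)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else samples
  if (is.character(fi)) {
    miss <- setdiff(fi, rownames(x$values))
    if (length(miss)) stop("unknown features: ", paste(utils::head(miss, 5), collapse = ", "))
    fi <- match(fi, rownames(x$values))
  }
  if (is.character(si)) {
    miss <- setdiff(si, colnames(x$values))
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    si <- match(si, colnames(x$values))
  }
  ExpressionMatrix(x$values[fi, si, drop = FALSE],
                   x$feature_meta[fi, , drop = FALSE],
                   x$sample_meta[si, , drop = FALSE],
                   transformed = x$transformed)
}

#' Default analysis thresholds
#'
#' One place for every numeric cut used across the pipeline. All
#' inequalities downstream are strict unless noted otherwise, matching the
#' printed conventions this workflow follows: a feature is expressed when
#' its count exceeds `min_count`; dysregulation requires adjusted p below
#' the stage's cut and fold change beyond `fc`; ceRNA edges require a
#' hypergeometric p below `hypergeom_p`, a ceRNA-mRNA Pearson correlation
#' above `pcc_cerna_mrna`, and strictly more than `min_shared_mirnas`
#' shared miRNAs.
#'
#' @param min_count Expression filter count cut (strictly greater-than).
#' @param min_sample_frac Fraction of samples that must pass `min_count`.
#' @param padj_tumorigenesis Adjusted-p cut for tumor-vs-normal calls.
#' @param padj_subclass Adjusted-p cut for subclass calls.
#' @param fdr_prognosis FDR cut for prognosis classification and DE.
#' @param fc Fold-change cut (linear scale, applied two-sided).
#' @param pcc_mirna_target Pearson cut for miRNA-target anti-correlation
#'   (pairs kept when PCC is at or below this value).
#' @param pcc_cerna_mrna Pearson cut for ceRNA-mRNA co-expression (strict >).
#' @param min_shared_mirnas Shared-miRNA count cut (strict >).
#' @param hypergeom_p Hypergeometric p cut (strict <).
#' @param pcc_cis_pair Pearson cut for cis ncRNA-neighbor pairs (strict >).
#'
#' @return A named list of class `cerna_thresholds`.
#' @export
cerna_thresholds <- function(min_count = 5, min_sample_frac = 0.2,
                             padj_tumorigenesis = 0.1, padj_subclass = 0.25,
                             fdr_prognosis = 0.05, fc = 2,
                             pcc_mirna_target = -0.4, pcc_cerna_mrna = 0.6,
                             min_shared_mirnas = 4, hypergeom_p = 1e-6,
                             pcc_cis_pair = 0.8) {
  stopifnot(min_sample_frac >= 0, min_sample_frac <= 1,
            padj_tumorigenesis >= 0, padj_tumorigenesis <= 1,
            padj_subclass >= 0, padj_subclass <= 1,
            fdr_prognosis >= 0, fdr_prognosis <= 1,
            fc > 1, min_count >= 0, hypergeom_p > 0)
  structure(list(
    min_count = min_count, min_sample_frac = min_sample_frac,
    padj_tumorigenesis = padj_tumorigenesis, padj_subclass = padj_subclass,
    fdr_prognosis = fdr_prognosis, fc = fc,
    pcc_mirna_target = pcc_mirna_target, pcc_cerna_mrna = pcc_cerna_mrna,
    min_shared_mirnas = min_shared_mirnas, hypergeom_p = hypergeom_p,
    pcc_cis_pair = pcc_cis_pair), class = "cerna_thresholds")
}
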