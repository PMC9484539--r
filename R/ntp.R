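# Nearest-template prediction: single-sample classification against
# signed signature templates with resampling-based significance.

cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  1 - sum(a * b) / (na * nb)
}

#' Nearest-template prediction of sample classes
#'
#' Each sample's expression vector over the union of template genes is
#' standardized (mean 0, SD 1 across genes), then compared to every
#' class's signed template by cosine distance `d = 1 - cos(sample,
#' template)` over the template genes present in the matrix. The
#' predicted class minimizes the distance (ties broken by template list
#' order and flagged non-confident). Significance is resampled: `n_perm`
#' random templates of the same size are drawn from the matrix's features
#' and `p = (1 + #{d_random <= d_observed}) / (n_perm + 1)`; FDR across
#' samples by Benjamini-Hochberg.
#'
#' @param x Transformed `ExpressionMatrix`.
#' @param templates Named list (class label -> `data.frame(gene_id,
#'   sign)`), e.g. from [read_signatures()]; each template needs >= 2
#'   genes and >= 50% of them present in `x`.
#' @param n_perm Random templates per sample (default 1000).
#' @param fdr_cut Confidence threshold on the BH FDR.
#' @param seed Integer seed for the resampling null.
#' @return `data.frame(sample_id, predicted, distance, p, fdr, confident)`.
#' @export
ntp_classify <- function(x, templates, n_perm = 1000L, fdr_cut = 0.05,
                         seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"), length(templates) >= 2L)
  if (is.null(names(templates))) stop("templates must be a named list")
  feats <- rownames(x$values)
  templates <- lapply(templates, function(tp) {
    stopifnot(all(c("gene_id", "sign") %in% names(tp)))
    if (nrow(tp) < 2L) stop("templates need >= 2 genes")
    if (anyDuplicated(tp$gene_id)) stop("gene repeated within a template")
    present <- tp$gene_id %in% feats
    if (mean(present) < 0.5)
      stop("template coverage below 50% of signature genes")
    tp[present, , drop = FALSE]
  })
  sig_union <- unique(unlist(lapply(templates, `[[`, "gene_id")))
  expr <- x$values[sig_union, , drop = FALSE]

  set.seed(seed)
  n_samp <- ncol(expr)
  out <- data.frame(sample_id = colnames(expr), predicted = NA_character_,
                    distance = NA_real_, p = NA_real_, fdr = NA_real_,
                    confident = FALSE)
  all_feats <- rownames(x$values)
  tied <- logical(n_samp)
  for (j in seq_len(n_samp)) {
    v <- expr[, j]
    if (stats::sd(v) == 0) {
      warning("sample ", colnames(expr)[j],
              " has zero variance over signature genes; left unclassified")
      next
    }
    v <- (v - mean(v)) / stats::sd(v)
    names(v) <- sig_union
    d <- vapply(templates, function(tp)
      cosine_distance(v[tp$gene_id], tp$sign), numeric(1))
    best <- which.min(d)  # ties resolve to the first template
    tied[j] <- sum(d == d[best], na.rm = TRUE) > 1L
    out$predicted[j] <- names(templates)[best]
    out$distance[j] <- d[best]
    tp <- templates[[best]]
    m <- nrow(tp)
    # random templates of matched size drawn from the full feature space;
    # the sample vector over each random gene set is standardized the same
    # way as the observed signature vector
    full <- x$values[, j]
    d_null <- vapply(seq_len(n_perm), function(r) {
      g <- sample(all_feats, m)
      w <- full[g]
      s <- stats::sd(w)
      if (s == 0) return(NA_real_)
      cosine_distance((w - mean(w)) / s, tp$sign)
    }, numeric(1))
    out$p[j] <- (1 + sum(d_null <= out$distance[j], na.rm = TRUE)) / (n_perm + 1)
  }
  ok <- !is.na(out$p)
  out$fdr[ok] <- adjust_bh(out$p[ok])
  # tied predictions are never confident
  out$confident <- ok & !is.na(out$fdr) & out$fdr < fdr_cut & !tied
  out
}
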