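# ceRNA network assembly: shared-miRNA hypergeometric test combined with
# co-expression and shared-count criteria, plus cis ncRNA-neighbor pairs.

#' Upper-tail hypergeometric probability of shared miRNAs
#'
#' P(X >= k) for the number of miRNAs shared by two target sets of sizes
#' `K` and `n` drawn from a universe of `N` miRNAs; evaluated on the log
#' scale internally for stability at extreme tails.
#'
#' @param k Observed shared count.
#' @param K miRNAs targeting the ceRNA.
#' @param n miRNAs targeting the mRNA.
#' @param N Universe size.
#' @return The tail probability.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("require 0 <= k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Assemble the ceRNA network from filtered miRNA-target pairs
#'
#' For every (ceRNA, mRNA) combination among the filtered pairs, counts
#' the shared miRNAs `k`, computes the hypergeometric tail probability of
#' that overlap within the miRNA universe, and the Pearson correlation of
#' the two transcripts across all samples. An edge is emitted when all
#' three criteria hold strictly: `k > min_shared`, `p_hyper < p_cut`, and
#' `pcc > pcc_cut`. The universe `N` is the number of distinct miRNAs
#' appearing in at least one filtered pair (the tested miRNA space); set
#' `universe` to override.
#'
#' @param pairs Filtered pair table from [filter_pairs()] (columns
#'   `mirna_id`, `target_id`, `target_class`).
#' @param expression Transformed `ExpressionMatrix`.
#' @param p_cut,pcc_cut,min_shared The three strict thresholds
#'   (defaults 1e-6, 0.6, 4).
#' @param universe Optional character vector of miRNA IDs defining `N`.
#' @return A `data.frame` of class `cerna_edges`, sorted by `p_hyper`:
#'   columns `cerna_id`, `cerna_class`, `mrna_id`, `shared_mirnas`
#'   (list column), `k`, `K`, `n`, `N`, `p_hyper`, `p_hyper_bh`, `pcc`.
#' @export
assemble_network <- function(pairs, expression, p_cut = 1e-6, pcc_cut = 0.6,
                             min_shared = 4L, universe = NULL) {
  stopifnot(inherits(expression, "ExpressionMatrix"))
  empty <- data.frame(cerna_id = character(), cerna_class = character(),
                      mrna_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_hyper = numeric(),
                      p_hyper_bh = numeric(), pcc = numeric())
  empty$shared_mirnas <- list()
  class(empty) <- c("cerna_edges", "data.frame")
  if (is.null(pairs) || !nrow(pairs)) return(empty)

  is_cerna <- pairs$target_class %in% c("lncRNA", "circRNA")
  cerna_pairs <- pairs[is_cerna, , drop = FALSE]
  mrna_pairs <- pairs[pairs$target_class == "mRNA", , drop = FALSE]
  if (!nrow(cerna_pairs) || !nrow(mrna_pairs)) return(empty)
  if (is.null(universe)) universe <- unique(pairs$mirna_id)
  N <- length(universe)

  mirnas_of <- function(df) lapply(split(df$mirna_id, df$target_id), unique)
  cer_m <- mirnas_of(cerna_pairs)
  mr_m <- mirnas_of(mrna_pairs)
  cls <- stats::setNames(cerna_pairs$target_class, cerna_pairs$target_id)

  rows <- list()
  for (ce in sort(names(cer_m))) {
    for (mr in sort(names(mr_m))) {
      shared <- sort(intersect(cer_m[[ce]], mr_m[[mr]]))
      k <- length(shared)
      if (k <= min_shared) next
      K <- length(cer_m[[ce]])
      n <- length(mr_m[[mr]])
      p <- hypergeom_tail(k, K, n, N)
      if (p >= p_cut) next
      if (!all(c(ce, mr) %in% rownames(expression$values))) next
      pcc <- stats::cor(expression$values[ce, ], expression$values[mr, ])
      if (is.na(pcc) || pcc <= pcc_cut) next
      rows[[length(rows) + 1L]] <- data.frame(
        cerna_id = ce, cerna_class = unname(cls[ce]), mrna_id = mr,
        k = k, K = K, n = n, N = N, p_hyper = p, pcc = pcc,
        shared = I(list(shared)))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$p_hyper, out$cerna_id, out$mrna_id), , drop = FALSE]
  edges <- data.frame(
    cerna_id = out$cerna_id, cerna_class = out$cerna_class,
    mrna_id = out$mrna_id, k = out$k, K = out$K, n = out$n, N = out$N,
    p_hyper = out$p_hyper, p_hyper_bh = adjust_bh(out$p_hyper),
    pcc = out$pcc)
  edges$shared_mirnas <- unclass(out$shared)
  rownames(edges) <- NULL
  class(edges) <- c("cerna_edges", "data.frame")
  edges
}

#' Report cis ncRNA-neighbor gene co-expression pairs
#'
#' Pairs each ncRNA with annotated genes whose span lies within
#' `max_distance` of the ncRNA's span (antisense overlap included) and
#' reports those with Pearson correlation strictly above `pcc_cut` across
#' all samples; candidates for cis regulation of the neighbor.
#'
#' @param expression Transformed `ExpressionMatrix`.
#' @param ncrna_coords `data.frame(feature_id, chrom, start, end)` for the
#'   query ncRNAs.
#' @param genes A [gene_models()] table; gene IDs must match expression
#'   feature IDs to be scored.
#' @param pcc_cut Correlation threshold (strict >; default 0.8).
#' @param max_distance Maximum gap between spans in bases.
#' @return `data.frame(ncrna_id, gene_id, distance, pcc)`.
#' @export
cis_pairs <- function(expression, ncrna_coords, genes, pcc_cut = 0.8,
                      max_distance = 10000L) {
  stopifnot(inherits(expression, "ExpressionMatrix"),
            inherits(genes, "gene_models"))
  span <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end))))
  out <- list()
  for (i in seq_len(nrow(ncrna_coords))) {
    nc <- ncrna_coords[i, ]
    if (!nc$feature_id %in% rownames(expression$values)) next
    near <- span[span$chrom == nc$chrom, , drop = FALSE]
    if (!nrow(near)) next
    dist <- pmax(0L, pmax(near$start - nc$end, nc$start - near$end))
    keep <- dist <= max_distance & near$gene_id != nc$feature_id
    near <- near[keep, , drop = FALSE]
    dist <- dist[keep]
    for (j in seq_len(nrow(near))) {
      if (!near$gene_id[j] %in% rownames(expression$values)) next
      pcc <- stats::cor(expression$values[nc$feature_id, ],
                        expression$values[near$gene_id[j], ])
      if (!is.na(pcc) && pcc > pcc_cut)
        out[[length(out) + 1L]] <- data.frame(
          ncrna_id = nc$feature_id, gene_id = near$gene_id[j],
          distance = dist[j], pcc = pcc)
    }
  }
  if (!length(out))
    return(data.frame(ncrna_id = character(), gene_id = character(),
                      distance = integer(), pcc = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
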