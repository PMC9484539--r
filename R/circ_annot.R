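# Back-splice junction origin annotation against gene models, and the
# alternative-circularization summary.
#
# Classification cascade (per junction, same-strand genes only):
#   1. exonic    - both breakpoints within `slack` of exon boundaries of
#                  one gene (acceptor vs an exon start, donor vs an exon
#                  end);
#   2. intronic  - the full span strictly inside a single intron;
#   3. exonic*   - overlaps a gene and either breakpoint falls inside an
#                  exon (dominant-category fallback, flagged ambiguous);
#   4. intronic* - overlaps a gene some other way (flagged ambiguous);
#   5. intergenic- overlaps no same-strand gene (antisense-only overlap
#                  counts as intergenic: splice-site annotation is
#                  strand-specific).

#' Classify back-splice junctions by genomic origin
#'
#' @param junctions A `circ_junctions` table ([read_junctions()] or
#'   [simulate_annotation()]), 1-based inclusive coordinates.
#' @param genes A [gene_models()] table.
#' @param slack Breakpoint tolerance in bases for the exon-boundary match
#'   (0 = exact; 2 accommodates aligner wobble).
#' @return `data.frame(circ_id, origin, host_gene, ambiguous)`; `origin`
#'   is one of `exonic`, `intronic`, `intergenic`; `host_gene` is `NA`
#'   iff intergenic. Every junction receives exactly one origin.
#' @export
classify_origin <- function(junctions, genes, slack = 0L) {
  stopifnot(inherits(genes, "gene_models"), slack >= 0)
  by_gene <- split(genes, genes$gene_id)
  gene_span <- do.call(rbind, lapply(by_gene, function(g)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end))))
  n <- nrow(junctions)
  out <- data.frame(circ_id = junctions$circ_id,
                    origin = "intergenic", host_gene = NA_character_,
                    ambiguous = FALSE)
  for (i in seq_len(n)) {
    j <- junctions[i, ]
    cand <- gene_span[gene_span$chrom == j$chrom &
                        gene_span$strand == j$strand &
                        gene_span$start <= j$end & gene_span$end >= j$start, ,
                      drop = FALSE]
    if (!nrow(cand)) {
      if (!j$chrom %in% genes$chrom)
        warning("junction ", j$circ_id, " on unannotated chromosome ",
                j$chrom, "; called intergenic")
      next
    }
    call <- NULL
    for (gid in cand$gene_id) {
      g <- by_gene[[gid]]
      on_start <- any(abs(g$start - j$start) <= slack)
      on_end <- any(abs(g$end - j$end) <= slack)
      if (on_start && on_end) { call <- list("exonic", gid, FALSE); break }
    }
    if (is.null(call)) {
      for (gid in cand$gene_id) {
        g <- by_gene[[gid]]
        if (nrow(g) < 2L) next
        istart <- g$end[-nrow(g)] + 1L
        iend <- g$start[-1L] - 1L
        inside <- istart <= j$start & j$end <= iend
        if (any(inside)) { call <- list("intronic", gid, FALSE); break }
      }
    }
    if (is.null(call)) {
      # dominant-category fallback: either breakpoint inside an exon
      for (gid in cand$gene_id) {
        g <- by_gene[[gid]]
        in_exon <- function(p) any(g$start <= p & p <= g$end)
        if (in_exon(j$start) || in_exon(j$end)) {
          call <- list("exonic", gid, TRUE)
          break
        }
      }
    }
    if (is.null(call)) call <- list("intronic", cand$gene_id[1], TRUE)
    out$origin[i] <- call[[1]]
    out$host_gene[i] <- call[[2]]
    out$ambiguous[i] <- call[[3]]
  }
  out
}

#' Summarize alternative circularization per host gene
#'
#' Counts circRNA isoforms (exonic plus intronic calls) per host gene and
#' reports the fraction of host genes producing at least `k` isoforms
#' (`k = 2` flags any alternative circularization; use `k = 3` for a
#' strictly-more-than-two reading).
#'
#' @param calls Origin table from [classify_origin()].
#' @param k Isoform-count threshold (fraction reported at `>= k`).
#' @return List with `per_gene` (`data.frame(host_gene, n_isoforms)`) and
#'   `fraction` (host genes with `n_isoforms >= k`).
#' @export
alt_circularization <- function(calls, k = 2L) {
  stopifnot(k >= 1L)
  hosted <- calls[!is.na(calls$host_gene), , drop = FALSE]
  if (!nrow(hosted))
    return(list(per_gene = data.frame(host_gene = character(),
                                      n_isoforms = integer()),
                fraction = NA_real_))
  tab <- table(hosted$host_gene)
  per_gene <- data.frame(host_gene = names(tab),
                         n_isoforms = as.integer(tab))
  list(per_gene = per_gene, fraction = mean(per_gene$n_isoforms >= k))
}
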