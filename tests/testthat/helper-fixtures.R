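# Small deterministic fixtures shared across test files.

small_config <- function(seed = 42L, ...) {
  defaults <- list(
    n_pairs = 8L,
    n_features_by_biotype = c(mRNA = 300L, lncRNA = 120L,
                              circRNA = 60L, miRNA = 60L),
    n_sponge_triplets = 2L,
    n_signature_genes = 30L,
    seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# raw-count matrix with explicit metadata, half tumor half normal
toy_matrix <- function(values, transformed = FALSE) {
  n <- ncol(values)
  stopifnot(n %% 2 == 0)
  meta <- data.frame(sample_id = colnames(values),
                     condition = rep(c("tumor", "normal"), each = n / 2))
  ExpressionMatrix(values, sample_meta = meta, transformed = transformed)
}

# vector with an exact Pearson correlation r to x, built from an
# orthogonal direction z
vector_with_cor <- function(x, z, r) {
  xs <- (x - mean(x)) / sd(x)
  zc <- z - mean(z)
  zc <- zc - sum(zc * xs) / sum(xs * xs) * xs
  zs <- zc / sd(zc)
  r * xs + sqrt(1 - r^2) * zs
}

# two-exon-plus gene model fixture on one chromosome:
# gene_A (+): exons 101-200, 301-400, 501-600
# gene_B (-): exons 2001-2100, 2301-2400
toy_genes <- function() {
  gene_models(data.frame(
    gene_id = c("gene_A", "gene_A", "gene_A", "gene_B", "gene_B"),
    chrom = "chr1",
    strand = c("+", "+", "+", "-", "-"),
    start = c(101L, 301L, 501L, 2001L, 2301L),
    end = c(200L, 400L, 600L, 2100L, 2400L),
    biotype = "protein_coding"))
}
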