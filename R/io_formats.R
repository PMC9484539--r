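# Readers/writers for the standard formats the pipeline touches:
# GTF gene models, count TSVs, BED-like back-splice junctions, FASTA,
# signature/GMT/target tables, and network TSV/GraphML.
#
# Coordinate conventions: GTF is 1-based inclusive, junction BED is 0-based
# half-open. Each is converted exactly once, at read time, to the 1-based
# inclusive internal convention.

#' Construct a gene-model table
#'
#' Gene models are stored as one exon per row with per-gene invariants
#' enforced: exons sorted by start, non-overlapping within a gene,
#' `start <= end`, one chromosome/strand/biotype per gene.
#'
#' @param exons `data.frame` with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive), `biotype`.
#' @return The validated `data.frame` with class `gene_models`, sorted by
#'   gene then exon start.
#' @export
gene_models <- function(exons) {
  req <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  miss <- setdiff(req, names(exons))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  exons <- as.data.frame(exons)[req]
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(exons$start > exons$end)) stop("exon start > end")
  if (any(exons$start < 1)) stop("coordinates are 1-based; start < 1")
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  for (idx in by_gene) {
    g <- exons[idx, , drop = FALSE]
    if (length(unique(g$chrom)) != 1L || length(unique(g$strand)) != 1L)
      stop("gene ", g$gene_id[1], " spans multiple chromosomes or strands")
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)]))
      stop("gene ", g$gene_id[1], " has overlapping exons")
  }
  rownames(exons) <- NULL
  class(exons) <- c("gene_models", "data.frame")
  exons
}

#' Read gene models from a GTF file
#'
#' Parses exon records of a GENCODE-style GTF (1-based inclusive) into a
#' [gene_models()] table. Records other than `exon` are ignored.
#'
#' @param path Path to a GTF file whose exon lines carry a `gene_id`
#'   attribute (and optionally `gene_biotype`).
#' @return A `gene_models` table.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  is_exon <- vapply(strsplit(lines[body], "\t", fixed = TRUE),
                    function(f) length(f) >= 9 && f[3] == "exon", logical(1))
  bad <- body[is_exon][!grepl("gene_id", lines[body][is_exon], fixed = TRUE)]
  if (length(bad))
    stop("GTF line ", bad[1], " lacks a gene_id attribute")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else rep("other", length(gr))
  biotype[is.na(biotype)] <- "other"
  gene_models(data.frame(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    biotype = biotype))
}

#' Write gene models to a GTF file
#'
#' Emits one `exon` record per row, 1-based inclusive, with `gene_id` and
#' `gene_biotype` attributes; round-trips losslessly through [read_gtf()].
#'
#' @param models A `gene_models` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(models$start, models$end),
    strand = models$strand,
    type = "exon",
    source = "cernakit",
    gene_id = models$gene_id,
    gene_biotype = models$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a count matrix TSV into an ExpressionMatrix
#'
#' Expects a header row of sample IDs and a first column of feature IDs;
#' the body must be non-negative integers. Malformed cells are rejected
#' with their coordinates rather than coerced.
#'
#' @param path Count TSV path.
#' @param feature_meta,sample_meta Optional metadata `data.frame`s (or TSV
#'   paths) passed to [ExpressionMatrix()]; every sample/feature of the
#'   matrix must be present there.
#' @return A raw-count `ExpressionMatrix`.
#' @export
read_counts <- function(path, feature_meta = NULL, sample_meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("count table needs a feature column plus samples")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature ID in ", path, ": ",
         ids[duplicated(ids)][1])
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at feature '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(num)[bad[1, 2]]))
  if (is.character(feature_meta)) feature_meta <- utils::read.delim(feature_meta)
  if (is.character(sample_meta)) sample_meta <- utils::read.delim(sample_meta)
  ExpressionMatrix(num, feature_meta, sample_meta)
}

#' Write an ExpressionMatrix body as TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path; first column `feature_id`, then one column per
#'   sample.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back-splice junctions from a BED-like TSV
#'
#' Six headerless columns: chrom, start (0-based), end (half-open), name,
#' read support, strand. Coordinates are converted once, here, to the
#' 1-based inclusive internal convention (acceptor `start`, donor `end`).
#'
#' @param path Junction TSV path.
#' @return `data.frame` with columns `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, `read_support` (class `circ_junctions`).
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE)
  if (ncol(df) < 6L) stop("junction file needs 6 BED-like columns")
  out <- data.frame(
    circ_id = as.character(df[[4L]]),
    chrom = as.character(df[[1L]]),
    start = as.integer(df[[2L]]) + 1L,
    end = as.integer(df[[3L]]),
    strand = as.character(df[[6L]]),
    read_support = as.integer(df[[5L]]))
  if (any(is.na(out$start) | is.na(out$end)))
    stop("non-numeric junction coordinates in ", path)
  if (any(out$start >= out$end)) stop("junction start must precede end")
  if (any(out$read_support < 0, na.rm = TRUE)) stop("negative read support")
  class(out) <- c("circ_junctions", "data.frame")
  out
}

#' Write back-splice junctions as a BED-like TSV
#'
#' @param junctions A `circ_junctions` table (1-based inclusive).
#' @param path Output path; written 0-based half-open, headerless.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path) {
  df <- data.frame(junctions$chrom, junctions$start - 1L, junctions$end,
                   junctions$circ_id, junctions$read_support, junctions$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read RNA sequences from FASTA
#'
#' @param path FASTA path. `T` is accepted and converted to `U`.
#' @return Named character vector of uppercase RNA sequences.
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("non-RNA characters in sequence ", names(seqs)[bad][1])
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write RNA sequences to FASTA
#'
#' @param seqs Named character vector of RNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' Accepts either the normalized schema (`mirna_id`, `target_id`,
#' `evidence`, `source`) or two common database dialects, detected from the
#' header: a validated-interaction dialect with `miRNA` / `Target Gene`
#' columns, and a prediction dialect with `miR Family` / `Gene Symbol`
#' columns. Both are normalized to one schema; duplicate
#' (miRNA, target, source) rows are dropped.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `mirna_id`, `target_id`, `evidence`
#'   (`"validated"` or `"predicted"`), `source`.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  lower <- tolower(names(df))
  norm <- function(mirna, target, evidence, source) {
    out <- data.frame(mirna_id = as.character(mirna),
                      target_id = as.character(target),
                      evidence = evidence, source = source)
    out[!duplicated(out[c("mirna_id", "target_id", "source")]), , drop = FALSE]
  }
  if (all(c("mirna_id", "target_id") %in% lower)) {
    ev <- if ("evidence" %in% lower) df[[which(lower == "evidence")]] else "validated"
    src <- if ("source" %in% lower) df[[which(lower == "source")]] else "user"
    return(norm(df[[which(lower == "mirna_id")]],
                df[[which(lower == "target_id")]], ev, src))
  }
  if ("mirna" %in% lower && "target gene" %in% lower) {
    return(norm(df[[which(lower == "mirna")]],
                df[[which(lower == "target gene")]],
                "validated", "miRTarBase"))
  }
  if ("mir family" %in% lower && "gene symbol" %in% lower) {
    return(norm(df[[which(lower == "mir family")]],
                df[[which(lower == "gene symbol")]],
                "predicted", "TargetScan"))
  }
  stop("unrecognized target-table dialect in ", path)
}

#' Read signed signature templates from TSV
#'
#' @param path TSV with columns `class`, `gene_id`, `sign` (+1/-1).
#' @return A list of templates as consumed by [ntp_classify()]: one element
#'   per class label, each a `data.frame` with `gene_id` and `sign`.
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path)
  req <- c("class", "gene_id", "sign")
  if (!all(req %in% names(df))) stop("signature TSV needs columns class, gene_id, sign")
  if (!all(df$sign %in% c(-1L, 1L))) stop("sign must be +1 or -1")
  lapply(split(df[c("gene_id", "sign")], df$class), function(d) {
    if (anyDuplicated(d$gene_id)) stop("gene repeated within a class")
    rownames(d) <- NULL
    d
  })
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("GMT line ", which(bad)[1], " has fewer than 3 fields")
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1L))
}

#' Write a ceRNA network to TSV or GraphML
#'
#' The TSV has one row per ceRNA-mRNA edge with the shared miRNAs
#' semicolon-joined. The GraphML graph contains one node per distinct
#' molecule (ceRNAs, mRNAs, and shared miRNAs) with `biotype` and
#' `direction` attributes, a ceRNA-mRNA edge per network edge, and
#' miRNA-ceRNA / miRNA-mRNA support edges.
#'
#' @param edges A `cerna_edges` table from [assemble_network()].
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @param directions Optional named character vector mapping molecule IDs
#'   to `"up"`/`"down"`; absent molecules are written as `"ns"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("tsv", "graphml"),
                          directions = NULL) {
  format <- match.arg(format)
  shared_chr <- vapply(edges$shared_mirnas, paste, character(1), collapse = ";")
  if (format == "tsv") {
    df <- data.frame(
      cerna_id = edges$cerna_id, cerna_class = edges$cerna_class,
      mrna_id = edges$mrna_id, shared_mirnas = shared_chr,
      k = edges$k, K = edges$K, n = edges$n, N = edges$N,
      p_hyper = edges$p_hyper, pcc = edges$pcc)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  mirnas <- unique(unlist(edges$shared_mirnas))
  nodes <- data.frame(
    name = c(unique(edges$cerna_id), unique(edges$mrna_id), mirnas),
    biotype = c(edges$cerna_class[!duplicated(edges$cerna_id)],
                rep("mRNA", length(unique(edges$mrna_id))),
                rep("miRNA", length(mirnas))))
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  dirs <- rep("ns", nrow(nodes))
  if (!is.null(directions)) {
    hit <- nodes$name %in% names(directions)
    dirs[hit] <- unname(directions[nodes$name[hit]])
  }
  nodes$direction <- dirs
  el <- data.frame(from = character(), to = character(),
                   relation = character())
  if (nrow(edges))
    el <- rbind(
      data.frame(from = edges$cerna_id, to = edges$mrna_id,
                 relation = rep("ceRNA", nrow(edges))),
      do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
        m <- edges$shared_mirnas[[i]]
        if (!length(m)) return(NULL)
        data.frame(from = rep(m, 2L),
                   to = c(rep(edges$cerna_id[i], length(m)),
                          rep(edges$mrna_id[i], length(m))),
                   relation = "miRNA_target")
      })))
  el <- el[!duplicated(el), , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
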