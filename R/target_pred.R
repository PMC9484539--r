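# Strict-seed miRNA target site discovery and candidate pair filtering.
#
# A canonical site is an exact Watson-Crick reverse complement of the
# miRNA seed on the target (no G:U wobble). With the miRNA seed spanning
# positions 2-8 (5'->3'), a target site read 5'->3' is
# [comp(m8)]..[comp(m2)][A opposite m1]; the 6mer core is the reverse
# complement of positions 2-7, extended upstream to match position 8
# (7mer-m8) and/or downstream by an A opposite position 1 (7mer-A1, 8mer).

rna_revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))

check_rna <- function(x, what = "sequence") {
  if (grepl("[^ACGU]", x))
    stop(what, " contains non-RNA characters (expect uppercase A/C/G/U)")
  x
}

#' The 7mer-m8 site sequence of a miRNA
#'
#' Reverse complement of miRNA positions 2-8; the minimal site reported in
#' strict mode.
#'
#' @param mirna_seq Mature miRNA sequence, uppercase RNA, 5'->3'.
#' @return The 7-base site sequence (target strand, 5'->3').
#' @export
seed_site_sequence <- function(mirna_seq) {
  check_rna(mirna_seq, "miRNA")
  if (nchar(mirna_seq) < 8L) stop("miRNA shorter than 8 bases")
  rna_revcomp(substr(mirna_seq, 2L, 8L))
}

#' Scan a target sequence for canonical seed sites
#'
#' Finds every exact reverse-complement match of the miRNA 6mer core
#' (positions 2-7) in the target and classifies each maximally as `6mer`,
#' `7mer-A1`, `7mer-m8` or `8mer`. In strict mode (the default) only the
#' sites with position-8 pairing (`7mer-m8`, `8mer`) are reported.
#'
#' @param mirna_seq Mature miRNA sequence (>= 18 bases, uppercase RNA).
#' @param target_seq Target RNA sequence, uppercase.
#' @param strict Report only 7mer-m8/8mer sites.
#' @return `data.frame(position, site_type)`; `position` is the 1-based
#'   start of the full site span on the target.
#' @export
seed_sites <- function(mirna_seq, target_seq, strict = TRUE) {
  check_rna(mirna_seq, "miRNA")
  check_rna(target_seq, "target")
  if (nchar(mirna_seq) < 18L) stop("mature miRNA shorter than 18 bases")
  empty <- data.frame(position = integer(), site_type = character())
  core6 <- rna_revcomp(substr(mirna_seq, 2L, 7L))
  len <- nchar(target_seq)
  if (len < 6L) return(empty)
  hits <- Biostrings::matchPattern(core6, Biostrings::RNAString(target_seq))
  p <- Biostrings::start(hits)
  if (!length(p)) return(empty)
  comp_m8 <- rna_revcomp(substr(mirna_seq, 8L, 8L))
  has_m8 <- p > 1L & substring(target_seq, p - 1L, p - 1L) == comp_m8
  has_a1 <- p + 6L <= len & substring(target_seq, p + 6L, p + 6L) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
                 ifelse(has_m8, "7mer-m8",
                        ifelse(has_a1, "7mer-A1", "6mer")))
  pos <- ifelse(has_m8, p - 1L, p)
  out <- data.frame(position = as.integer(pos), site_type = type)
  if (strict) out <- out[out$site_type %in% c("7mer-m8", "8mer"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many miRNAs against many targets
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param targets Named character vector of target sequences.
#' @param strict Passed to [seed_sites()].
#' @return `data.frame(mirna_id, target_id, position, site_type)`.
#' @export
find_seed_sites <- function(mirnas, targets, strict = TRUE) {
  out <- list()
  for (m in names(mirnas)) {
    for (t in names(targets)) {
      s <- seed_sites(mirnas[[m]], targets[[t]], strict = strict)
      if (nrow(s))
        out[[length(out) + 1L]] <- data.frame(mirna_id = m, target_id = t, s)
    }
  }
  if (!length(out))
    return(data.frame(mirna_id = character(), target_id = character(),
                      position = integer(), site_type = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble candidate miRNA-target pairs
#'
#' ncRNA (lncRNA/circRNA) candidates come from seed-site hits on the ncRNA
#' sequences; mRNA candidates come from the external interaction table
#' (predicted and validated sources merged, duplicates collapsed with
#' pooled evidence). Each pair is annotated with both molecules'
#' dysregulation directions; molecules without a DE call are dropped with
#' a warning.
#'
#' @param de_calls `data.frame` with `feature_id`, `direction`
#'   (`"up"`/`"down"`/`"ns"`) and `biotype` columns covering every
#'   molecule of interest.
#' @param sites Seed-site table from [find_seed_sites()] whose targets are
#'   ncRNAs.
#' @param external Normalized target table from [read_target_table()]
#'   (mRNA targets), or `NULL`.
#' @return `data.frame(mirna_id, target_id, target_class, evidence,
#'   mirna_dir, target_dir)` with one row per (miRNA, target).
#' @export
build_candidates <- function(de_calls, sites = NULL, external = NULL) {
  stopifnot(all(c("feature_id", "direction", "biotype") %in% names(de_calls)))
  dirs <- stats::setNames(de_calls$direction, de_calls$feature_id)
  bios <- stats::setNames(de_calls$biotype, de_calls$feature_id)
  rows <- list()
  if (!is.null(sites) && nrow(sites)) {
    key <- paste(sites$mirna_id, sites$target_id)
    nc <- sites[!duplicated(key), c("mirna_id", "target_id"), drop = FALSE]
    rows[[1L]] <- data.frame(nc, evidence = "seed")
  }
  if (!is.null(external) && nrow(external)) {
    ev <- ifelse(external$evidence == "validated", "validated_db", "predicted_db")
    key <- paste(external$mirna_id, external$target_id)
    merged <- vapply(split(ev, key), function(e)
      paste(sort(unique(e)), collapse = ";"), character(1))
    first <- external[!duplicated(key), c("mirna_id", "target_id"), drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      first, evidence = unname(merged[paste(first$mirna_id, first$target_id)]))
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), evidence = character(),
                      mirna_dir = character(), target_dir = character()))
  pairs <- do.call(rbind, rows)
  known <- pairs$mirna_id %in% names(dirs) & pairs$target_id %in% names(dirs)
  if (any(!known)) {
    warning(sum(!known), " candidate pair(s) dropped: molecule lacks a DE call")
    pairs <- pairs[known, , drop = FALSE]
  }
  cls <- unname(bios[pairs$target_id])
  cls[cls == "protein_coding"] <- "mRNA"
  out <- data.frame(
    mirna_id = pairs$mirna_id, target_id = pairs$target_id,
    target_class = cls, evidence = pairs$evidence,
    mirna_dir = unname(dirs[pairs$mirna_id]),
    target_dir = unname(dirs[pairs$target_id]))
  rownames(out) <- NULL
  out
}

#' Filter candidate pairs by opposite dysregulation and anti-correlation
#'
#' Keeps pairs whose miRNA and target are dysregulated in opposite
#' directions (up/down or down/up) and whose Pearson correlation across
#' all cohort samples (tumor plus normal, transformed scale) is at or
#' below the threshold (default -0.4, inclusive). Pairs with fewer than
#' `min_samples` shared samples, or a molecule absent from the expression
#' matrix, are dropped with a warning.
#'
#' @param pairs Candidate table from [build_candidates()].
#' @param expression Transformed `ExpressionMatrix` containing miRNAs and
#'   targets.
#' @param pcc_cut Retain pairs with `pcc <= pcc_cut`.
#' @param min_samples Minimum shared samples for a correlation.
#' @return The retained rows with a `pcc` column appended.
#' @export
filter_pairs <- function(pairs, expression, pcc_cut = -0.4, min_samples = 4L) {
  stopifnot(inherits(expression, "ExpressionMatrix"))
  if (!expression$transformed)
    warning("correlations computed on raw counts; pass a transformed matrix")
  if (!nrow(pairs)) return(cbind(pairs, pcc = numeric(0)))
  if (ncol(expression$values) < min_samples)
    stop("fewer than ", min_samples, " samples available for correlation")
  present <- pairs$mirna_id %in% rownames(expression$values) &
    pairs$target_id %in% rownames(expression$values)
  if (any(!present)) {
    warning(sum(!present), " pair(s) dropped: molecule missing from expression")
    pairs <- pairs[present, , drop = FALSE]
  }
  opposite <- (pairs$mirna_dir == "up" & pairs$target_dir == "down") |
    (pairs$mirna_dir == "down" & pairs$target_dir == "up")
  pairs <- pairs[opposite, , drop = FALSE]
  if (!nrow(pairs)) return(cbind(pairs, pcc = numeric(0)))
  pcc <- vapply(seq_len(nrow(pairs)), function(i)
    stats::cor(expression$values[pairs$mirna_id[i], ],
               expression$values[pairs$target_id[i], ]), numeric(1))
  keep <- !is.na(pcc) & pcc <= pcc_cut
  out <- cbind(pairs, pcc = pcc)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
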