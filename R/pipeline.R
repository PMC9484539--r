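# End-to-end orchestration: filter -> DE -> subclass -> origin annotation
# -> targets -> ceRNA network -> GSEA -> survival, with per-stage output
# files, a provenance sidecar, and deterministic reruns.

pipeline_stages <- c("preprocess", "de", "classify", "annotate",
                     "targets", "cerna", "gsea", "survival")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full ncRNA analysis pipeline
#'
#' Executes the enabled stages in dependency order on an in-memory cohort
#' (typically a `synthetic_cohort`, or an equivalent list built from
#' files via the readers in this package). Every stage writes its result
#' table under `outdir`, a `provenance.json` sidecar records the
#' configuration hash, seed and package version, and a rerun with the
#' same inputs and seed is bit-identical.
#'
#' @param cohort A `synthetic_cohort`, or a list with at least `counts`
#'   (raw `ExpressionMatrix`); optional elements `truth_templates`
#'   (signatures for classification) and `survival`.
#' @param outdir Output directory (created if needed).
#' @param thresholds A [cerna_thresholds()] list.
#' @param stages Subset of
#'   `c("preprocess","de","classify","annotate","targets","cerna","gsea","survival")`;
#'   a stage whose prerequisite is disabled raises an error.
#' @param seed Integer seed for resampling stages (NTP, GSEA).
#' @param sequences Named RNA sequences for seed scanning (default: from
#'   [simulate_sequences()] when `cohort` carries a config).
#' @param annotation List with `genes` and `junctions` (default: from
#'   [simulate_annotation()] likewise).
#' @param external_targets miRNA-mRNA table for mRNA candidates (default:
#'   [simulate_target_table()] likewise).
#' @param signatures Template list for [ntp_classify()] (default:
#'   `cohort$truth_templates`).
#' @param gene_sets Named list for [gsea_significance()]; `NULL` skips
#'   set-level GSEA and reports only the correlation ranking.
#' @param gsea_query Feature ID ranked against; default: the first
#'   retained lncRNA (independent of other stage toggles).
#' @return Invisibly, a list with each stage's result and a `files`
#'   vector of everything written.
#' @export
run_pipeline <- function(cohort, outdir, thresholds = cerna_thresholds(),
                         stages = pipeline_stages, seed = 1L,
                         sequences = NULL, annotation = NULL,
                         external_targets = NULL, signatures = NULL,
                         gene_sets = NULL, gsea_query = NULL) {
  stopifnot(is.list(cohort), inherits(cohort$counts, "ExpressionMatrix"))
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  deps <- list(de = "preprocess", classify = "preprocess",
               targets = c("preprocess", "de"),
               cerna = c("preprocess", "de", "targets"),
               gsea = "preprocess", survival = "preprocess")
  for (st in stages) {
    need <- setdiff(deps[[st]], stages)
    if (length(need))
      stop("stage '", st, "' requires disabled stage(s): ",
           paste(need, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  report <- list(files = character())
  emit <- function(df, file) {
    path <- file.path(outdir, file)
    write_tsv(df, path)
    report$files <<- c(report$files, path)
    path
  }
  has_config <- inherits(cohort, "synthetic_cohort")

  if ("preprocess" %in% stages) {
    report$filtered <- run_stage("preprocess", function() {
      f <- filter_expressed(cohort$counts, thresholds$min_count,
                            thresholds$min_sample_frac)
      message(sprintf("preprocess: %d of %d features retained",
                      nrow(f$values), nrow(cohort$counts$values)))
      f
    })
    report$size_factors <- size_factors(report$filtered)
    report$transformed <- transform_counts(report$filtered, report$size_factors)
    emit(data.frame(feature_id = rownames(report$filtered$values),
                    report$filtered$values, check.names = FALSE),
         "filtered_counts.tsv")
    emit(data.frame(sample_id = names(report$size_factors),
                    size_factor = report$size_factors), "size_factors.tsv")
  }

  if ("de" %in% stages) {
    report$de <- run_stage("de", function() {
      res <- nb_wald_test(report$filtered, factors = report$size_factors)
      res <- call_dysregulated(res, thresholds$padj_tumorigenesis, thresholds$fc)
      res$biotype <- report$filtered$feature_meta$biotype
      message(sprintf("de: %d up, %d down of %d features",
                      sum(res$direction == "up"), sum(res$direction == "down"),
                      nrow(res)))
      res
    })
    emit(report$de, "de_results.tsv")
  }

  if ("classify" %in% stages) {
    report$ntp <- run_stage("classify", function() {
      templates <- if (!is.null(signatures)) signatures else cohort$truth_templates
      if (is.null(templates)) stop("no signature templates supplied")
      tumor <- cohort$counts$sample_meta$sample_id[
        cohort$counts$sample_meta$condition == "tumor"]
      sub <- subset_expression(report$transformed, samples = tumor)
      ntp_classify(sub, templates, n_perm = 1000L,
                   fdr_cut = thresholds$fdr_prognosis, seed = seed)
    })
    emit(report$ntp, "ntp_results.tsv")
  }

  if ("annotate" %in% stages) {
    report$origin <- run_stage("annotate", function() {
      if (is.null(annotation)) {
        if (!has_config) stop("no annotation supplied")
        annotation <<- simulate_annotation(cohort$config)
      }
      classify_origin(annotation$junctions, annotation$genes)
    })
    report$alt_circ <- alt_circularization(report$origin)
    emit(report$origin, "origin_calls.tsv")
    emit(report$alt_circ$per_gene, "alt_circularization.tsv")
  }

  if ("targets" %in% stages) {
    report$pairs <- run_stage("targets", function() {
      if (is.null(sequences)) {
        if (!has_config) stop("no sequences supplied")
        sequences <<- simulate_sequences(cohort$config,
                                         cohort$truth_triplets)$sequences
      }
      if (is.null(external_targets) && has_config)
        external_targets <<- simulate_target_table(cohort)
      de <- report$de
      dys <- de[de$direction != "ns", , drop = FALSE]
      mir <- dys$feature_id[dys$biotype == "miRNA"]
      nc <- dys$feature_id[dys$biotype %in% c("lncRNA", "circRNA")]
      sites <- find_seed_sites(sequences[intersect(mir, names(sequences))],
                               sequences[intersect(nc, names(sequences))])
      cand <- build_candidates(
        de[, c("feature_id", "direction", "biotype")], sites,
        external_targets)
      filtered <- filter_pairs(cand, report$transformed,
                               pcc_cut = thresholds$pcc_mirna_target)
      message(sprintf("targets: %d candidate pairs, %d after filters",
                      nrow(cand), nrow(filtered)))
      filtered
    })
    emit(report$pairs, "target_pairs.tsv")
  }

  if ("cerna" %in% stages) {
    report$network <- run_stage("cerna", function() {
      net <- assemble_network(report$pairs, report$transformed,
                              p_cut = thresholds$hypergeom_p,
                              pcc_cut = thresholds$pcc_cerna_mrna,
                              min_shared = thresholds$min_shared_mirnas)
      message(sprintf("cerna: %d edges", nrow(net)))
      net
    })
    dirs <- stats::setNames(report$de$direction, report$de$feature_id)
    p1 <- file.path(outdir, "cerna_network.tsv")
    p2 <- file.path(outdir, "cerna_network.graphml")
    write_network(report$network, p1, "tsv")
    write_network(report$network, p2, "graphml", directions = dirs)
    report$files <- c(report$files, p1, p2)
  }

  if ("gsea" %in% stages) {
    report$gsea <- run_stage("gsea", function() {
      query <- gsea_query
      if (is.null(query)) {
        # default independent of other stage toggles: first retained lncRNA
        lnc <- report$transformed$feature_meta$feature_id[
          report$transformed$feature_meta$biotype == "lncRNA"]
        if (!length(lnc)) stop("no query feature available")
        query <- lnc[1]
      }
      ranked <- correlation_rank(report$transformed, query)
      res <- list(query = query, ranked = ranked)
      if (!is.null(gene_sets))
        res$sets <- gsea_significance(ranked, gene_sets, n_perm = 1000L,
                                      seed = seed)
      res
    })
    emit(report$gsea$ranked, "gsea_ranking.tsv")
    if (!is.null(report$gsea$sets)) {
      flat <- report$gsea$sets
      flat$leading_edge <- vapply(flat$leading_edge, paste, character(1),
                                  collapse = ";")
      emit(flat, "gsea_results.tsv")
    }
  }

  if ("survival" %in% stages) {
    report$prognosis <- run_stage("survival", function() {
      if (is.null(cohort$survival)) stop("cohort has no survival table")
      lnc <- report$transformed$feature_meta$feature_id[
        report$transformed$feature_meta$biotype == "lncRNA"]
      sub <- subset_expression(report$transformed, features = lnc,
                               samples = cohort$survival$sample_id)
      prognostic_screen(sub, cohort$survival,
                        alpha = thresholds$fdr_prognosis)
    })
    emit(report$prognosis, "prognostic_screen.tsv")
  }

  prov <- list(
    package = "cernakit",
    version = as.character(utils::packageVersion("cernakit")),
    seed = seed,
    stages = stages,
    thresholds = unclass(thresholds),
    config_hash = config_hash(if (has_config) cohort$config else cohort))
  prov_path <- file.path(outdir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  report$files <- c(report$files, prov_path)
  invisible(report)
}

# stable content hash of an arbitrary configuration list
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(
    x[order(names(x))][!vapply(x, is.function, logical(1))],
    auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Intersect the two prognostic screens
#'
#' The survival screen (Cox on an expression cohort with follow-up) and
#' the class-based screen (DE between predicted poor and good prognosis
#' groups) each nominate lncRNAs; this reports the features significant
#' in both, with the evidence columns of each side.
#'
#' @param cox_results `data.frame` with `feature_id` and `significant`
#'   (from [prognostic_screen()]).
#' @param class_de `data.frame` with `feature_id` and `direction` (from
#'   [call_dysregulated()] on the poor-vs-good contrast); any direction
#'   other than `"ns"` counts as significant.
#' @return Merged `data.frame`, one row per feature passing both screens.
#' @export
intersect_prognostic <- function(cox_results, class_de) {
  a <- cox_results[cox_results$significant, , drop = FALSE]
  b <- class_de[class_de$direction != "ns", , drop = FALSE]
  out <- merge(a, b, by = "feature_id", suffixes = c("_cox", "_classde"))
  out[order(out$feature_id), , drop = FALSE]
}
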