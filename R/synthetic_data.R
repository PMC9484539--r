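# Synthetic paired tumor/normal cohorts with planted ground truth:
# NB counts with log-normal size factors, planted fold changes, sponge
# (ceRNA) modules driven by a shared latent miRNA-activity factor, signed
# subclass templates, back-splice junctions of known origin, and Weibull
# survival tied to a planted prognostic score.

#' Simulation configuration
#'
#' Defaults emulate a small paired liver-cancer cohort: 8 tumor/normal
#' pairs profiled for mRNA, lncRNA, circRNA and miRNA, a tenth of features
#' dysregulated four-fold, moderate NB overdispersion, and sponge modules
#' in which one lncRNA or circRNA and one mRNA share eight miRNAs.
#'
#' @param n_pairs Number of tumor/normal pairs.
#' @param n_features_by_biotype Named integer vector of feature counts for
#'   `mRNA`, `lncRNA`, `circRNA`, `miRNA`.
#'
#' @details
#' The sponge-module defaults are sized for recoverability under the
#' strict network criteria: with six modules of eight miRNAs the tested
#' miRNA universe holds roughly fifty miRNAs, so a fully recovered module
#' has a hypergeometric tail near `1/choose(48, 8)` (about 3e-9), leaving
#' orders-of-magnitude headroom below the 1e-6 cut even when incidental
#' background seed matches inflate a target's miRNA set by a few entries.
#' The default `sponge_effect = 2` is the high-coupling regime: planted
#' modules carry an expected |log2 fold change| of 4, twice the calling
#' threshold, so module members are decisively dysregulated.
#' @param de_fraction Fraction of each biotype planted as differentially
#'   expressed (tumor mean shifted by `±log2fc_magnitude`).
#' @param log2fc_magnitude Planted absolute log2 fold change.
#' @param nb_dispersion NB dispersion alpha (> 0); `var = mu + alpha*mu^2`.
#' @param n_sponge_triplets Number of sponge modules. Each module is one
#'   sponge (lncRNA or circRNA), one mRNA, and `mirnas_per_sponge` miRNAs
#'   coupled through a per-sample latent factor: sponge and mRNA load
#'   `+sponge_effect`, miRNAs `-sponge_effect` (log2 scale). The latent
#'   factor has mean +1 in tumors, -1 in normals and SD 0.5 within
#'   condition, so a nonzero `sponge_effect` drives both the
#'   within-condition co-expression and opposite-direction dysregulation.
#' @param mirnas_per_sponge miRNAs shared by each module's sponge and mRNA.
#' @param sponge_effect Latent-factor loading (log2 units per latent SD).
#' @param subclass_sizes Named integer vector of tumor counts per subclass
#'   label; must sum to `n_pairs`.
#' @param subclass_shift Log2 shift applied to a class's signature genes in
#'   that class's tumors.
#' @param n_signature_genes Total signature genes, split evenly over
#'   classes, signs drawn ±1.
#' @param n_prognostic Number of lncRNAs carrying the prognostic score.
#' @param prognostic_loading Log2 loading of the score on those lncRNAs.
#' @param survival_baseline_scale Weibull scale of baseline survival
#'   (arbitrary time units, months by convention).
#' @param survival_shape Weibull shape.
#' @param survival_effect Log hazard per unit prognostic score.
#' @param censor_rate Probability a tumor sample is censored (censoring
#'   time drawn uniformly before the event).
#' @param origin_props Named proportions for junction origins
#'   (`exonic`, `intergenic`, `intronic`).
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   cohorts.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_pairs = 8L,
    n_features_by_biotype = c(mRNA = 1500L, lncRNA = 400L,
                              circRNA = 150L, miRNA = 120L),
    de_fraction = 0.1,
    log2fc_magnitude = 2,
    nb_dispersion = 0.1,
    n_sponge_triplets = 6L,
    mirnas_per_sponge = 8L,
    sponge_effect = 2,
    subclass_sizes = c(S1 = 3L, S2 = 3L, S3 = 2L),
    subclass_shift = 2,
    n_signature_genes = 60L,
    n_prognostic = 10L,
    prognostic_loading = 1.5,
    survival_baseline_scale = 60,
    survival_shape = 1.5,
    survival_effect = 0.7,
    censor_rate = 0.3,
    origin_props = c(exonic = 0.8582, intergenic = 0.07, intronic = 0.0718),
    seed = 1L) {
  stopifnot(n_pairs >= 1, all(n_features_by_biotype >= 0),
            de_fraction >= 0, de_fraction <= 1,
            nb_dispersion > 0, n_sponge_triplets >= 0,
            mirnas_per_sponge >= 1, censor_rate >= 0, censor_rate <= 1,
            survival_baseline_scale > 0, survival_shape > 0,
            all(origin_props >= 0), sum(origin_props) > 0)
  req <- c("mRNA", "lncRNA", "circRNA", "miRNA")
  if (!all(req %in% names(n_features_by_biotype)))
    stop("n_features_by_biotype needs entries: ", paste(req, collapse = ", "))
  if (sum(subclass_sizes) != n_pairs)
    stop("subclass_sizes must sum to n_pairs")
  n_sponges <- n_sponge_triplets
  if (n_sponges * mirnas_per_sponge > n_features_by_biotype[["miRNA"]])
    stop("not enough miRNA features for the requested sponge modules")
  if (n_sponges > n_features_by_biotype[["lncRNA"]] + n_features_by_biotype[["circRNA"]] ||
      n_sponges + n_signature_genes > n_features_by_biotype[["mRNA"]])
    stop("not enough features for the requested sponge modules")
  structure(as.list(environment())[setdiff(ls(), c("req", "n_sponges"))],
            class = "simulation_config")
}

feature_ids <- function(biotype, n)
  sprintf("%s_%04d", biotype, seq_len(n))

#' Simulate a paired tumor/normal cohort with planted ground truth
#'
#' Counts are NB with per-sample size factors drawn log-normal(0, 0.2).
#' Planted structure: four-way fold changes, sponge modules with the sign
#' pattern ceRNA inference assumes (miRNA anti-correlated with both sponge
#' and target, sponge-target positively correlated), signed subclass
#' templates, and Weibull survival whose log hazard is linear in a
#' standard-normal per-tumor prognostic score.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort`:
#'   \describe{
#'     \item{counts}{raw-count [ExpressionMatrix()]}
#'     \item{truth_de}{`data.frame(feature_id, direction)` of planted DE}
#'     \item{truth_triplets}{`data.frame(sponge, mirna, mrna)`, one row per
#'       planted sponge-miRNA-mRNA triplet}
#'     \item{truth_subclass}{named vector, tumor sample -> class label}
#'     \item{truth_prognostic}{lncRNA IDs carrying the prognostic score}
#'     \item{survival}{`data.frame(sample_id, time, event, score)` for
#'       tumor samples}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nfb <- config$n_features_by_biotype
  n_pairs <- config$n_pairs
  samples <- data.frame(
    sample_id = c(sprintf("P%02d_T", seq_len(n_pairs)),
                  sprintf("P%02d_N", seq_len(n_pairs))),
    condition = rep(c("tumor", "normal"), each = n_pairs),
    pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2L))
  n_samp <- nrow(samples)
  is_tumor <- samples$condition == "tumor"

  feats <- data.frame(
    feature_id = unlist(lapply(names(nfb), function(b) feature_ids(b, nfb[[b]]))),
    biotype = rep(names(nfb), times = unlist(nfb)))
  n_feat <- nrow(feats)

  # baseline log2 means and library size factors
  base_log2 <- stats::runif(n_feat, log2(20), log2(2000))
  sf <- exp(stats::rnorm(n_samp, 0, 0.2))
  log2mu <- matrix(base_log2, n_feat, n_samp,
                   dimnames = list(feats$feature_id, samples$sample_id))

  # ordinary planted DE (disjoint from sponge modules, assigned below)
  truth_de <- data.frame(feature_id = character(), direction = character())
  module <- list(sponges = character(), mrnas = character(), mirnas = character())
  if (config$n_sponge_triplets > 0) {
    nc_pool <- c(feature_ids("lncRNA", nfb[["lncRNA"]]),
                 feature_ids("circRNA", nfb[["circRNA"]]))
    # alternate lncRNA / circRNA sponges
    lnc <- feature_ids("lncRNA", nfb[["lncRNA"]])
    circ <- feature_ids("circRNA", nfb[["circRNA"]])
    sponges <- character(config$n_sponge_triplets)
    li <- ci <- 1L
    for (i in seq_len(config$n_sponge_triplets)) {
      if (i %% 2L == 1L && li <= length(lnc)) { sponges[i] <- lnc[li]; li <- li + 1L }
      else { sponges[i] <- circ[ci]; ci <- ci + 1L }
    }
    module$sponges <- sponges
    module$mrnas <- feature_ids("mRNA", nfb[["mRNA"]])[seq_len(config$n_sponge_triplets)]
    module$mirnas <- feature_ids("miRNA", nfb[["miRNA"]])[
      seq_len(config$n_sponge_triplets * config$mirnas_per_sponge)]
  }
  reserved <- unlist(module)

  if (config$de_fraction > 0) {
    for (b in names(nfb)) {
      pool <- setdiff(feats$feature_id[feats$biotype == b], reserved)
      n_de <- round(config$de_fraction * nfb[[b]])
      n_de <- min(n_de, length(pool))
      if (n_de == 0) next
      chosen <- sample(pool, n_de)
      dirs <- sample(c("up", "down"), n_de, replace = TRUE)
      shift <- ifelse(dirs == "up", 1, -1) * config$log2fc_magnitude
      log2mu[chosen, is_tumor] <- log2mu[chosen, is_tumor] + shift
      truth_de <- rbind(truth_de, data.frame(feature_id = chosen, direction = dirs))
    }
  }

  # sponge modules: shared latent factor with condition-dependent mean
  truth_triplets <- data.frame(sponge = character(), mirna = character(),
                               mrna = character())
  if (config$n_sponge_triplets > 0) {
    mpm <- config$mirnas_per_sponge
    for (i in seq_len(config$n_sponge_triplets)) {
      # condition gap 2 with within-condition SD 0.5: the member-level
      # two-group signal stays decisive (z ~ 2 / (0.5 * sqrt(2/n_pairs)))
      # while within-condition sponge/miRNA coupling still dominates
      # count noise
      L <- stats::rnorm(n_samp, mean = ifelse(is_tumor, 1, -1), sd = 0.5)
      mir_i <- module$mirnas[((i - 1L) * mpm + 1L):(i * mpm)]
      up <- c(module$sponges[i], module$mrnas[i])
      log2mu[up, ] <- sweep(log2mu[up, , drop = FALSE], 2L,
                            config$sponge_effect * L, `+`)
      log2mu[mir_i, ] <- sweep(log2mu[mir_i, , drop = FALSE], 2L,
                               config$sponge_effect * L, `-`)
      truth_triplets <- rbind(truth_triplets, data.frame(
        sponge = module$sponges[i], mirna = mir_i, mrna = module$mrnas[i]))
      if (config$sponge_effect != 0)
        truth_de <- rbind(truth_de, data.frame(
          feature_id = c(up, mir_i),
          direction = c("up", "up", rep("down", length(mir_i)))))
    }
  }

  # subclass templates on mRNA signature genes
  classes <- rep(names(config$subclass_sizes), times = config$subclass_sizes)
  truth_subclass <- stats::setNames(classes, samples$sample_id[is_tumor])
  n_cls <- length(config$subclass_sizes)
  sig_per_cls <- config$n_signature_genes %/% n_cls
  sig_pool <- setdiff(feature_ids("mRNA", nfb[["mRNA"]]), reserved)
  templates <- list()
  used <- 0L
  for (cl in if (sig_per_cls > 0L) names(config$subclass_sizes) else character()) {
    genes <- sig_pool[(used + 1L):(used + sig_per_cls)]
    used <- used + sig_per_cls
    signs <- sample(c(1L, -1L), sig_per_cls, replace = TRUE)
    templates[[cl]] <- data.frame(gene_id = genes, sign = signs)
    in_cls <- samples$sample_id %in% names(truth_subclass)[truth_subclass == cl]
    log2mu[genes, in_cls] <- log2mu[genes, in_cls] +
      config$subclass_shift * signs
  }

  # prognostic score on lncRNAs, survival for tumor samples
  lnc_pool <- setdiff(feature_ids("lncRNA", nfb[["lncRNA"]]), reserved)
  n_prog <- min(config$n_prognostic, length(lnc_pool))
  prog <- utils::tail(lnc_pool, n_prog)
  score <- stats::rnorm(n_pairs)
  log2mu[prog, is_tumor] <- log2mu[prog, is_tumor] +
    config$prognostic_loading * rep(score, each = n_prog)
  u <- stats::runif(n_pairs)
  t_event <- config$survival_baseline_scale *
    (-log(u) * exp(-config$survival_effect * score))^(1 / config$survival_shape)
  censored <- stats::runif(n_pairs) < config$censor_rate
  time <- ifelse(censored, t_event * stats::runif(n_pairs), t_event)
  survival <- data.frame(sample_id = samples$sample_id[is_tumor],
                         time = time, event = as.integer(!censored),
                         score = score)

  mu <- 2^log2mu * rep(sf, each = n_feat)
  counts <- matrix(
    stats::rnbinom(n_feat * n_samp, mu = mu, size = 1 / config$nb_dispersion),
    n_feat, n_samp, dimnames = dimnames(log2mu))

  truth_de <- truth_de[!duplicated(truth_de$feature_id), , drop = FALSE]
  rownames(truth_de) <- NULL
  structure(list(
    counts = ExpressionMatrix(counts, feats, samples),
    truth_de = truth_de,
    truth_triplets = truth_triplets,
    truth_subclass = truth_subclass,
    truth_templates = templates,
    truth_prognostic = prog,
    truth_size_factors = stats::setNames(sf, samples$sample_id),
    survival = survival,
    config = config), class = "synthetic_cohort")
}

#' Synthetic external miRNA-mRNA interaction table
#'
#' Builds a validated-style interaction table covering every planted
#' (miRNA, mRNA) pair of the cohort's sponge modules plus random decoy
#' rows among non-module molecules, emulating a curated database input.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_decoys Random non-module rows to add.
#' @return `data.frame(mirna_id, target_id, evidence, source)`.
#' @export
simulate_target_table <- function(cohort, n_decoys = 50L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  set.seed(cohort$config$seed + 3L)
  tri <- cohort$truth_triplets
  rows <- data.frame(mirna_id = tri$mirna, target_id = tri$mrna)
  nfb <- cohort$config$n_features_by_biotype
  if (n_decoys > 0) {
    mir_pool <- setdiff(feature_ids("miRNA", nfb[["miRNA"]]), tri$mirna)
    mrna_pool <- setdiff(feature_ids("mRNA", nfb[["mRNA"]]), tri$mrna)
    rows <- rbind(rows, data.frame(
      mirna_id = sample(mir_pool, n_decoys, replace = TRUE),
      target_id = sample(mrna_pool, n_decoys, replace = TRUE)))
  }
  rows <- rows[!duplicated(rows), , drop = FALSE]
  rownames(rows) <- NULL
  data.frame(rows, evidence = "validated", source = "synthetic_db")
}

random_rna <- function(n_bases)
  paste(sample(c("A", "C", "G", "U"), n_bases, replace = TRUE), collapse = "")

#' Simulate miRNA/target sequences with planted seed sites
#'
#' Generates random-background RNA sequences for every miRNA, lncRNA,
#' circRNA and mRNA of the cohort. For each planted sponge triplet the
#' sponge and mRNA sequences receive at least one exact 7mer-m8 site
#' (the reverse complement of the triplet miRNA's positions 2-8).
#'
#' @param config A [simulation_config()].
#' @param triplets `truth_triplets` table from [simulate_cohort()].
#' @param target_length Length of non-miRNA sequences (bases).
#' @param mirna_length Length of mature miRNAs (bases).
#' @return A list with `sequences` (named character vector, RNA 5'->3')
#'   and `truth_sites` (`data.frame(target_id, mirna_id, position)` of
#'   planted 7mer-m8 site starts, 1-based).
#' @export
simulate_sequences <- function(config, triplets, target_length = 500L,
                               mirna_length = 22L) {
  stopifnot(inherits(config, "simulation_config"))
  if (target_length < 7L) stop("target_length shorter than a seed site")
  set.seed(config$seed + 1L)
  nfb <- config$n_features_by_biotype
  mirna_ids <- feature_ids("miRNA", nfb[["miRNA"]])
  target_ids <- c(feature_ids("lncRNA", nfb[["lncRNA"]]),
                  feature_ids("circRNA", nfb[["circRNA"]]),
                  feature_ids("mRNA", nfb[["mRNA"]]))
  seqs <- c(
    stats::setNames(vapply(mirna_ids, function(i) random_rna(mirna_length),
                           character(1)), mirna_ids),
    stats::setNames(vapply(target_ids, function(i) random_rna(target_length),
                           character(1)), target_ids))
  truth_sites <- data.frame(target_id = character(), mirna_id = character(),
                            position = integer())
  if (nrow(triplets)) {
    bad <- setdiff(triplets$mirna, mirna_ids)
    if (length(bad)) stop("unknown miRNA in triplets: ", bad[1])
    occupied <- list()  # per target: starts already planted
    for (i in seq_len(nrow(triplets))) {
      site <- seed_site_sequence(seqs[[triplets$mirna[i]]])
      w <- nchar(site)
      for (tid in c(triplets$sponge[i], triplets$mrna[i])) {
        # plant at a position not overlapping an earlier planted site, so
        # every truth site survives in the final sequence
        used <- occupied[[tid]]
        free <- seq_len(target_length - w + 1L)
        if (length(used))
          free <- free[vapply(free, function(p)
            all(abs(p - used) >= w), logical(1))]
        if (!length(free))
          stop("no room left to plant a site in ", tid)
        pos <- if (length(free) == 1L) free else sample(free, 1L)
        s <- seqs[[tid]]
        substr(s, pos, pos + w - 1L) <- site
        seqs[[tid]] <- s
        occupied[[tid]] <- c(used, pos)
        truth_sites <- rbind(truth_sites, data.frame(
          target_id = tid, mirna_id = triplets$mirna[i], position = pos))
      }
    }
  }
  list(sequences = seqs, truth_sites = truth_sites)
}

#' Simulate gene models and back-splice junctions with known origin
#'
#' Lays non-overlapping multi-exon genes along one synthetic chromosome
#' and draws one junction per circRNA feature from three classes:
#' both breakpoints on exon boundaries of one gene (exonic), strictly
#' inside one intron (intronic), or overlapping no gene (intergenic).
#' Exonic and intronic junctions are assigned host genes with replacement,
#' so a configurable share of genes yields multiple circRNA isoforms.
#'
#' @param config A [simulation_config()]; `origin_props` sets the class
#'   mix and the circRNA feature count sets the junction count.
#' @param exons_per_gene Exons per gene.
#' @param exon_length,intron_length,gene_gap Layout in bases.
#' @return A list with `genes` (a [gene_models()] table), `junctions`
#'   (a `circ_junctions` table), and `truth_origin` (named vector,
#'   circ_id -> origin label).
#' @export
simulate_annotation <- function(config, exons_per_gene = 4L,
                                exon_length = 200L, intron_length = 400L,
                                gene_gap = 10000L) {
  stopifnot(inherits(config, "simulation_config"), exons_per_gene >= 2L)
  set.seed(config$seed + 2L)
  n_junc <- config$n_features_by_biotype[["circRNA"]]
  props <- config$origin_props / sum(config$origin_props)
  n_ex <- round(props[["exonic"]] * n_junc)
  n_in <- round(props[["intronic"]] * n_junc)
  n_ig <- n_junc - n_ex - n_in

  # gene pool sized so host draws recur at rate ~Poisson(1.35): roughly
  # half of the genes that host any circRNA produce >= 2 isoforms
  n_genes <- max(4L, ceiling((n_ex + n_in) / 1.35))
  gene_len <- exons_per_gene * exon_length + (exons_per_gene - 1L) * intron_length
  gene_start <- gene_gap + (seq_len(n_genes) - 1L) * (gene_len + gene_gap)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    starts <- gene_start[g] + (seq_len(exons_per_gene) - 1L) *
      (exon_length + intron_length)
    data.frame(gene_id = sprintf("gene_%03d", g), chrom = "chrS",
               strand = if (g %% 2L == 0L) "-" else "+",
               start = starts, end = starts + exon_length - 1L,
               biotype = "protein_coding")
  }))
  genes <- gene_models(exons)

  circ_ids <- feature_ids("circRNA", n_junc)
  labels <- c(rep("exonic", n_ex), rep("intronic", n_in), rep("intergenic", n_ig))
  junc <- vector("list", n_junc)
  hosts <- sample.int(n_genes, n_ex + n_in, replace = TRUE)
  for (i in seq_len(n_junc)) {
    if (labels[i] == "exonic") {
      g <- genes[genes$gene_id == sprintf("gene_%03d", hosts[i]), ]
      pick <- sort(sample.int(nrow(g), 2L))  # may be the same exon pair twice
      junc[[i]] <- data.frame(circ_id = circ_ids[i], chrom = "chrS",
                              start = g$start[pick[1]], end = g$end[pick[2]],
                              strand = g$strand[1], read_support = 1L + stats::rpois(1, 20))
    } else if (labels[i] == "intronic") {
      g <- genes[genes$gene_id == sprintf("gene_%03d", hosts[i]), ]
      k <- sample.int(nrow(g) - 1L, 1L)
      istart <- g$end[k] + 1L
      iend <- g$start[k + 1L] - 1L
      junc[[i]] <- data.frame(circ_id = circ_ids[i], chrom = "chrS",
                              start = istart + 5L, end = iend - 5L,
                              strand = g$strand[1], read_support = 1L + stats::rpois(1, 10))
    } else {
      gap <- sample.int(n_genes + 1L, 1L)
      left <- if (gap == 1L) 1L else gene_start[gap - 1L] + gene_len
      junc[[i]] <- data.frame(circ_id = circ_ids[i], chrom = "chrS",
                              start = left + 100L, end = left + 100L + 300L,
                              strand = sample(c("+", "-"), 1L),
                              read_support = 1L + stats::rpois(1, 5))
    }
  }
  junctions <- do.call(rbind, junc)
  class(junctions) <- c("circ_junctions", "data.frame")
  list(genes = genes, junctions = junctions,
       truth_origin = stats::setNames(labels, circ_ids))
}
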