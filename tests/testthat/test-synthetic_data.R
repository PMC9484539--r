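test_that("identical config and seed give bit-identical cohorts", {
  cfg <- small_config(seed = 9L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$survival, b$survival)
  expect_identical(simulate_sequences(cfg, a$truth_triplets),
                   simulate_sequences(cfg, b$truth_triplets))
})

test_that("no planted effects means empty DE truth and near-zero sponge correlations", {
  cfg <- small_config(seed = 2L, de_fraction = 0, n_sponge_triplets = 0L)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$truth_de), 0L)

  # sponge_effect = 0: module members stay uncorrelated and undysregulated
  cors <- vapply(1:25, function(s) {
    cfg0 <- small_config(seed = 100L + s, de_fraction = 0, sponge_effect = 0,
                         subclass_shift = 0, prognostic_loading = 0)
    coh0 <- simulate_cohort(cfg0)
    tri <- coh0$truth_triplets
    expect_equal(nrow(coh0$truth_de), 0L)
    tr <- transform_counts(coh0$counts)
    mean(vapply(seq_len(nrow(tri)), function(i)
      stats::cor(tr$values[tri$mirna[i], ], tr$values[tri$mrna[i], ]),
      numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("null counts match NB mean-variance moments", {
  # one large null cohort: per-feature MoM dispersion of normalized counts
  # should concentrate around the configured alpha
  cfg <- small_config(
    seed = 31L, n_pairs = 300L, de_fraction = 0, n_sponge_triplets = 0L,
    subclass_sizes = c(S1 = 300L), subclass_shift = 0,
    n_signature_genes = 0L, prognostic_loading = 0,
    n_features_by_biotype = c(mRNA = 150L, lncRNA = 20L,
                              circRNA = 10L, miRNA = 10L))
  coh <- simulate_cohort(cfg)
  norm <- sweep(coh$counts$values, 2L, coh$truth_size_factors, `/`)
  m <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  alpha_hat <- (v - m) / m^2
  expect_lt(abs(median(alpha_hat) - 0.1), 0.02)
})

test_that("downstream detection power increases with planted fold change", {
  power_at <- function(lfc) {
    cfg <- small_config(seed = 77L, log2fc_magnitude = lfc,
                        n_sponge_triplets = 0L)
    coh <- simulate_cohort(cfg)
    de <- call_dysregulated(nb_wald_test(filter_expressed(coh$counts)),
                            padj_cut = 0.1, fc_cut = 2)
    called <- de$feature_id[de$direction != "ns"]
    mean(coh$truth_de$feature_id %in% called)
  }
  p_weak <- power_at(1)
  p_strong <- power_at(3)
  expect_gt(p_strong, p_weak)
  expect_gt(p_strong, 0.8)
})

test_that("sequence simulation plants rediscoverable 7mer-m8 sites", {
  cfg <- small_config(seed = 6L)
  coh <- simulate_cohort(cfg)
  sq <- simulate_sequences(cfg, coh$truth_triplets)

  # hand-derived site for the canonical let-7a sequence
  expect_equal(seed_site_sequence("UGAGGUAGUAGGUUGUAUAGUU"), "CUACCUC")

  # every planted site is present verbatim at its recorded position
  for (i in seq_len(nrow(sq$truth_sites))) {
    row <- sq$truth_sites[i, ]
    site <- seed_site_sequence(sq$sequences[[row$mirna_id]])
    expect_equal(substr(sq$sequences[[row$target_id]], row$position,
                        row$position + nchar(site) - 1L), site)
  }

  # cross-module oracle: the strict seed matcher rediscovers every site
  for (i in seq_len(nrow(sq$truth_sites))) {
    row <- sq$truth_sites[i, ]
    hits <- seed_sites(sq$sequences[[row$mirna_id]],
                       sq$sequences[[row$target_id]])
    expect_true(row$position %in% hits$position)
  }

  # zero triplets -> background only
  sq0 <- simulate_sequences(cfg, coh$truth_triplets[0, ])
  expect_equal(nrow(sq0$truth_sites), 0L)
})

test_that("annotation simulation yields the configured origin mix and valid models", {
  cfg_all_ex <- small_config(seed = 4L, origin_props = c(
    exonic = 1, intergenic = 0, intronic = 0))
  ann <- simulate_annotation(cfg_all_ex)
  expect_true(all(ann$truth_origin == "exonic"))

  cfg <- small_config(seed = 4L)
  ann2 <- simulate_annotation(cfg)
  expect_equal(length(ann2$truth_origin), 60L)
  tab <- table(ann2$truth_origin)
  expect_gt(tab[["exonic"]], tab[["intronic"]])
  expect_true(all(ann2$junctions$start < ann2$junctions$end))
  # classification of the truth set reproduces every label (exhaustive
  # check lives with the annotation acceptance test)
  calls <- classify_origin(ann2$junctions, ann2$genes)
  expect_equal(unname(ann2$truth_origin[calls$circ_id]), calls$origin)
})

test_that("sizing violations are rejected", {
  expect_error(small_config(n_sponge_triplets = 20L, mirnas_per_sponge = 8L),
               "miRNA features")
  expect_error(small_config(subclass_sizes = c(S1 = 2L)), "sum to n_pairs")
})

test_that("survival truth has positive times and approximately the censor rate", {
  cfg <- small_config(seed = 13L, n_pairs = 200L,
                      subclass_sizes = c(S1 = 200L), censor_rate = 0.3)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$survival$time > 0))
  expect_lt(abs(mean(coh$survival$event == 0) - 0.3), 0.1)
})
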