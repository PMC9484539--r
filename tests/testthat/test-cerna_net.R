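# brute-force enumeration oracle for P(X >= k): walk the whole support
oracle_hyper_tail <- function(k, K, n, N) {
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  probs <- vapply(lo:hi, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1))
  sum(probs[(lo:hi) >= k])
}

test_that("hypergeometric tail matches enumeration, including the worked case", {
  expect_equal(hypergeom_tail(3, 4, 5, 10), 66 / 252)
  expect_equal(oracle_hyper_tail(3, 4, 5, 10), 66 / 252)
  expect_equal(hypergeom_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_tail(6, 6, 6, 6), 1)  # forced complete overlap
  expect_error(hypergeom_tail(5, 4, 5, 10), "k <= min")
  expect_error(hypergeom_tail(1, 4, 11, 10), "N")
})

test_that("network assembly applies all three strict criteria", {
  # ceRNA C1 shares m1..m5 with M1; expression engineered for known PCC
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  z <- c(1, -1, 1, -1, 1, -1, 1, -1)
  vals <- rbind(C1 = x, M1 = x,                        # pcc exactly 1
                M2 = vector_with_cor(x, z, 0.5),       # pcc 0.5 -> fails
                matrix(0, 6, 8, dimnames = list(paste0("m", 1:6), NULL)))
  colnames(vals) <- sprintf("s%d", 1:8)
  expr <- toy_matrix(vals + 10, transformed = TRUE)

  mk_pairs <- function(mirnas, target, class)
    data.frame(mirna_id = mirnas, target_id = target, target_class = class,
               evidence = "seed", mirna_dir = "down", target_dir = "up",
               pcc = -0.9)
  universe <- sprintf("u%02d", 1:44)  # large enough for p < 1e-6 at k = 5

  pairs5 <- rbind(mk_pairs(paste0("m", 1:5), "C1", "lncRNA"),
                  mk_pairs(paste0("m", 1:5), "M1", "mRNA"))
  net5 <- assemble_network(pairs5, expr, universe = universe)
  expect_equal(nrow(net5), 1L)
  expect_equal(net5$k, 5L)
  expect_equal(net5$shared_mirnas[[1]], paste0("m", 1:5))
  expect_equal(net5$p_hyper, 1 / choose(44, 5))
  expect_equal(net5$pcc, 1)

  # k = 4 shared: rejected by the strict > 4 rule
  pairs4 <- rbind(mk_pairs(paste0("m", 1:4), "C1", "lncRNA"),
                  mk_pairs(paste0("m", 1:4), "M1", "mRNA"))
  expect_equal(nrow(assemble_network(pairs4, expr, universe = universe)), 0L)

  # PCC 0.5: rejected by the strict > 0.6 rule despite k = 5, tiny p
  pairsM2 <- rbind(mk_pairs(paste0("m", 1:5), "C1", "lncRNA"),
                   mk_pairs(paste0("m", 1:5), "M2", "mRNA"))
  expect_equal(nrow(assemble_network(pairsM2, expr, universe = universe)), 0L)

  # small universe: p above 1e-6 rejects even a perfect overlap
  expect_equal(nrow(assemble_network(pairs5, expr,
                                     universe = sprintf("u%02d", 1:10))), 0L)

  # assembly is invariant to input pair order
  shuffled <- pairs5[sample.int(nrow(pairs5)), ]
  net_shuf <- assemble_network(shuffled, expr, universe = universe)
  expect_equal(net_shuf, net5)

  expect_equal(nrow(assemble_network(pairs5[0, ], expr)), 0L)
})

test_that("cis pair reporting gates on correlation and distance", {
  x <- c(1, 2, 3, 4, 5, 6)
  z <- c(1, -1, -1, 1, 1, -1)
  vals <- rbind(AS1 = x, near = x,                      # pcc 1
                mid = vector_with_cor(x, z, 0.75),      # pcc 0.75 -> out
                far = x)
  colnames(vals) <- sprintf("s%d", 1:6)
  expr <- toy_matrix(vals + 10, transformed = TRUE)
  genes <- gene_models(data.frame(
    gene_id = c("near", "mid", "far"), chrom = "chr1",
    strand = c("-", "-", "-"),
    start = c(1200L, 1500L, 60000L), end = c(1400L, 1900L, 61000L),
    biotype = "protein_coding"))
  coords <- data.frame(feature_id = "AS1", chrom = "chr1",
                       start = 1000L, end = 1250L)
  res <- cis_pairs(expr, coords, genes, pcc_cut = 0.8, max_distance = 10000L)
  expect_equal(res$gene_id, "near")
  expect_equal(res$pcc, 1)
  # "mid" is within distance but r = 0.75 < 0.8; "far" is 58 kb away
  expect_false("mid" %in% res$gene_id)
  expect_false("far" %in% res$gene_id)
})
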