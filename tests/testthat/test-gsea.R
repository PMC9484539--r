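# independent running-sum oracle, written as an explicit loop; returns
# both extremes so a machine-precision tie between the positive and
# negative deviation accepts either signed value
oracle_es_range <- function(scores, hit, p = 1) {
  n <- length(scores)
  nr <- sum(abs(scores[hit])^p)
  run <- 0; hi <- 0; lo <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(scores[i])^p / nr else -1 / (n - sum(hit))
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  c(hi = hi, lo = lo)
}
matches_oracle <- function(got, rng) {
  expected <- if (abs(rng["hi"]) >= abs(rng["lo"])) rng[["hi"]] else rng[["lo"]]
  isTRUE(all.equal(got, expected, tolerance = 1e-9)) ||
    (abs(abs(rng["hi"]) - abs(rng["lo"])) < 1e-9 &&
       isTRUE(all.equal(abs(got), abs(rng[["hi"]]), tolerance = 1e-9)))
}

ranked_df <- function(scores, ids = sprintf("g%03d", seq_along(scores))) {
  structure(data.frame(gene_id = ids, score = scores),
            class = c("ranked_list", "data.frame"))
}

test_that("the enrichment score reproduces the hand-walked fixture", {
  ranked <- ranked_df(c(3, 2, 1, 0.5), c("g1", "g2", "g3", "g4"))
  res <- enrichment_score(ranked, c("g1", "g3"))
  # hits contribute 3/4 then 1/4; misses -1/2: running 0.75, 0.25, 0.5, 0
  expect_equal(res$es, 0.75)
  expect_equal(res$running, c(0.75, 0.25, 0.5, 0))
  expect_equal(res$leading_edge, "g1")

  # single-gene set at rank 1: full hit mass before any miss
  expect_equal(enrichment_score(ranked, "g1")$es, 1)
  # set concentrated at the bottom scores negative
  expect_lt(enrichment_score(ranked, c("g3", "g4"))$es, 0)

  expect_error(enrichment_score(ranked, "absent"), "no gene")
  expect_error(enrichment_score(ranked, paste0("g", 1:4)), "entire")
})

test_that("the enrichment score matches the brute-force oracle on random instances", {
  set.seed(5)
  for (r in 1:120) {
    n <- sample(10:60, 1)
    scores <- sort(runif(n, -1, 1), decreasing = TRUE)
    ids <- sprintf("g%03d", 1:n)
    members <- sample(ids, sample(2:(n - 1), 1))
    got <- enrichment_score(ranked_df(scores, ids), members)$es
    expect_true(matches_oracle(got, oracle_es_range(scores, ids %in% members)),
                info = paste("rep", r))
  }
})

test_that("correlation ranking orders by PCC with deterministic tie-breaks", {
  x <- c(1, 2, 3, 4, 5, 6)
  vals <- rbind(query = x, twin = 2 * x + 1, anti = -x,
                noise = c(2, 1, 4, 3, 6, 5))
  colnames(vals) <- sprintf("s%d", 1:6)
  expr <- toy_matrix(vals + 10, transformed = TRUE)
  rk <- correlation_rank(expr, "query")
  expect_equal(rk$gene_id[1], "twin")
  expect_equal(rk$score[1], 1)
  expect_equal(rk$gene_id[nrow(rk)], "anti")
  expect_equal(rk$score[nrow(rk)], -1)

  # scores invariant to affine transform of the query
  expr2 <- expr
  expr2$values["query", ] <- 5 * expr2$values["query", ] - 2
  expect_equal(correlation_rank(expr2, "query"), rk)

  flat <- expr
  flat$values["query", ] <- 1
  expect_error(correlation_rank(flat, "query"), "zero variance")
})

test_that("permutation significance is minimal for a top-k set and deterministic", {
  set.seed(9)
  scores <- sort(runif(200, -1, 1), decreasing = TRUE)
  ranked <- ranked_df(scores)
  top <- ranked$gene_id[1:10]
  res <- gsea_significance(ranked, list(top_set = top), n_perm = 199L,
                           seed = 11L)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$nes, 1)
  expect_equal(sign(res$nes), sign(res$es))

  res2 <- gsea_significance(ranked, list(top_set = top), n_perm = 199L,
                            seed = 11L)
  expect_identical(res[c("es", "nes", "p", "fdr")],
                   res2[c("es", "nes", "p", "fdr")])

  expect_warning(
    out <- gsea_significance(ranked, list(tiny = ranked$gene_id[1:2]),
                             n_perm = 100L, seed = 1L),
    "skipped")
  expect_equal(nrow(out), 0L)
})
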