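# independent sliding-window oracle: compare every target window to the
# reverse complement of miRNA positions 2..8 built with a lookup table
oracle_m8_sites <- function(mirna, target) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seed <- strsplit(substr(mirna, 2, 8), "")[[1]]
  site <- paste(rev(unname(comp[seed])), collapse = "")
  hits <- integer(0)
  if (nchar(target) >= 7)
    for (p in 1:(nchar(target) - 6))
      if (substr(target, p, p + 6) == site) hits <- c(hits, p)
  hits
}

test_that("strict seed scan finds the hand-derived let-7 site", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
  target <- paste0("GGGG", "CUACCUC", "GGGG")
  s <- seed_sites(let7, target)
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 5L)
  expect_equal(s$site_type, "7mer-m8")

  # full reverse complement of the miRNA contains the site at the
  # seed-complement offset (positions 15..21 of the 22-nt revcomp)
  full_rc <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(let7)))
  s2 <- seed_sites(let7, full_rc)
  expect_true(15L %in% s2$position)

  expect_equal(nrow(seed_sites(let7, "AAAAAAAAAAAAAAAA")), 0L)
  expect_error(seed_sites(let7, "ACGT"), "non-RNA")
  expect_error(seed_sites("ACGU", "ACGU"), "18 bases")
})

test_that("site types classify by m8 pairing and the A1 anchor", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
  # 6mer core = revcomp(GAGGUA) = UACCUC; m8 adds C upstream; A1 adds A downstream
  core <- "UACCUC"
  all_types <- function(target) seed_sites(let7, target, strict = FALSE)
  expect_equal(all_types(paste0("GG", core, "GG"))$site_type, "6mer")
  expect_equal(all_types(paste0("GG", core, "AGG"))$site_type, "7mer-A1")
  expect_equal(all_types(paste0("GC", core, "GG"))$site_type, "7mer-m8")
  expect_equal(all_types(paste0("GC", core, "AGG"))$site_type, "8mer")
  # strict mode drops the 6mer and 7mer-A1 variants
  expect_equal(nrow(seed_sites(let7, paste0("GG", core, "AGG"))), 0L)
  expect_equal(seed_sites(let7, paste0("GC", core, "AGG"))$site_type, "8mer")
})

test_that("strict scan agrees with the sliding-window oracle on random pairs", {
  set.seed(8)
  bases <- c("A", "C", "G", "U")
  for (r in 1:100) {
    mirna <- paste(sample(bases, 21, replace = TRUE), collapse = "")
    target <- paste(sample(bases, 80, replace = TRUE), collapse = "")
    got <- seed_sites(mirna, target)
    expect_identical(got$position, oracle_m8_sites(mirna, target),
                     info = paste("rep", r))
  }
})

test_that("candidate assembly joins seed sites, external tables, and DE calls", {
  de <- data.frame(
    feature_id = c("m1", "m2", "lnc1", "g1"),
    direction = c("down", "up", "up", "up"),
    biotype = c("miRNA", "miRNA", "lncRNA", "mRNA"))
  expect_equal(nrow(build_candidates(de)), 0L)

  sites <- data.frame(mirna_id = "m1", target_id = "lnc1",
                      position = 5L, site_type = "7mer-m8")
  cand <- build_candidates(de, sites)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$evidence, "seed")
  expect_equal(cand$target_class, "lncRNA")
  expect_equal(cand$mirna_dir, "down")

  # duplicate (miRNA, mRNA) across database dialects merges evidence
  ext <- data.frame(mirna_id = c("m1", "m1"), target_id = c("g1", "g1"),
                    evidence = c("validated", "predicted"),
                    source = c("dbA", "dbB"))
  cand2 <- build_candidates(de, sites, ext)
  mrow <- cand2[cand2$target_id == "g1", ]
  expect_equal(nrow(mrow), 1L)
  expect_equal(mrow$evidence, "predicted_db;validated_db")

  # unknown molecule dropped with warning
  ext_bad <- data.frame(mirna_id = "m9", target_id = "g1",
                        evidence = "validated", source = "dbA")
  expect_warning(out <- build_candidates(de, NULL, ext_bad), "DE call")
  expect_equal(nrow(out), 0L)
})

test_that("pair filters enforce opposite direction and the inclusive -0.4 cut", {
  x <- c(1, 2, 3, 4, 5, 6)
  z <- c(1, -1, -1, 1, 1, -1)
  vals <- rbind(mir_a = vector_with_cor(x, z, -0.5),
                mir_b = vector_with_cor(x, z, -0.3),
                mir_c = vector_with_cor(x, z, -0.4),
                mir_d = vector_with_cor(x, z, -0.9),
                tgt = x)
  colnames(vals) <- sprintf("s%d", 1:6)
  expr <- toy_matrix(vals + 5, transformed = TRUE)

  pairs <- data.frame(
    mirna_id = c("mir_a", "mir_b", "mir_c", "mir_d"),
    target_id = "tgt", target_class = "mRNA", evidence = "seed",
    mirna_dir = c("down", "down", "down", "up"),
    target_dir = c("up", "up", "up", "up"))
  kept <- filter_pairs(pairs, expr, pcc_cut = -0.4)
  expect_true("mir_a" %in% kept$mirna_id)   # r = -0.5, opposite dirs
  expect_false("mir_b" %in% kept$mirna_id)  # r = -0.3 fails the cut
  expect_false("mir_d" %in% kept$mirna_id)  # up/up fails direction first
  # the cut is inclusive: a pair at exactly the realized boundary passes
  r_c <- stats::cor(expr$values["mir_c", ], expr$values["tgt", ])
  kept_c <- filter_pairs(pairs, expr, pcc_cut = r_c)
  expect_true("mir_c" %in% kept_c$mirna_id)

  few <- subset_expression(expr, samples = c("s1", "s2", "s3"))
  expect_error(filter_pairs(pairs, few), "fewer than 4")
})
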