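# textbook log-rank oracle: per distinct event time, a 2x2 table gives
# observed and expected events in group 1 and the hypergeometric variance
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

six_subject_fixture <- function() {
  data.frame(
    sample_id = paste0("s", 1:6),
    time = c(2, 4, 5, 1, 3, 6),
    event = c(1, 1, 0, 1, 1, 1),
    group = rep(c("hi", "lo"), each = 3))
}

test_that("the product-limit estimator matches hand computation", {
  # two subjects, events at 1 and 2: S = 1/2 on [1, 2), 0 after
  km <- km_estimate(data.frame(time = c(1, 2), event = c(1, 1)))
  expect_equal(km$surv, c(0.5, 0))

  # all censored: S stays at 1
  km0 <- km_estimate(data.frame(time = c(3, 5, 8), event = c(0, 0, 0)))
  expect_true(all(km0$surv == 1))

  # censoring decrements the risk set without dropping S:
  # events at 1 (n=4) and 3 (n=2, after a censor at 2): S = 3/4, then 3/8
  km2 <- km_estimate(data.frame(time = c(1, 2, 3, 4),
                                event = c(1, 0, 1, 0)))
  expect_equal(km2$surv[km2$time == 1], 0.75)
  expect_equal(km2$surv[km2$time == 3], 0.375)

  # non-increasing step function
  set.seed(2)
  km3 <- km_estimate(data.frame(time = rexp(50) + 0.01,
                                event = rbinom(50, 1, 0.7)))
  expect_true(all(diff(km3$surv) <= 1e-12))

  expect_error(km_estimate(data.frame(time = c(1, -1), event = c(1, 1))),
               "positive")
})

test_that("the rho = 0 test equals the hand-tabulated log-rank on the fixture", {
  fx <- six_subject_fixture()
  got <- grho_test(fx, fx$group, rho = 0)
  expect_equal(got$statistic,
               oracle_logrank(fx$time, fx$event, fx$group),
               tolerance = 1e-12)
  expect_equal(got$df, 1L)

  # identical groups: O = E exactly
  same <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 0), 2))
  res0 <- grho_test(same, rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  expect_error(grho_test(fx, rep("one", 6)), "2 non-empty groups")
})

test_that("well-separated exponential groups are detected decisively", {
  set.seed(10)
  d <- data.frame(time = c(rexp(50, rate = 5), rexp(50, rate = 1)),
                  event = 1)
  res <- grho_test(d, rep(c("fast", "slow"), each = 50))
  expect_lt(res$p, 0.001)
})

test_that("Cox regression recovers planted effects and flags degeneracies", {
  expect_error(
    cox_univariate(data.frame(time = 1:5, event = c(1, 1, 1, 0, 1)),
                   rep(2, 5)), "vary")

  # null covariate: no systematic association
  set.seed(3)
  d0 <- data.frame(time = rexp(200), event = rbinom(200, 1, 0.8))
  res0 <- cox_univariate(d0, rnorm(200))
  expect_lt(abs(res0$z), 3)

  # planted log-hazard slope via the simulator's Weibull mechanism
  cfg <- small_config(seed = 15L, n_pairs = 300L,
                      subclass_sizes = c(S1 = 300L),
                      survival_effect = 0.7, survival_shape = 1.5)
  coh <- simulate_cohort(cfg)
  # Weibull with shape a: the score's log-hazard coefficient is
  # survival_effect itself (the simulator divides by a inside the time
  # transform), so Cox should recover 0.7
  res <- cox_univariate(coh$survival, coh$survival$score)
  expect_false(res$flagged)
  expect_lt(abs(res$beta - 0.7), 0.15)
})

test_that("the prognostic screen flags score-tracking features at rate alpha under the null", {
  cfg <- small_config(seed = 16L, n_pairs = 60L, subclass_sizes = c(S1 = 60L))
  coh <- simulate_cohort(cfg)
  tr <- transform_counts(filter_expressed(coh$counts))
  # build a small screen: the planted prognostic lncRNAs plus noise
  feats <- c(coh$truth_prognostic,
             setdiff(rownames(tr$values), coh$truth_prognostic)[1:40])
  sub <- subset_expression(tr, features = intersect(feats, rownames(tr$values)),
                           samples = coh$survival$sample_id)
  res <- prognostic_screen(sub, coh$survival, alpha = 0.05)
  expect_equal(nrow(res), nrow(sub$values))
  hit <- res$significant[match(coh$truth_prognostic, res$feature_id)]
  expect_gt(mean(hit, na.rm = TRUE), 0.5)

  # permuted survival: calls at roughly the nominal rate
  set.seed(8)
  perm <- coh$survival
  perm$time <- sample(perm$time)
  perm$event <- sample(perm$event)
  res_null <- prognostic_screen(sub, perm, alpha = 0.05)
  expect_lt(mean(res_null$significant), 0.15)
})
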