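# Survival estimation, log-rank, cutpoint scan, exact tests, association.

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # no censoring: equals the empirical survival function
  set.seed(17)
  tm <- sample(1:50, 30, TRUE)
  km2 <- km_estimate(tm, rep(1, 30))
  orc <- oracle_km(tm, rep(1, 30))
  expect_equal(km2$surv[match(orc$time, km2$time)], orc$surv,
               tolerance = 1e-12)
  ecdf_surv <- vapply(orc$time, function(t) mean(tm > t), numeric(1))
  expect_equal(orc$surv, ecdf_surv, tolerance = 1e-12)
  # censoring reduces the risk set without steps
  set.seed(18)
  ev <- rbinom(30, 1, 0.6)
  km3 <- km_estimate(tm, ev)
  orc3 <- oracle_km(tm, ev)
  expect_equal(km3$surv[match(orc3$time, km3$time)], orc3$surv,
               tolerance = 1e-12)
  expect_true(all(diff(km3$surv) <= 1e-12))

  expect_equal(unique(km_estimate(c(3, 6), c(0, 0))$surv), 1)  # all censored
  km1 <- km_estimate(5, 1)
  expect_equal(km1$surv, 0)
  expect_equal(km1$time, 5)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank equals the direct (O-E)^2/V recomputation", {
  set.seed(19)
  for (i in 1:10) {
    n <- 40
    g <- rep(1:2, each = n / 2)
    tm <- round(rexp(n, 0.05), 2)
    ev <- rbinom(n, 1, 0.7)
    lr <- logrank_test(g, tm, ev)
    expect_equal(lr$chisq, oracle_logrank_chisq(g, tm, ev),
                 tolerance = 1e-10)
    # label swap leaves the statistic unchanged
    expect_equal(logrank_test(3 - g, tm, ev)$chisq, lr$chisq,
                 tolerance = 1e-12)
  }
  # identical survival in both groups: statistic 0, p 1
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4)
  lr0 <- logrank_test(rep(1:2, each = 4), tm, rep(1, 8))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(rep(1, 4), 1:4, rep(1, 4)), "two groups")
})

test_that("cutpoint scan maximises log-rank and matches the brute-force oracle", {
  set.seed(20)
  for (i in 1:5) {
    n <- 30
    burden <- runif(n, 0, 0.01)
    tm <- round(rexp(n, 0.03 + 5 * burden), 2)
    ev <- rbinom(n, 1, 0.8)
    cp <- cox_cutpoint(burden, tm, ev)
    orc <- oracle_cutpoint(burden, tm, ev)
    expect_equal(cp$cutoff, orc$cutoff, tolerance = 1e-12)
    expect_equal(cp$statistic, orc$chisq, tolerance = 1e-10)
    expect_gte(cp$n_low, 3L)
    expect_gte(cp$n_high, 3L)
  }
})

test_that("cutpoint lands in the separating gap of a separable cohort", {
  # low-burden subjects all have late censored times, high-burden all die
  burden <- c(runif(10, 0, 0.001), runif(10, 0.005, 0.01))
  tm <- c(runif(10, 50, 60), runif(10, 1, 5))
  ev <- rep(c(0, 1), each = 10)
  cp <- cox_cutpoint(burden, tm, ev)
  expect_gt(cp$cutoff, 0.001)
  expect_lt(cp$cutoff, 0.005)
  expect_equal(cp$n_low, 10L)
})

test_that("cutpoint split is invariant to monotone transforms of burden", {
  set.seed(21)
  burden <- runif(20, 0, 0.01)
  tm <- round(rexp(20, 0.05), 2)
  ev <- rbinom(20, 1, 0.8)
  cp1 <- cox_cutpoint(burden, tm, ev)
  cp2 <- cox_cutpoint(log10(burden + 1e-6), tm, ev)
  expect_equal(burden < cp1$cutoff,
               log10(burden + 1e-6) < cp2$cutoff)
  expect_equal(cp1$statistic, cp2$statistic, tolerance = 1e-10)
  expect_error(cox_cutpoint(burden[1:5], tm[1:5], ev[1:5]), "at least 10")
})

test_that("Fisher p equals hypergeometric enumeration and is symmetric", {
  expect_equal(fisher_2x2(5, 0, 0, 5), 2 / choose(10, 5), tolerance = 1e-12)
  set.seed(22)
  for (i in 1:25) {
    tot <- sample(8:40, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    p <- fisher_2x2(a, b, c, d)
    expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-10)
    expect_equal(fisher_2x2(a, c, b, d), p, tolerance = 1e-12)  # transpose
  }
  expect_error(fisher_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("Pearson chi-squared matches the direct formula, no continuity correction", {
  tab <- matrix(c(12, 5, 7, 9), 2)
  got <- chisq_contingency(tab)
  orc <- oracle_chisq(tab)
  expect_equal(got$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(got$p, orc$p, tolerance = 1e-10)
  # identical rows: statistic 0, p 1
  same <- matrix(c(5, 5, 9, 9, 2, 2), 2)
  got0 <- chisq_contingency(same)
  expect_equal(got0$statistic, 0, tolerance = 1e-12)
  expect_equal(got0$p, 1, tolerance = 1e-12)
  # multi-level table (group x RAI-like stages)
  tab3 <- matrix(c(4, 6, 3, 7, 5, 5, 2, 8, 6, 4), 2)
  expect_equal(chisq_contingency(tab3)$statistic,
               oracle_chisq(tab3)$statistic, tolerance = 1e-10)
  expect_error(chisq_contingency(matrix(0, 2, 2)), "all-zero")
})

test_that("associate_groups builds per-marker tests and survival comparisons", {
  cfg <- small_config(seed = 123, n_samples_group1 = 10L,
                      n_samples_group2 = 10L)
  coh <- simulate_cohort(cfg, counts_only = TRUE)
  group <- coh$group
  assoc <- associate_groups(group, coh$clinical,
                            burdens = data.frame(
                              sample_id = names(group),
                              pct_lgt = 100 * coh$truth_counts$n_lgt /
                                coh$truth_counts$n_pairs))
  expect_s3_class(assoc, "lgt_assoc")
  expect_true(all(c("ighv_mutated", "del13q", "cd38", "rai_stage") %in%
                    assoc$markers$marker))
  expect_true(all(assoc$markers$p >= 0 & assoc$markers$p <= 1))
  expect_true(all(c("os", "pfs") %in% names(assoc$survival)))
  expect_equal(length(assoc$markers$p_bh), nrow(assoc$markers))

  # marker perfectly aligned with a 10v10 grouping
  cl <- coh$clinical
  cl$ighv_mutated <- ifelse(group[cl$sample_id] == 1, "yes", "no")
  a2 <- associate_groups(group, cl)
  expect_equal(a2$markers$p[a2$markers$marker == "ighv_mutated"],
               2 / choose(20, 10), tolerance = 1e-12)

  # an all-missing marker is skipped and logged
  cl$del17q <- "NA"
  a3 <- associate_groups(group, cl)
  expect_false("del17q" %in% a3$markers$marker)
  expect_equal(unname(a3$n_dropped["del17q"]), 20L)

  expect_error(associate_groups(setNames(1:2, c("X1", "X2")), coh$clinical),
               "no overlapping samples")
})
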