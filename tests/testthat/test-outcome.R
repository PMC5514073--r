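test_that("Clopper-Pearson matches closed forms at the boundaries for all n <= 50", {
  for (n in 1:50) {
    ci0 <- clopper_pearson(0, n)
    expect_equal(ci0[["lower"]], 0)
    expect_equal(ci0[["upper"]], 1 - 0.025^(1 / n), tolerance = 1e-12)
    cin <- clopper_pearson(n, n)
    expect_equal(cin[["lower"]], 0.025^(1 / n), tolerance = 1e-12)
    expect_equal(cin[["upper"]], 1)
  }
  expect_error(clopper_pearson(7, 6), "k <= n")
})

test_that("Clopper-Pearson agrees with the exact binomial test interval", {
  for (kn in list(c(5, 6), c(3, 10), c(17, 20), c(1, 40))) {
    ci <- clopper_pearson(kn[1], kn[2])
    bt <- stats::binom.test(kn[1], kn[2])$conf.int
    expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-10)
  }
  # the 5/6 sensitivity interval prints as 36-100%
  ci <- clopper_pearson(5, 6)
  expect_equal(round(100 * ci[["lower"]]), 36)
  expect_equal(round(100 * ci[["upper"]]), 100)
})

test_that("contingency metrics reproduce known tables and flag degeneracy", {
  m <- contingency_metrics(tp = 5, fp = 0, fn = 1, tn = 6)
  expect_equal(round(100 * m$sensitivity$estimate, 1), 83.3)
  expect_equal(round(100 * m$specificity$estimate, 1), 100)
  expect_equal(round(100 * m$ppv$estimate, 1), 100)
  expect_equal(round(100 * m$npv$estimate, 1), 85.7)
  expect_true(all(vapply(c("sensitivity", "specificity", "ppv", "npv"),
                         function(k) {
                           v <- m[[k]]
                           v$lower <= v$estimate && v$estimate <= v$upper
                         }, logical(1))))

  perfect <- contingency_metrics(3, 0, 0, 3)
  expect_equal(perfect$sensitivity$estimate, 1)
  expect_equal(perfect$npv$estimate, 1)

  deg <- contingency_metrics(0, 0, 0, 4)
  expect_false(deg$sensitivity$defined)
  expect_false(deg$ppv$defined)
  expect_true(deg$specificity$defined)

  # counts round-trip from the per-metric numerators/denominators
  expect_equal(m$sensitivity$k, 5)
  expect_equal(m$sensitivity$n - m$sensitivity$k, unname(m$counts["fn"]))
  expect_equal(m$specificity$k, unname(m$counts["tn"]))
  expect_equal(m$ppv$n, unname(m$counts["tp"] + m$counts["fp"]))
})

test_that("Kaplan-Meier estimates match hand product-limit arithmetic", {
  all_cens <- km_curve(c(5, 8, 12), c(0, 0, 0), rep("a", 3))
  expect_true(all(all_cens$survival == 1))

  two_events <- km_curve(c(2, 4), c(1, 1), rep("a", 2))
  expect_equal(two_events$survival, c(0.5, 0))

  # {1 event, 2 censored, 3 event}: S = 2/3 after t=1, then 0 at t=3
  mix <- km_curve(c(1, 2, 3), c(1, 0, 1), rep("a", 3))
  expect_equal(mix$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(mix$n_risk, c(3, 2, 1))

  # non-increasing on arbitrary instances
  set.seed(71)
  for (r in 1:5) {
    t <- sample(1:40, 12, replace = TRUE)
    e <- rbinom(12, 1, 0.6)
    g <- rep(c("x", "y"), 6)
    km <- km_curve(t, e, g)
    for (gr in unique(km$group)) {
      expect_true(all(diff(km$survival[km$group == gr]) <= 1e-12))
    }
  }
})

test_that("log-rank matches the risk-table oracle and is label-symmetric", {
  # identical event patterns in both groups -> no difference
  t0 <- c(3, 6, 9, 3, 6, 9)
  e0 <- c(1, 1, 0, 1, 1, 0)
  g0 <- rep(c("a", "b"), each = 3)
  lr0 <- logrank_test(t0, e0, g0)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # 6-vs-6 with censoring against the hand O-E/V sum
  t1 <- c(4, 7, 9, 12, 15, 20, 5, 8, 11, 14, 18, 25)
  e1 <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 0, 1, 1)
  g1 <- rep(c("a", "b"), each = 6)
  lr1 <- logrank_test(t1, e1, g1)
  expect_equal(lr1$chisq, oracle_logrank_chisq(t1, e1, g1), tolerance = 1e-8)

  swapped <- logrank_test(t1, e1, ifelse(g1 == "a", "b", "a"))
  expect_equal(lr1$chisq, swapped$chisq, tolerance = 1e-12)
  expect_equal(lr1$p, swapped$p, tolerance = 1e-12)

  expect_error(logrank_test(t1, rep(0, 12), g1), "event")
})

test_that("group comparison tests match direct formulas", {
  # KS on identical samples
  ks <- ks_af_by_group(c(1, 2, 3, 1, 2, 3), rep(c("r", "n"), each = 3))
  expect_equal(ks$statistic, 0)

  # Bonferroni is multiplication by the number of timepoints tested
  det <- c(rep(c(TRUE, FALSE), times = c(12, 20)),   # tp 1
           rep(c(TRUE, FALSE), times = c(8, 24)))    # tp 2
  grp <- rep(rep(c("r", "n"), times = c(16, 16)), 2)
  tp <- rep(1:2, each = 32)
  res <- detection_rate_by_timepoint(det, grp, tp)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 2))

  # chi-squared statistic equals the expected-count formula, no correction
  grp2 <- rep(c("rec", "non"), times = c(17, 16))
  det2 <- c(rep(TRUE, 9), rep(FALSE, 8), rep(TRUE, 1), rep(FALSE, 15))
  res2 <- detection_rate_by_timepoint(det2, grp2, rep(1, 33))
  tab <- table(grp2, det2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res2$chisq, sum((tab - expected)^2 / expected), tolerance = 1e-10)
})

test_that("Kruskal-Wallis + Dunn flag the plasma-vs-urine AF gap", {
  set.seed(74)
  af <- c(rbeta(40, 1, 60), rbeta(40, 3, 30), rbeta(40, 4, 25))
  type <- rep(c("PLS", "UCP", "USN"), each = 40)
  res <- af_by_sample_type_test(af, type)
  expect_lt(res$kruskal$p, 0.01)
  dn <- res$dunn
  expect_equal(nrow(dn), 3)
  expect_equal(dn$p_adj, pmin(1, dn$p_raw * 3))
  pls_urine <- dn[dn$group1 == "PLS" | dn$group2 == "PLS", ]
  expect_true(all(pls_urine$p_adj < 0.05))

  # z statistic against the no-tie closed form on a tiny instance
  x <- c(1, 2, 3, 4, 5, 6)
  gsm <- rep(c("a", "b"), each = 3)
  dn2 <- dunn_test(x, gsm)
  z_hand <- (mean(rank(x)[1:3]) - mean(rank(x)[4:6])) /
    sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(dn2$z, z_hand, tolerance = 1e-12)

  expect_error(af_by_sample_type_test(rep(0.1, 6), gsm), "tied")
})

test_that("median time to event uses half-up rounding and reports the range", {
  expect_equal(median_time_to_event(c(10))$median_days, 10)
  expect_equal(median_time_to_event(c(1, 2, 3, 4))$median_days, 3)
  r <- median_time_to_event(c(378, 269, 507, 293, 264, 466, 265, 472))
  expect_equal(r$median_days, 336)
  expect_equal(r$min_days, 264)
  expect_equal(r$max_days, 507)
  expect_error(median_time_to_event(numeric(0)), "empty")
})
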