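test_that("residuals match the brute-force least-squares solution", {
  set.seed(51)
  ctrl_vals <- rnorm(20, 0, 0.1)
  test_vals <- ctrl_vals
  test_vals[c(4, 13)] <- test_vals[c(4, 13)] + 1.0   # spike on 2 of 20 bins
  g <- flat_genome(1, 20)
  ft <- fit_against_control(as_profile(test_vals, g), as_profile(ctrl_vals, g))

  # normal equations solved directly
  x <- ctrl_vals; y <- test_vals
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(ft$slope, slope, tolerance = 1e-9)
  expect_equal(ft$intercept, intercept, tolerance = 1e-9)
  expect_equal(ft$residuals, y - intercept - slope * x, tolerance = 1e-9)
})

test_that("the score is zero iff test is an affine function of the control", {
  set.seed(52)
  ctrl_vals <- rnorm(50, 0, 0.2)
  g <- flat_genome(1, 50)
  ctrl <- as_profile(ctrl_vals, g)

  expect_equal(imbalance_score(ctrl, ctrl)$score, 0, tolerance = 1e-18)
  affine <- as_profile(2 * ctrl_vals + 1, g)
  expect_equal(imbalance_score(affine, ctrl)$score, 0, tolerance = 1e-18)

  bent <- as_profile(2 * ctrl_vals + 1 + c(rep(0, 49), 0.5), g)
  expect_gt(imbalance_score(bent, ctrl)$score, 1e-4)

  expect_error(fit_against_control(ctrl, as_profile(rep(0.3, 50), g)),
               "constant")
})

test_that("top-5% residual selection follows the ceil rule with stable ties", {
  r <- rep(0, 100); r[37] <- 0.8
  sc <- score_from_residuals(r)
  expect_equal(sc$n_extreme, 5)
  expect_equal(sc$score, 0.8^2)          # four zero bins contribute nothing
  expect_true(37 %in% sc$which)

  expect_equal(score_from_residuals(rep(1, 41))$n_extreme, ceiling(0.05 * 41))
  # ties broken by bin order: all-equal residuals keep the first bins
  expect_equal(score_from_residuals(rep(1, 40))$which, 1:2)
})

test_that("control pooling is order-free and sums raw counts", {
  g <- make_genome(2, 40, seed = 61)
  m <- sampling_model()
  cnts <- setNames(lapply(1:4, function(k)
    simulate_counts(g, list(), numeric(0), m, seed = 70 + k)),
    paste0("b", 1:4))
  a <- pool_controls(cnts, g)
  b <- pool_controls(rev(cnts), g)
  expect_equal(a$log2ratio, b$log2ratio)
  expect_setequal(a$members, b$members)
})

test_that("imbalance grows with tumour fraction on a fixed aberrant profile", {
  g <- make_genome(4, 40, seed = 63)
  m <- sampling_model()
  ctrl <- pool_controls(setNames(lapply(1:4, function(k)
    simulate_counts(g, list(), numeric(0), m, seed = 80 + k)), paste0("b", 1:4)), g)
  cl <- clone_profile(g, "c", data.frame(chrom = c("chr1", "chr3"),
                                         from_bin = c(5, 10), to_bin = c(20, 21),
                                         cn = c(3, 1)))
  s0 <- imbalance_score(correct_counts(
    simulate_counts(g, list(cl), 0, m, seed = 90), g), ctrl)$score
  s1 <- imbalance_score(correct_counts(
    simulate_counts(g, list(cl), 0.2, m, seed = 90), g), ctrl)$score
  expect_gt(s1, s0)
  res <- imbalance_score(correct_counts(
    simulate_counts(g, list(cl), 0.2, m, seed = 90), g), ctrl)
  expect_equal(res$n_extreme, ceiling(0.05 * res$n))
})

test_that("leave-one-out control threshold exceeds germline-only scores rarely", {
  g <- make_genome(3, 40, seed = 65)
  m <- sampling_model()
  cnts <- setNames(lapply(1:5, function(k)
    simulate_counts(g, list(), numeric(0), m, seed = 110 + k)), paste0("b", 1:5))
  thr <- imbalance_threshold(cnts, g)
  expect_gt(thr, 0)
  expect_error(imbalance_threshold(cnts[1:2], g), "at least 3")
})

test_that("concordance R2 behaves at the identity and under independence", {
  set.seed(55)
  g <- flat_genome(1, 1000)
  a_vals <- rnorm(1000)
  a <- as_profile(a_vals, g)
  expect_equal(concordance_r2(a, a)$r2_adj, 1)

  b <- as_profile(rnorm(1000), g)
  expect_lt(abs(concordance_r2(a, b)$r2_adj), 0.01)

  expect_error(concordance_r2(as_profile(rep(1, 1000), g), b), "constant")
})
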