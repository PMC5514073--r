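test_that("the threshold is the higher of the technical and sampling floors", {
  expect_equal(detection_threshold(2000), 0.005)
  expect_equal(detection_threshold(50), 0.02)
  expect_equal(detection_threshold(200), 0.005)   # exact tie, well-defined
  expect_equal(detection_threshold(c(10000, 100)), c(0.005, 0.01))
  expect_error(detection_threshold(0), "> 0")
})

test_that("detection requires the AF to strictly exceed the binding floor", {
  expect_true(call_variant(10000, 60, 1e4)$detected)          # af 0.006
  expect_false(call_variant(10000, 50, 1e4)$detected)         # af exactly 0.005
  expect_false(call_variant(1000, 12, 50)$detected)           # 0.012 < 0.02 floor
  r <- call_variant(1000, 12, 50)
  expect_equal(r$threshold_used, 0.02)
  expect_equal(r$af, 0.012)                                   # AF retained anyway
})

test_that("threshold dominance: more input never raises the bar; detection is monotone in AF", {
  ge_grid <- c(20, 100, 200, 1000, 1e5)
  thr <- detection_threshold(ge_grid)
  expect_true(all(diff(thr) <= 0))

  tab <- data.frame(depth = 10000, alt_reads = round(seq(0, 400, by = 25)),
                    genomic_equivalents = 500)
  called <- call_variants(tab)
  expect_true(all(diff(called$detected) >= 0))   # once detected, stays detected
})

test_that("presence is any-detection over available fluids; missingness is unevaluable", {
  det <- data.frame(
    patient = "P1", timepoint = c(1, 1, 1, 2, 2),
    sample_type = c("PLS", "UCP", "USN", "PLS", "UCP"),
    detected = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    af = c(0.001, 0.002, 0.03, 0.001, 0.001),
    stringsAsFactors = FALSE)
  expect_true(patient_presence(det, "P1", 1))    # USN alone suffices
  expect_false(patient_presence(det, "P1", 2))   # tested, all below threshold
  expect_true(is.na(patient_presence(det, "P1", 3)))  # nothing assayed
  expect_true(is.na(patient_presence(det, "P2", 1)))
})

test_that("max AF per timepoint keeps missing visits missing", {
  det <- data.frame(
    patient = "P1", timepoint = c(1, 1, 3),
    sample_type = "USN",
    detected = c(TRUE, FALSE, TRUE),
    af = c(0.07, 0.001, 0.03), stringsAsFactors = FALSE)
  s <- max_af_per_timepoint(det, "P1", "USN", timepoints = 1:3)
  expect_equal(unname(s), c(0.07, NA, 0.03))

  one <- det[3, ]
  expect_equal(unname(max_af_per_timepoint(one, "P1", "USN", timepoints = 3)), 0.03)
})

test_that("the cohort grid spans patients x panel x timepoints x fluids", {
  empty <- detection_grid(
    data.frame(patient = character(0), locus_id = character(0),
               gene = character(0), timepoint = integer(0),
               sample_type = character(0), detected = logical(0),
               af = numeric(0)),
    data.frame(patient = character(0), timepoint = integer(0),
               sample_type = character(0), sample_id = character(0)))
  expect_equal(nrow(empty), 0)

  det <- data.frame(patient = "P1", locus_id = "TP53_1", gene = "TP53",
                    timepoint = 1, sample_type = "USN", detected = TRUE,
                    af = 0.04, stringsAsFactors = FALSE)
  sheet <- data.frame(patient = "P1", timepoint = 1,
                      sample_type = c("PLS", "USN"),
                      sample_id = c("a", "b"), stringsAsFactors = FALSE)
  grid <- detection_grid(det, sheet)
  expect_equal(sum(grid$status == "detected"), 1)
  expect_equal(nrow(grid), 3)  # 1 patient x 1 locus x 1 tp x 3 types
  expect_equal(grid$status[grid$sample_type == "UCP"], "missing")

  cc <- small_cohort(seed = 3)
  called <- call_variants(cc$cohort$variants)
  called <- merge(called, cc$cohort$sample_sheet[, c("sample_id", "timepoint", "sample_type")],
                  by = "sample_id")
  g <- detection_grid(called, cc$cohort$sample_sheet)
  panels <- unique(called[, c("patient", "locus_id")])
  n_tp <- length(cc$scenario$timepoint_days)
  expect_equal(nrow(g), nrow(panels) * n_tp * 3)
})

test_that("with published thresholds, germline samples stay negative", {
  m <- sampling_model(variant_depth = 7600, error_rate = 1e-4,
                      genomic_equivalents = 5000)
  reads <- simulate_variant_reads(rep(0, 2000), m, seed = 17)
  called <- call_variants(cbind(reads, sample_id = "BUF"))
  expect_equal(sum(called$detected), 0)
})

test_that("tumour fraction is estimated as twice the mean panel AF", {
  v <- data.frame(sample_id = c("s1", "s1", "s2"), af = c(0.04, 0.06, 0.10))
  est <- estimate_tumour_fraction(v)
  expect_equal(est$tf_estimate[est$sample_id == "s1"], 0.10)
  expect_equal(est$tf_estimate[est$sample_id == "s2"], 0.20)
})
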