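test_that("identical scenario and seed reproduce the cohort exactly", {
  a <- simulate_cohort(cohort_scenario(n_patients = 5, n_recurrers = 2,
                                       genome = make_genome(3, 30, seed = 4),
                                       seed = 9))
  b <- simulate_cohort(cohort_scenario(n_patients = 5, n_recurrers = 2,
                                       genome = make_genome(3, 30, seed = 4),
                                       seed = 9))
  expect_identical(a$sample_sheet, b$sample_sheet)
  expect_identical(a$variants, b$variants)
  expect_identical(a$bin_counts, b$bin_counts)
  expect_identical(a$truth, b$truth)
})

test_that("the default design has 17 patients, 3 fluids per visit, 8 recurrers", {
  sc <- cohort_scenario(seed = 1)
  co <- simulate_cohort(sc)
  ss <- co$sample_sheet
  fluids <- ss[ss$sample_type %in% c("PLS", "UCP", "USN"), ]
  for (tp in seq_along(sc$timepoint_days)) {
    expect_equal(nrow(fluids[fluids$timepoint == tp, ]), 17 * 3)
  }
  expect_equal(length(unique(ss$patient)), 17)
  by_pat <- ss[!duplicated(ss$patient), ]
  expect_equal(sum(by_pat$recurred), 8)
  expect_true(all(by_pat$recurrence_days > 0))
  expect_true(all(diff(sc$timepoint_days) > 0))
  # TUR and germline baseline samples exist per patient
  expect_equal(sum(ss$sample_type == "TUR"), 17)
  expect_equal(sum(ss$sample_type == "BUF"), 17)
})

test_that("trajectory archetypes shape the ground truth as declared", {
  sc <- cohort_scenario(seed = 1)
  arch <- vapply(sc$patients, `[[`, character(1), "archetype")

  resp <- sc$patients[[which(arch == "responder-decay")[1]]]
  for (st in c("PLS", "UCP", "USN")) {
    expect_true(all(diff(resp$tf[, st]) < 0))   # strictly decreasing
  }

  sw <- sc$patients[[which(arch == "clonal-switch")[1]]]
  cf <- sw$clone_frac
  expect_true(all(diff(cf[, "A"]) < 0))
  expect_true(all(diff(cf[, "B"]) > 0))
  expect_equal(sum(diff(sign(cf[, "A"] - cf[, "B"])) != 0), 1)  # one crossing
})

test_that("urine carries more tumour DNA than plasma in the ground truth", {
  co <- simulate_cohort(cohort_scenario(seed = 1))
  tr <- co$truth$samples
  fl <- tr[tr$sample_type %in% c("PLS", "UCP", "USN"), ]
  mean_tf <- tapply(fl$true_tf, fl$sample_type, mean)
  expect_gt(mean_tf[["USN"]], mean_tf[["PLS"]])
  expect_gt(mean_tf[["UCP"]], mean_tf[["PLS"]])

  # and in the simulated AFs of panel-positive patients
  v <- merge(co$variants, co$sample_sheet[, c("sample_id", "sample_type")],
             by = "sample_id")
  v <- v[v$sample_type %in% c("PLS", "USN"), ]
  af <- tapply(v$af, v$sample_type, mean)
  expect_gt(af[["USN"]], af[["PLS"]])
})

test_that("cohort files round-trip through the TSV writers", {
  cc <- small_cohort(seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(cc$cohort, dir)
  expect_true(file.exists(file.path(dir, "sample_sheet.tsv")))

  ss <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_equal(ss$sample_id, cc$cohort$sample_sheet$sample_id)
  v <- read_variants(file.path(dir, "variants.tsv"))
  expect_equal(v$alt_reads, cc$cohort$variants$alt_reads)
  g <- read_genome_bins(file.path(dir, "genome_bins.tsv"))
  expect_equal(g$start, cc$cohort$genome$start)

  sid <- names(cc$cohort$bin_counts)[1]
  cnt <- read_bin_counts(file.path(dir, "counts", paste0(sid, ".tsv")), g)
  expect_equal(cnt, cc$cohort$bin_counts[[sid]])
  expect_error(read_bin_counts(file.path(dir, "counts", "nope.tsv")), "not found")
})
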