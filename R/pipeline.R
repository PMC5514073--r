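#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one serialisable
#' list. Input is either a simulated cohort (`scenario`) or on-disk tables
#' (`input_dir` as written by [write_cohort()]).
#'
#' @param scenario a `cohort_scenario` (used when `input_dir` is NULL).
#' @param input_dir directory holding `sample_sheet.tsv`, `variants.tsv`,
#'   `genome_bins.tsv` and `counts/`.
#' @param out_dir where to write stage outputs (NULL: nothing written).
#' @param cbs_alpha,cbs_nperm,cbs_min_width CBS split test parameters.
#' @param k_mad,min_abs gain/loss calling thresholds.
#' @param frac_extreme extreme-residual fraction of the imbalance score.
#' @param technical technical AF detection floor.
#' @param conf confidence level for contingency CIs.
#' @param classify_timepoint on-treatment visit used for the
#'   presence-vs-recurrence classification (default 2: just before the second
#'   chemo cycle).
#' @param run_cna run the sWGS copy-number arm (the slow part).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, input_dir = NULL, out_dir = NULL,
                            cbs_alpha = 0.01, cbs_nperm = 1000,
                            cbs_min_width = 2, k_mad = 3, min_abs = 0.10,
                            frac_extreme = 0.05, technical = 0.005,
                            conf = 0.95, classify_timepoint = 2L,
                            run_cna = TRUE, seed = 1L) {
  stopifnot(frac_extreme > 0, frac_extreme < 1, technical > 0, technical < 1,
            conf > 0, conf < 1)
  if (is.null(scenario) && is.null(input_dir)) {
    scenario <- cohort_scenario(seed = seed)
  }
  structure(list(scenario = scenario, input_dir = input_dir,
                 out_dir = out_dir, cbs_alpha = cbs_alpha,
                 cbs_nperm = cbs_nperm, cbs_min_width = cbs_min_width,
                 k_mad = k_mad, min_abs = min_abs,
                 frac_extreme = frac_extreme, technical = technical,
                 conf = conf, classify_timepoint = as.integer(classify_timepoint),
                 run_cna = run_cna, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_cohort_inputs <- function(input_dir) {
  need <- c(sample_sheet = "sample_sheet.tsv", variants = "variants.tsv",
            genome = "genome_bins.tsv")
  for (field in names(need)) {
    path <- file.path(input_dir, need[[field]])
    if (!file.exists(path)) {
      stop(errorCondition(
        sprintf("missing input for field '%s': %s", field, path),
        class = c("urotrace_missing_input", "error")))
    }
  }
  genome <- read_genome_bins(file.path(input_dir, "genome_bins.tsv"))
  counts <- list()
  cdir <- file.path(input_dir, "counts")
  if (dir.exists(cdir)) {
    for (f in list.files(cdir, pattern = "\\.tsv$", full.names = TRUE)) {
      counts[[sub("\\.tsv$", "", basename(f))]] <- read_bin_counts(f, genome)
    }
  }
  structure(list(genome = genome,
                 sample_sheet = read_sample_sheet(file.path(input_dir, "sample_sheet.tsv")),
                 variants = read_variants(file.path(input_dir, "variants.tsv")),
                 bin_counts = counts, truth = NULL, scenario = NULL),
            class = "mutdna_cohort")
}

#' Analyse a cohort end to end
#'
#' The in-memory core of the pipeline: applies the dual-threshold SNV
#' detection rule, builds the cohort detection grid and per-patient presence
#' calls, classifies patients by mutDNA presence at the chosen on-treatment
#' visit, computes the detection-vs-recurrence contingency metrics with exact
#' CIs, Kaplan-Meier curves and the log-rank test, the group-comparison tests
#' (KS on AFs by outcome, per-timepoint chi-squared with Bonferroni,
#' Kruskal-Wallis + Dunn across sample types), SNV-based tumour-fraction
#' estimates, and (optionally) the sWGS arm: corrected profiles, CBS
#' segments, gain/loss calls, CNA detectability, genome-wide imbalance scores
#' against the pooled germline control, and concordance of each fluid profile
#' with the matched tumour profile.
#'
#' Patients with no panel SNV observed anywhere are an unevaluable stratum
#' and are excluded from the presence classification, as are patients with no
#' peripheral sample at the classification visit.
#'
#' @param cohort a `mutdna_cohort` (simulated or loaded from disk).
#' @param config a `pipeline_config`.
#' @return a `mutdna_analysis` list; see Details.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(scenario = cohort$scenario)) {
  sheet <- cohort$sample_sheet
  detections <- call_variants(cohort$variants, technical = config$technical)
  meta_cols <- c("timepoint", "days", "sample_type", "recurrence_days", "recurred")
  detections <- merge(detections,
                      sheet[, c("sample_id", meta_cols)],
                      by = "sample_id", sort = FALSE)
  fluid <- detections[detections$sample_type %in% fluid_types, , drop = FALSE]

  grid <- detection_grid(detections, sheet)

  patients <- unique(sheet$patient)
  tps <- sort(unique(sheet$timepoint[sheet$sample_type %in% fluid_types]))
  presence <- expand.grid(patient = patients, timepoint = tps,
                          stringsAsFactors = FALSE)
  presence$present <- mapply(function(p, tp) patient_presence(fluid, p, tp),
                             presence$patient, presence$timepoint)

  evaluable <- unique(detections$patient)
  cls <- data.frame(patient = patients, stringsAsFactors = FALSE)
  out_by_patient <- sheet[!duplicated(sheet$patient),
                          c("patient", "recurrence_days", "recurred")]
  cls <- merge(cls, out_by_patient, by = "patient")
  cls$evaluable <- cls$patient %in% evaluable
  pm <- match(paste(cls$patient, config$classify_timepoint),
              paste(presence$patient, presence$timepoint))
  cls$present <- presence$present[pm]
  cls$group <- ifelse(!cls$evaluable | is.na(cls$present), "unevaluable",
                      ifelse(cls$present, "present", "absent"))

  ev <- cls[cls$group != "unevaluable", , drop = FALSE]
  tab <- c(tp = sum(ev$group == "present" & ev$recurred),
           fp = sum(ev$group == "present" & !ev$recurred),
           fn = sum(ev$group == "absent" & ev$recurred),
           tn = sum(ev$group == "absent" & !ev$recurred))
  contingency <- contingency_metrics(tab[["tp"]], tab[["fp"]], tab[["fn"]],
                                     tab[["tn"]], conf = config$conf)

  km <- NULL; logrank <- NULL
  if (length(unique(ev$group)) == 2 && sum(ev$recurred) >= 1) {
    km <- km_curve(ev$recurrence_days, ev$recurred, ev$group)
    logrank <- logrank_test(ev$recurrence_days, ev$recurred, ev$group)
  }

  comparisons <- list()
  if (nrow(fluid)) {
    outcome_group <- ifelse(fluid$recurred, "recurred", "recurrence-free")
    if (length(unique(outcome_group)) == 2) {
      comparisons$ks_af <- ks_af_by_group(fluid$af, outcome_group)
      comparisons$by_timepoint <- detection_rate_by_timepoint(
        fluid$detected, outcome_group, fluid$timepoint)
    }
    if (length(unique(fluid$sample_type)) >= 2 && diff(range(fluid$af)) > 0) {
      comparisons$by_sample_type <- af_by_sample_type_test(fluid$af,
                                                           fluid$sample_type)
    }
  }

  tf_est <- estimate_tumour_fraction(fluid)
  tf_recovery <- NULL
  if (!is.null(cohort$truth) && nrow(tf_est)) {
    tf_est <- merge(tf_est,
                    cohort$truth$samples[, c("sample_id", "true_tf")],
                    by = "sample_id")
    if (nrow(tf_est) >= 3 && stats::sd(tf_est$true_tf) > 0) {
      fit <- stats::lm(tf_estimate ~ true_tf, data = tf_est)
      tf_recovery <- list(slope = unname(stats::coef(fit)[2]),
                          intercept = unname(stats::coef(fit)[1]),
                          n = nrow(tf_est))
    }
  }

  cna <- NULL
  if (config$run_cna && length(cohort$bin_counts)) {
    cna <- run_cna_arm(cohort, config)
  }

  structure(list(detections = detections, grid = grid, presence = presence,
                 classification = cls, contingency = contingency,
                 km = km, logrank = logrank, comparisons = comparisons,
                 tf_estimates = tf_est, tf_recovery = tf_recovery,
                 cna = cna, config = config),
            class = "mutdna_analysis")
}

# the sWGS arm: correction, CBS, calls, imbalance score, TUR concordance
run_cna_arm <- function(cohort, config) {
  genome <- cohort$genome
  ids <- names(cohort$bin_counts)
  ctrl_ids <- grep("^CTRL", ids, value = TRUE)
  control <- if (length(ctrl_ids)) {
    pool_controls(cohort$bin_counts[ctrl_ids], genome)
  } else NULL

  test_ids <- setdiff(ids, ctrl_ids)
  profiles <- list(); seg_rows <- list(); sample_rows <- list()
  for (sid in test_ids) {
    prof <- correct_counts(cohort$bin_counts[[sid]], genome, sample_id = sid)
    seg <- segment_profile(prof, alpha = config$cbs_alpha,
                           n_perm = config$cbs_nperm,
                           min_width = config$cbs_min_width,
                           seed = config$seed + 17L)
    seg <- call_segments(seg, k_mad = config$k_mad, min_abs = config$min_abs)
    profiles[[sid]] <- prof
    seg_rows[[sid]] <- cbind(sample_id = sid, seg$segments)
    score <- if (!is.null(control)) {
      imbalance_score(prof, control, frac = config$frac_extreme)
    } else NULL
    sample_rows[[sid]] <- data.frame(
      sample_id = sid, cna_detected = cna_detectable(seg),
      n_segments = nrow(seg$segments), noise = seg$noise,
      imbalance_score = if (is.null(score)) NA_real_ else score$score,
      n_extreme = if (is.null(score)) NA_integer_ else score$n_extreme,
      stringsAsFactors = FALSE)
  }

  # concordance of each fluid profile with the matched tumour (TUR) profile
  conc_rows <- list()
  sheet <- cohort$sample_sheet
  for (sid in test_ids) {
    row <- sheet[sheet$sample_id == sid, , drop = FALSE]
    if (!nrow(row) || !(row$sample_type %in% fluid_types)) next
    tur_id <- sprintf("%s_T0_TUR", row$patient)
    if (!(tur_id %in% names(profiles))) next
    cc <- concordance_r2(profiles[[tur_id]], profiles[[sid]])
    conc_rows[[sid]] <- data.frame(sample_id = sid, patient = row$patient,
                                   timepoint = row$timepoint,
                                   sample_type = row$sample_type,
                                   r2_adj = cc$r2_adj, n = cc$n,
                                   stringsAsFactors = FALSE)
  }

  list(control = control,
       samples = do.call(rbind, unname(sample_rows)),
       segments = do.call(rbind, unname(seg_rows)),
       concordance = do.call(rbind, unname(conc_rows)),
       profiles = profiles)
}

#' Run the full pipeline
#'
#' Simulates or loads the cohort inputs, runs [analyze_cohort()], and (when
#' `config$out_dir` is set) writes the stage outputs: `detections.tsv`,
#' `grid.tsv`, `presence.tsv`, `classification.tsv`, `segments.tsv`,
#' `cna_samples.tsv`, `concordance.tsv`, `km_curve.tsv`, a machine-readable
#' `summary.json` and a human-readable `report.txt`. Fully deterministic
#' under a fixed config; partially written outputs are removed on failure.
#'
#' @param config a `pipeline_config`.
#' @return the `mutdna_analysis`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cohort <- if (!is.null(config$input_dir)) {
    load_cohort_inputs(config$input_dir)
  } else {
    simulate_cohort(config$scenario)
  }
  analysis <- analyze_cohort(cohort, config)
  if (!is.null(config$out_dir)) {
    created <- !dir.exists(config$out_dir)
    tryCatch(
      write_analysis(analysis, config$out_dir),
      error = function(e) {
        if (created) unlink(config$out_dir, recursive = TRUE)
        stop(e)
      }
    )
  }
  invisible(analysis)
}

write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(analysis$detections, "detections.tsv")
  wt(analysis$grid, "grid.tsv")
  wt(analysis$presence, "presence.tsv")
  wt(analysis$classification, "classification.tsv")
  wt(analysis$km, "km_curve.tsv")
  if (!is.null(analysis$cna)) {
    wt(analysis$cna$segments, "segments.tsv")
    wt(analysis$cna$samples, "cna_samples.tsv")
    wt(analysis$cna$concordance, "concordance.tsv")
  }
  jsonlite::write_json(analysis_summary(analysis),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print_report(analysis)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Machine-readable summary of an analysis
#'
#' @param analysis a `mutdna_analysis`.
#' @return nested list suitable for JSON serialisation.
#' @export
analysis_summary <- function(analysis) {
  m <- analysis$contingency
  met <- function(v) list(estimate = v$estimate, lower = v$lower,
                          upper = v$upper, k = v$k, n = v$n,
                          defined = v$defined)
  out <- list(
    counts = as.list(m$counts),
    metrics = list(sensitivity = met(m$sensitivity),
                   specificity = met(m$specificity),
                   ppv = met(m$ppv), npv = met(m$npv)),
    classification = analysis$classification[, c("patient", "group",
                                                 "recurred",
                                                 "recurrence_days")],
    logrank = analysis$logrank[c("chisq", "p")],
    tf_recovery = analysis$tf_recovery
  )
  if (!is.null(analysis$comparisons$ks_af)) {
    out$ks_af <- analysis$comparisons$ks_af[c("statistic", "p")]
  }
  if (!is.null(analysis$comparisons$by_sample_type)) {
    out$kruskal <- analysis$comparisons$by_sample_type$kruskal
  }
  if (!is.null(analysis$cna)) {
    out$cna <- analysis$cna$samples
  }
  out
}

print_report <- function(analysis) {
  cat("mutDNA cohort analysis\n")
  cat("======================\n\n")
  cat(sprintf("patients: %d (%d evaluable for cycle-%d classification)\n",
              nrow(analysis$classification),
              sum(analysis$classification$group != "unevaluable"),
              analysis$config$classify_timepoint))
  print(analysis$contingency)
  if (!is.null(analysis$logrank)) {
    cat(sprintf("log-rank (presence at cycle %d): chisq %.2f, p = %.4g\n",
                analysis$config$classify_timepoint, analysis$logrank$chisq,
                analysis$logrank$p))
  }
  if (!is.null(analysis$tf_recovery)) {
    cat(sprintf("tumour-fraction recovery: slope %.3f over %d samples\n",
                analysis$tf_recovery$slope, analysis$tf_recovery$n))
  }
  if (!is.null(analysis$cna)) {
    cat(sprintf("sWGS arm: %d samples profiled, %d CNA-detectable\n",
                nrow(analysis$cna$samples),
                sum(analysis$cna$samples$cna_detected)))
  }
  invisible(analysis)
}

#' @export
print.mutdna_analysis <- function(x, ...) print_report(x)
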