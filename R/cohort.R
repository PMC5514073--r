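#' Construct a cohort scenario
#'
#' Defines the ground truth for a synthetic longitudinal liquid-biopsy cohort:
#' patients with clonal copy-number/SNV structure, compartment-specific tumour
#' fractions over the chemotherapy course, recurrence outcomes, and the
#' sampling model. The default mirrors the study design the package targets:
#' 17 muscle-invasive bladder cancer patients under neoadjuvant chemotherapy,
#' five on-treatment visits after the initial resection (TUR), three body
#' fluids per visit (plasma PLS, urine cell pellet UCP, urine supernatant
#' USN), and 8 recurrers.
#'
#' Patient trajectory kinds:
#' \describe{
#'   \item{persistent}{tumour fraction stays high throughout (non-responder).}
#'   \item{responder-decay}{tumour fraction decays steeply after the first
#'     cycle, falling below the detection floor by the cycle-2 visit.}
#'   \item{clonal-switch}{two clones with contrasting chemo-sensitivity: the
#'     initially dominant clone recedes while a resistant minor clone expands,
#'     their fractions crossing once.}
#'   \item{mutDNA-absent}{negligible shedding into body fluids; with
#'     `has_snvs = TRUE` the tumour still carries panel SNVs (an evaluable
#'     false negative), with `FALSE` the SNV panel is empty and the patient is
#'     unevaluable for SNV-based classification.}
#' }
#'
#' Urine compartments shed more tumour DNA than plasma in every default
#' archetype (USN >= UCP > PLS), reflecting direct shedding from the bladder.
#'
#' @param n_patients cohort size.
#' @param n_recurrers number of patients with early recurrence.
#' @param timepoint_days days since TUR of the on-treatment visits (strictly
#'   increasing).
#' @param genome optional `genome_bins`; default is an 8-chromosome, 40-bin
#'   1-Mb frame.
#' @param model a `sampling_model` holding depths/noise defaults.
#' @param n_controls number of germline (buffy coat) sWGS samples available
#'   for the pooled control.
#' @param seed integer seed; fixes every downstream draw.
#' @return a `cohort_scenario` list.
#' @export
cohort_scenario <- function(n_patients = 17L, n_recurrers = 8L,
                            timepoint_days = c(30, 51, 72, 93, 114),
                            genome = NULL, model = sampling_model(),
                            n_controls = 8L, seed = 1L) {
  stopifnot(n_patients >= 1, n_recurrers >= 0, n_recurrers <= n_patients)
  if (any(diff(timepoint_days) <= 0) || any(timepoint_days <= 0)) {
    stop("cohort_scenario: timepoint_days must be positive and strictly increasing")
  }
  if (is.null(genome)) {
    genome <- make_genome(n_chrom = 8L, bins_per_chrom = 40L, seed = seed + 101L)
  }
  n_tp <- length(timepoint_days)

  with_seed(seed, {
    archetypes <- assign_archetypes(n_patients, n_recurrers)
    patients <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      a <- archetypes[i, ]
      patients[[i]] <- build_patient(
        id = sprintf("P%02d", i), archetype = a$archetype,
        recurred = a$recurred, has_snvs = a$has_snvs,
        genome = genome, n_tp = n_tp
      )
    }
    structure(list(
      genome = genome, timepoint_days = timepoint_days,
      sample_types = c("PLS", "UCP", "USN"),
      patients = patients, model = model,
      n_controls = as.integer(n_controls), seed = as.integer(seed)
    ), class = "cohort_scenario")
  })
}

# archetype mix for the default cohort: recurrers are mostly persistent
# shedders plus one clonal switch and one low-shedding (false-negative)
# patient; non-recurrers are responders plus SNV-panel-negative patients.
assign_archetypes <- function(n_patients, n_recurrers) {
  rec <- character(0); rec_snv <- logical(0)
  if (n_recurrers > 0) {
    rec <- rep("persistent", n_recurrers)
    if (n_recurrers >= 2) rec[n_recurrers - 1] <- "clonal-switch"
    if (n_recurrers >= 3) rec[n_recurrers] <- "mutDNA-absent"
    rec_snv <- rep(TRUE, n_recurrers)
  }
  n_non <- n_patients - n_recurrers
  non <- character(0); non_snv <- logical(0)
  if (n_non > 0) {
    n_quiet <- min(4L, max(0L, n_non - 1L))
    non <- c(rep("responder-decay", n_non - n_quiet), rep("mutDNA-absent", n_quiet))
    non_snv <- c(rep(TRUE, n_non - n_quiet), rep(FALSE, n_quiet))
  }
  data.frame(archetype = c(rec, non), recurred = rep(c(TRUE, FALSE), c(n_recurrers, n_non)),
             has_snvs = c(rec_snv, non_snv), stringsAsFactors = FALSE)
}

# per-compartment pre-treatment tumour fractions and per-timepoint trajectory
# multipliers; urine >> plasma throughout
archetype_params <- function(archetype, n_tp) {
  base <- switch(archetype,
    "persistent"     = c(PLS = 0.020, UCP = 0.12, USN = 0.18),
    "responder-decay" = c(PLS = 0.006, UCP = 0.025, USN = 0.04),
    "clonal-switch"  = c(PLS = 0.025, UCP = 0.12, USN = 0.20),
    "mutDNA-absent"  = c(PLS = 2e-4, UCP = 8e-4, USN = 1.2e-3),
    stop("unknown archetype: ", archetype)
  )
  traj <- switch(archetype,
    "persistent"     = exp(stats::rnorm(n_tp, 0, 0.15)) * c(1, 0.9, 1.1, 0.8, 1.0)[pmin(1:n_tp, 5)],
    "responder-decay" = c(1, 0.05, 0.01, 0.003, 0.001)[pmin(1:n_tp, 5)],
    "clonal-switch"  = c(1, 0.7, 0.5, 0.9, 1.3)[pmin(1:n_tp, 5)],
    "mutDNA-absent"  = rep(1, n_tp)
  )
  list(base = base, traj = traj)
}

# draw CNA events for one clone: one broad gain, one broad loss, one focal amp
draw_events <- function(genome, avoid_chroms = character(0)) {
  chroms <- setdiff(unique(genome$chrom), avoid_chroms)
  if (!length(chroms)) chroms <- unique(genome$chrom)  # small genomes: allow overlap
  pick <- sample(chroms, min(3, length(chroms)))
  per_chrom <- table(genome$chrom)
  ev <- list()
  mk <- function(chrom, width, cn) {
    n <- as.integer(per_chrom[[chrom]])
    from <- sample.int(max(1, n - width), 1)
    data.frame(chrom = chrom, from_bin = from, to_bin = min(n, from + width - 1),
               cn = cn, stringsAsFactors = FALSE)
  }
  ev[[1]] <- mk(pick[1], sample(10:15, 1), 3L)                 # broad single-copy gain
  if (length(pick) >= 2) ev[[2]] <- mk(pick[2], sample(8:12, 1), 1L)  # broad loss
  if (length(pick) >= 3) ev[[3]] <- mk(pick[3], 2L, 6L)        # focal amplification
  do.call(rbind, ev)
}

# panel SNV loci for one clone, biased towards TP53 as in bladder cancer
draw_snvs <- function(genome, n, prefix) {
  genes <- sample(c("TP53", "TP53", "TP53", "KRAS", "PIK3CA", "BRAF",
                    "CTNNB1", "FGFR3", "NFE2L2"), n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  bin <- sample.int(nrow(genome), n)
  data.frame(
    locus_id = sprintf("%s_%s_%d", prefix, genes, seq_len(n)),
    gene = genes,
    chrom = genome$chrom[bin],
    pos = genome$start[bin] + sample.int(1e6, n),
    ref = ref, alt = alt,
    cell_frac = 1,
    stringsAsFactors = FALSE
  )
}

build_patient <- function(id, archetype, recurred, has_snvs, genome, n_tp) {
  pars <- archetype_params(archetype, n_tp)
  types <- c("PLS", "UCP", "USN")
  tf <- outer(pars$traj, pars$base[types])
  dimnames(tf) <- list(NULL, types)
  tf <- pmin(tf, 0.95)

  if (archetype == "clonal-switch") {
    snv_a <- draw_snvs(genome, 1L, paste0(id, "A")); snv_a$gene <- "TP53"
    snv_b <- draw_snvs(genome, 2L, paste0(id, "B")); snv_b$gene <- c("TP53", "NFE2L2")
    ev_a <- draw_events(genome)
    ev_b <- draw_events(genome, avoid_chroms = unique(ev_a$chrom))
    clones <- list(clone_profile(genome, paste0(id, "_A"), ev_a, snv_a),
                   clone_profile(genome, paste0(id, "_B"), ev_b, snv_b))
    cf <- cbind(A = c(0.95, 0.60, 0.30, 0.08, 0.01)[pmin(1:n_tp, 5)],
                B = c(0.05, 0.40, 0.70, 0.92, 0.99)[pmin(1:n_tp, 5)])
    # within-tumour composition at cystectomy: resistant clone only
    cf_final <- c(A = 0.02, B = 0.98)
  } else {
    n_snv <- if (has_snvs) sample(1:3, 1) else 0L
    snvs <- if (n_snv > 0) draw_snvs(genome, n_snv, id) else NULL
    clones <- list(clone_profile(genome, paste0(id, "_T"), draw_events(genome), snvs))
    cf <- matrix(1, n_tp, 1, dimnames = list(NULL, "T"))
    cf_final <- c(T = 1)
  }

  outcome_days <- if (recurred) round(stats::runif(1, 264, 507)) else round(stats::runif(1, 463, 1008))

  list(id = id, archetype = archetype, recurred = recurred, has_snvs = has_snvs,
       clones = clones, clone_frac = cf, clone_frac_final = cf_final,
       tf = tf, tur_tf = 0.7, outcome_days = outcome_days)
}

#' Simulate a full synthetic cohort
#'
#' Draws every pipeline input from a [cohort_scenario()]: a sample sheet, a
#' per-variant read-count table, per-sample binned read counts for the sWGS
#' arm (TUR, germline controls and the first/last fluid visits, matching the
#' design in which copy-number profiling was applied to the first and final
#' time-points), and a ground-truth ledger (true tumour fractions, clone
#' fractions and per-locus true AFs) for parameter-recovery tests.
#'
#' Identical scenario + seed gives identical output.
#'
#' @param scenario a `cohort_scenario`.
#' @param cna_timepoints indices of fluid visits to profile with sWGS
#'   (default: first and last).
#' @return a `mutdna_cohort` list with elements `genome`, `sample_sheet`,
#'   `variants`, `bin_counts` (named list), `truth`, `scenario`.
#' @export
simulate_cohort <- function(scenario,
                            cna_timepoints = c(1L, length(scenario$timepoint_days))) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  genome <- scenario$genome
  model <- scenario$model
  n_tp <- length(scenario$timepoint_days)
  types <- scenario$sample_types

  with_seed(scenario$seed + 7L, {
    sheet <- list(); vars <- list(); counts <- list()
    truth_samples <- list(); truth_vars <- list(); truth_clones <- list()

    for (p in scenario$patients) {
      panel <- patient_panel(p)
      # tumour (TUR) and germline (BUF) baseline samples at day 0
      for (st in c("TUR", "BUF")) {
        sid <- sprintf("%s_T0_%s", p$id, st)
        sheet[[sid]] <- sample_row(sid, p, 0L, 0, st)
        if (nrow(panel)) {
          cf <- p$clone_frac[1, , drop = TRUE] * (st == "TUR")
          tfs <- if (st == "TUR") p$tur_tf else 0
          vars[[sid]] <- variant_rows(sid, p, panel, tf = tfs, cf = cf, model = model)
          truth_vars[[sid]] <- attr(vars[[sid]], "truth")
        }
        w <- if (st == "TUR") p$tur_tf * p$clone_frac[1, ] else rep(0, length(p$clones))
        counts[[sid]] <- simulate_counts(genome, p$clones, w, model)
        truth_samples[[sid]] <- truth_row(sid, p, 0L, st, sum(w))
        truth_clones[[sid]] <- clone_rows(sid, p, w)
      }
      # fluid visits
      for (tp in seq_len(n_tp)) {
        for (st in types) {
          sid <- sprintf("%s_T%d_%s", p$id, tp, st)
          sheet[[sid]] <- sample_row(sid, p, tp, scenario$timepoint_days[tp], st)
          tf_s <- p$tf[tp, st]
          cf <- p$clone_frac[tp, , drop = TRUE]
          if (nrow(panel)) {
            vars[[sid]] <- variant_rows(sid, p, panel, tf = tf_s, cf = cf, model = model)
            truth_vars[[sid]] <- attr(vars[[sid]], "truth")
          }
          w <- tf_s * cf
          if (tp %in% cna_timepoints) {
            counts[[sid]] <- simulate_counts(genome, p$clones, w, model)
          }
          truth_samples[[sid]] <- truth_row(sid, p, tp, st, tf_s)
          truth_clones[[sid]] <- clone_rows(sid, p, w)
        }
      }
    }
    # germline control sWGS samples for the pooled reference
    for (k in seq_len(scenario$n_controls)) {
      sid <- sprintf("CTRL%02d", k)
      counts[[sid]] <- simulate_counts(genome, list(), numeric(0), model)
    }

    variants <- do.call(rbind, unname(vars)) %||% empty_variants()
    rownames(variants) <- NULL
    cohort <- structure(list(
      genome = genome,
      sample_sheet = do.call(rbind, unname(sheet)),
      variants = variants,
      bin_counts = counts,
      truth = list(
        samples = do.call(rbind, unname(truth_samples)),
        variants = do.call(rbind, unname(truth_vars)),
        clones = do.call(rbind, unname(truth_clones))
      ),
      scenario = scenario
    ), class = "mutdna_cohort")
    rownames(cohort$sample_sheet) <- NULL
    cohort
  })
}

patient_panel <- function(p) {
  sn <- lapply(p$clones, function(cl) {
    if (is.null(cl$snvs)) NULL else cbind(cl$snvs, clone_id = cl$id)
  })
  out <- do.call(rbind, sn)
  if (is.null(out)) {
    out <- data.frame(locus_id = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      cell_frac = numeric(0), clone_id = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

sample_row <- function(sid, p, tp, days, st) {
  data.frame(sample_id = sid, patient = p$id, timepoint = tp, days = days,
             sample_type = st, recurrence_days = p$outcome_days,
             recurred = p$recurred, stringsAsFactors = FALSE)
}

truth_row <- function(sid, p, tp, st, tf) {
  data.frame(sample_id = sid, patient = p$id, timepoint = tp, sample_type = st,
             archetype = p$archetype, true_tf = tf, stringsAsFactors = FALSE)
}

clone_rows <- function(sid, p, w) {
  data.frame(sample_id = sid,
             clone_id = vapply(p$clones, `[[`, character(1), "id"),
             weight = as.numeric(w), stringsAsFactors = FALSE)
}

# simulate the variant read-count rows for one sample; truth attached as attr
variant_rows <- function(sid, p, panel, tf, cf, model) {
  cf_by_clone <- stats::setNames(as.numeric(cf) * tf,
                                 vapply(p$clones, `[[`, character(1), "id"))
  true_af <- cf_by_clone[panel$clone_id] * panel$cell_frac / 2
  true_af[is.na(true_af)] <- 0
  ge <- 10^stats::runif(1, 2, 5)  # log-uniform over [100, 1e5] genomic equivalents
  m <- model; m$genomic_equivalents <- ge
  reads <- simulate_variant_reads(pmin(true_af, 1), m)
  out <- data.frame(sample_id = sid, patient = p$id,
                    locus_id = panel$locus_id, gene = panel$gene,
                    chrom = panel$chrom, pos = panel$pos,
                    ref = panel$ref, alt = panel$alt,
                    depth = reads$depth, alt_reads = reads$alt_reads,
                    af = reads$af, genomic_equivalents = reads$genomic_equivalents,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(sample_id = sid, locus_id = panel$locus_id,
                                   true_af = as.numeric(true_af),
                                   stringsAsFactors = FALSE)
  out
}

empty_variants <- function() {
  data.frame(sample_id = character(0), patient = character(0),
             locus_id = character(0), gene = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             depth = integer(0), alt_reads = integer(0), af = numeric(0),
             genomic_equivalents = numeric(0), stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard pipeline input files: `sample_sheet.tsv`,
#' `variants.tsv`, `genome_bins.tsv`, one BED-style bin-count TSV per sWGS
#' sample under `counts/`, and `truth.json` with the ground-truth ledger.
#'
#' @param cohort a `mutdna_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "counts"), recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(cohort$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  write_tsv(as.data.frame(cohort$genome), file.path(dir, "genome_bins.tsv"))
  for (sid in names(cohort$bin_counts)) {
    df <- data.frame(chrom = cohort$genome$chrom, start = cohort$genome$start,
                     end = cohort$genome$end, count = cohort$bin_counts[[sid]])
    write_tsv(df, file.path(dir, "counts", paste0(sid, ".tsv")))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

#' Read pipeline input tables
#'
#' Readers for the TSV formats emitted by [write_cohort()] (or produced by an
#' upstream counting step). `read_bin_counts` checks bin frame agreement when
#' a genome is supplied.
#'
#' @param path file path.
#' @param genome optional `genome_bins` to validate coordinates against.
#' @return `read_sample_sheet`/`read_variants`/`read_genome_bins` return
#'   data.frames; `read_bin_counts` returns the integer count vector.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_sample_sheet
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_sample_sheet
#' @export
read_genome_bins <- function(path) {
  if (!file.exists(path)) stop("genome bin table not found: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  g$blacklisted <- as.logical(g$blacklisted)
  class(g) <- c("genome_bins", "data.frame")
  g
}

#' @rdname read_sample_sheet
#' @export
read_bin_counts <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("bin-count file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    if (nrow(df) != nrow(genome) ||
        !all(df$chrom == genome$chrom & df$start == genome$start)) {
      stop("bin-count file does not match the genome bin frame: ", path)
    }
  }
  df$count
}
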