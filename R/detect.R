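#' Dual-threshold mutant-AF detection threshold
#'
#' The allele-fraction threshold applied to each variant observation is the
#' higher of the technical floor (0.5\%, below which background substitution
#' noise becomes indistinguishable from signal) and the sampling floor
#' `1 / genomic_equivalents` (one mutant molecule among the amplifiable
#' template copies input to the reaction).
#'
#' @param genomic_equivalents amplifiable template copies per reaction (> 0);
#'   vectorised.
#' @param technical technical AF floor (default 0.005).
#' @return AF threshold(s).
#' @examples
#' detection_threshold(2000) # 0.005: technical floor binds
#' detection_threshold(50)   # 0.02:  sampling floor binds
#' @export
detection_threshold <- function(genomic_equivalents, technical = 0.005) {
  if (any(genomic_equivalents <= 0)) {
    stop("detection_threshold: genomic_equivalents must be > 0")
  }
  pmax(technical, 1 / genomic_equivalents)
}

#' Call a single variant observation
#'
#' A variant is detected when its AF strictly exceeds
#' [detection_threshold()]. The AF is returned regardless of the call so
#' longitudinal kinetics can be interpreted below threshold.
#'
#' @param depth total reads at the locus.
#' @param alt_reads mutant-supporting reads.
#' @param genomic_equivalents template copies input to the reaction.
#' @param technical technical AF floor.
#' @return a `detection_result` list: `detected`, `af`, `threshold_used`,
#'   `technical_threshold`, `sample_threshold`.
#' @export
call_variant <- function(depth, alt_reads, genomic_equivalents,
                         technical = 0.005) {
  stopifnot(depth > 0, alt_reads >= 0, alt_reads <= depth)
  af <- alt_reads / depth
  thr <- detection_threshold(genomic_equivalents, technical)
  structure(list(detected = af > thr, af = af, threshold_used = thr,
                 technical_threshold = technical,
                 sample_threshold = 1 / genomic_equivalents),
            class = "detection_result")
}

#' Apply the detection rule to a variant table
#'
#' Vectorised [call_variant()] over a variant read-count table (as emitted by
#' the cohort simulator or read from TSV): adds `af`, `threshold` and
#' `detected` columns.
#'
#' @param variants data.frame with columns `depth`, `alt_reads`,
#'   `genomic_equivalents` (and any identifying columns, carried through).
#' @param technical technical AF floor.
#' @return the input with `af`, `threshold`, `detected` columns added.
#' @export
call_variants <- function(variants, technical = 0.005) {
  need <- c("depth", "alt_reads", "genomic_equivalents")
  if (!all(need %in% names(variants))) {
    stop("call_variants: variant table must have columns ",
         paste(need, collapse = ", "))
  }
  variants$af <- variants$alt_reads / variants$depth
  variants$threshold <- detection_threshold(variants$genomic_equivalents, technical)
  variants$detected <- variants$af > variants$threshold
  variants
}

fluid_types <- c("PLS", "UCP", "USN")

#' Patient-level mutDNA presence at a timepoint
#'
#' mutDNA is present when any variant is detected in any available peripheral
#' sample type (PLS/UCP/USN) at the timepoint; absent when samples were
#' tested and all fell below threshold. When no peripheral sample is
#' available the timepoint is unevaluable (`NA`) — missingness never counts
#' as a negative.
#'
#' @param detections a called variant table (see [call_variants()]) with
#'   `patient`, `timepoint` and `sample_type` columns (rows exist only for
#'   samples actually assayed).
#' @param patient patient id.
#' @param timepoint timepoint index.
#' @param sample_types sample types considered peripheral.
#' @return `TRUE`, `FALSE`, or `NA` (unevaluable).
#' @export
patient_presence <- function(detections, patient, timepoint,
                             sample_types = fluid_types) {
  rows <- detections$patient == patient &
    detections$timepoint == timepoint &
    detections$sample_type %in% sample_types
  if (!any(rows)) return(NA)
  any(detections$detected[rows])
}

#' Maximum AF per timepoint for one sample type
#'
#' The per-visit maximum AF across a patient's panel variants in one sample
#' type — the summary used to display mutDNA kinetics. Visits with no assayed
#' sample of that type stay `NA`.
#'
#' @param detections called variant table with `patient`, `timepoint`,
#'   `sample_type`, `af`.
#' @param patient patient id.
#' @param sample_type one of the peripheral types.
#' @param timepoints timepoint indices to report (default: all fluid visits
#'   observed for the patient).
#' @return named numeric vector of max AF per timepoint (NA where missing).
#' @export
max_af_per_timepoint <- function(detections, patient, sample_type,
                                 timepoints = NULL) {
  d <- detections[detections$patient == patient &
                    detections$sample_type == sample_type, , drop = FALSE]
  if (is.null(timepoints)) {
    tps <- sort(unique(detections$timepoint[detections$patient == patient &
                                              detections$sample_type %in% fluid_types]))
  } else {
    tps <- timepoints
  }
  out <- vapply(tps, function(tp) {
    af <- d$af[d$timepoint == tp]
    if (!length(af)) NA_real_ else max(af)
  }, numeric(1))
  stats::setNames(out, tps)
}

#' Cohort detection grid
#'
#' Long-format grid of every (patient, variant, timepoint, sample type) cell
#' with status `detected`, `tested-negative`, or `missing` — the table behind
#' the cohort detection heat-grid. The full grid is spanned by each patient's
#' panel variants, all fluid timepoints in the sample sheet, and the three
#' peripheral sample types; cells without an assayed sample are `missing`.
#'
#' @param detections called variant table.
#' @param sample_sheet cohort sample sheet (defines which samples exist).
#' @param sample_types peripheral types spanning the grid.
#' @return data.frame `patient`, `locus_id`, `gene`, `timepoint`,
#'   `sample_type`, `status`, `af`.
#' @export
detection_grid <- function(detections, sample_sheet,
                           sample_types = fluid_types) {
  fluid_sheet <- sample_sheet[sample_sheet$sample_type %in% sample_types, ,
                              drop = FALSE]
  if (!nrow(fluid_sheet) || !nrow(detections)) {
    return(data.frame(patient = character(0), locus_id = character(0),
                      gene = character(0), timepoint = integer(0),
                      sample_type = character(0), status = character(0),
                      af = numeric(0), stringsAsFactors = FALSE))
  }
  panels <- unique(detections[, c("patient", "locus_id", "gene")])
  tps <- sort(unique(fluid_sheet$timepoint))
  grid <- merge(panels,
                expand.grid(timepoint = tps, sample_type = sample_types,
                            stringsAsFactors = FALSE))
  key <- function(df) paste(df$patient, df$timepoint, df$sample_type)
  available <- unique(key(fluid_sheet))
  dkey <- paste(detections$patient, detections$timepoint,
                detections$sample_type, detections$locus_id)
  gkey <- paste(grid$patient, grid$timepoint, grid$sample_type, grid$locus_id)
  m <- match(gkey, dkey)
  grid$af <- ifelse(is.na(m), NA_real_, detections$af[m])
  det <- !is.na(m) & detections$detected[ifelse(is.na(m), 1L, m)]
  grid$status <- ifelse(!(key(grid) %in% available) | is.na(m), "missing",
                        ifelse(det, "detected", "tested-negative"))
  grid[order(grid$patient, grid$locus_id, grid$timepoint, grid$sample_type), ]
}

#' Estimate tumour fraction from SNV allele fractions
#'
#' Simple clonal estimator: assuming panel variants are clonal and
#' heterozygous at copy-neutral loci, the tumour fraction of a sample is
#' twice its mean panel AF. Used for parameter-recovery checks against the
#' simulator's ground truth.
#'
#' @param variants called (or raw) variant table for one or more samples,
#'   with `sample_id` and `af` columns.
#' @return data.frame `sample_id`, `tf_estimate`.
#' @export
estimate_tumour_fraction <- function(variants) {
  if (!nrow(variants)) {
    return(data.frame(sample_id = character(0), tf_estimate = numeric(0)))
  }
  af <- tapply(variants$af, variants$sample_id, mean)
  data.frame(sample_id = names(af), tf_estimate = pmin(1, 2 * as.numeric(af)),
             stringsAsFactors = FALSE)
}
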