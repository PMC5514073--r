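#' Expected read-count factor for a tumour/germline mixture
#'
#' Relative expected coverage of a bin carrying tumour copy number `cn` in a
#' sample with tumour fraction `tf`, against a diploid germline background:
#' `1 + tf * (cn/2 - 1)`. Neutral bins (`cn = 2`) give 1 at any tumour
#' fraction.
#'
#' @param cn integer copy number (>= 0; 2 is diploid baseline).
#' @param tf tumour fraction in `[0, 1]`.
#' @return multiplicative coverage factor (vectorised).
#' @examples
#' expected_bin_factor(4, 1)    # 2: pure tumour, doubled
#' expected_bin_factor(3, 0.05) # 1.025
#' @export
expected_bin_factor <- function(cn, tf) {
  if (any(cn < 0)) stop("expected_bin_factor: cn must be >= 0")
  if (any(tf < 0 | tf > 1)) stop("expected_bin_factor: tf must be in [0, 1]")
  1 + tf * (cn / 2 - 1)
}

#' GC bias curve used by the read-count simulator
#'
#' Smooth unimodal (quadratic) coverage bias peaking at `peak` GC fraction —
#' the typical shape of PCR/sequencing GC bias in shallow WGS libraries. The
#' exact form is deliberately simple: the correction stage must remove it
#' whatever it is.
#'
#' @param gc GC fraction in `[0, 1]`.
#' @param peak GC value of maximum efficiency.
#' @param strength curvature of the bias.
#' @return relative efficiency (floored at 0.05).
#' @export
gc_bias <- function(gc, peak = 0.45, strength = 8) {
  pmax(0.05, 1 - strength * (gc - peak)^2)
}

#' Sampling model for one sequencing experiment
#'
#' Bundles the knobs that determine how much signal and noise a simulated
#' sample carries. Defaults follow the study conditions the package models:
#' ~13.6 million sWGS reads per sample, 7600x amplicon depth for SNVs, and a
#' per-reaction number of amplifiable template molecules (genomic equivalents,
#' GE) as quantified by dPCR.
#'
#' @param total_reads expected total sWGS read count over all bins.
#' @param variant_depth amplicon sequencing depth at SNV loci.
#' @param genomic_equivalents amplifiable template molecules per reaction.
#' @param error_rate symmetric per-base background substitution rate.
#' @param overdispersion negative-binomial overdispersion of bin counts
#'   (variance = mu + overdispersion * mu^2); 0 gives Poisson counts.
#' @param gc_peak,gc_strength parameters of [gc_bias()].
#' @return a `sampling_model` list.
#' @export
sampling_model <- function(total_reads = 13.6e6, variant_depth = 7600,
                           genomic_equivalents = 5000, error_rate = 1e-4,
                           overdispersion = 4e-4, gc_peak = 0.45,
                           gc_strength = 8) {
  stopifnot(total_reads > 0, variant_depth > 0, genomic_equivalents > 0,
            error_rate >= 0, error_rate <= 1, overdispersion >= 0)
  structure(list(total_reads = total_reads, variant_depth = variant_depth,
                 genomic_equivalents = genomic_equivalents,
                 error_rate = error_rate, overdispersion = overdispersion,
                 gc_peak = gc_peak, gc_strength = gc_strength),
            class = "sampling_model")
}

#' Define a tumour clone
#'
#' A clone is an integer copy-number profile over the genome bins (diploid
#' outside its declared events) plus a set of SNVs, each with a cellular
#' fraction (fraction of tumour cells carrying it).
#'
#' @param genome a `genome_bins` frame.
#' @param id clone label.
#' @param events NULL or a data.frame with columns `chrom`, `from_bin`,
#'   `to_bin` (1-based bin indices within the chromosome) and `cn`.
#' @param snvs NULL or a data.frame with columns `locus_id`, `gene`,
#'   `cell_frac` (in (0, 1]).
#' @return a `clone_profile` list with fields `id`, `cn`, `snvs`.
#' @export
clone_profile <- function(genome, id, events = NULL, snvs = NULL) {
  cn <- rep(2L, nrow(genome))
  if (!is.null(events) && nrow(events)) {
    for (k in seq_len(nrow(events))) {
      idx <- which(genome$chrom == events$chrom[k])
      if (!length(idx)) stop("clone_profile: unknown chromosome ", events$chrom[k])
      span <- idx[events$from_bin[k]:events$to_bin[k]]
      cn[span] <- as.integer(events$cn[k])
    }
  }
  if (any(cn < 0)) stop("clone_profile: copy numbers must be >= 0")
  if (!is.null(snvs) && nrow(snvs) &&
      any(snvs$cell_frac <= 0 | snvs$cell_frac > 1)) {
    stop("clone_profile: cell_frac must be in (0, 1]")
  }
  structure(list(id = id, cn = cn, snvs = snvs), class = "clone_profile")
}

#' Expected per-bin read counts for a clone mixture
#'
#' Analytic mean of the count model: expected count is proportional to
#' mappability x GC bias x the mixture coverage factor, rescaled so the
#' expectations sum to `model$total_reads`. Clone weights are the tumour
#' fractions contributed by each clone; the remainder `1 - sum(weights)` is
#' diploid germline.
#'
#' @param genome `genome_bins` frame.
#' @param clones list of `clone_profile`s.
#' @param weights numeric vector of clone tumour fractions (sum <= 1).
#' @param model a `sampling_model`.
#' @return numeric vector of expected counts (one per bin, blacklisted bins
#'   included — they are filtered downstream, not here).
#' @export
expected_counts <- function(genome, clones, weights, model) {
  if (nrow(genome) == 0) stop("expected_counts: empty genome")
  if (length(clones) != length(weights)) {
    stop("expected_counts: one weight per clone required")
  }
  if (any(weights < 0)) stop("expected_counts: negative clone weights")
  if (sum(weights) > 1 + 1e-12) stop("expected_counts: clone weights must sum to <= 1")
  factor <- rep(1 - sum(weights), nrow(genome))
  for (k in seq_along(clones)) {
    factor <- factor + weights[k] * (clones[[k]]$cn / 2)
  }
  # factor = 1 + sum_k w_k (cn_k/2 - 1)
  e <- genome$mappability * gc_bias(genome$gc, model$gc_peak, model$gc_strength) * factor
  e / sum(e) * model$total_reads
}

#' Simulate per-bin raw read counts
#'
#' Draws overdispersed counts around [expected_counts()]: negative binomial
#' with `size = 1/overdispersion` (Poisson when `overdispersion = 0`).
#' Blacklisted bins are still emitted; exclusion happens in the correction
#' stage.
#'
#' @inheritParams expected_counts
#' @param seed optional integer seed for a reproducible draw.
#' @return integer vector of counts, one per genome bin.
#' @export
simulate_counts <- function(genome, clones, weights, model, seed = NULL) {
  mu <- expected_counts(genome, clones, weights, model)
  with_seed(seed, {
    if (model$overdispersion <= 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / model$overdispersion)
    }
  })
}

#' Simulate sequencing reads at a variant locus
#'
#' Two-stage molecular bottleneck: the number of mutant template molecules in
#' the reaction is Binomial(GE, true_af); sequencing then resamples reads from
#' that finite molecule pool at `variant_depth`, with a symmetric per-base
#' substitution error `error_rate` (a wild-type read misread as mutant and
#' vice versa). This makes the 1/GE sampling floor of low-input reactions
#' explicit: with few genomic equivalents a low-AF variant is often absent
#' from the reaction altogether.
#'
#' @param true_af true mutant allele fraction(s) in the extracted DNA, in
#'   `[0, 1]`; vectorised over loci.
#' @param model a `sampling_model` (uses `genomic_equivalents`,
#'   `variant_depth`, `error_rate`).
#' @param seed optional integer seed.
#' @return data.frame with one row per locus: `depth`, `alt_reads`, `af`,
#'   `genomic_equivalents`.
#' @export
simulate_variant_reads <- function(true_af, model, seed = NULL) {
  ge <- model$genomic_equivalents
  depth <- model$variant_depth
  if (ge <= 0 || depth <= 0) {
    stop("simulate_variant_reads: depth and genomic_equivalents must be > 0")
  }
  if (any(true_af < 0 | true_af > 1)) {
    stop("simulate_variant_reads: true_af must be in [0, 1]")
  }
  n <- length(true_af)
  with_seed(seed, {
    ge_int <- max(1L, round(ge))
    mutant_mols <- stats::rbinom(n, ge_int, true_af)
    af_pool <- mutant_mols / ge_int
    e <- model$error_rate
    p_alt <- af_pool * (1 - e) + (1 - af_pool) * e
    alt <- stats::rbinom(n, depth, p_alt)
    data.frame(depth = depth, alt_reads = alt, af = alt / depth,
               genomic_equivalents = ge_int)
  })
}
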