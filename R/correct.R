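#' GC/mappability-correct binned read counts
#'
#' Turns raw per-bin counts into a median-centred log2-ratio profile:
#' blacklisted and poorly mappable bins are invalidated, counts (plus a 0.5
#' pseudocount to handle zeros) are divided by a smoothed GC-bias estimate —
#' a local-median fit of count versus GC in 20 equal-frequency GC bins with
#' linear interpolation — then by mappability, and finally expressed as log2
#' of the ratio to the sample median over valid bins. The median of the
#' resulting log2 ratios over valid bins is exactly 0.
#'
#' @param counts integer vector of raw counts aligned to `genome`.
#' @param genome a `genome_bins` frame.
#' @param sample_id label carried through to outputs.
#' @param n_gc_bins number of equal-frequency GC strata for the bias fit.
#' @param min_mappability bins below this mappability are invalidated.
#' @param pseudocount added to counts before ratios/logs.
#' @return a `corrected_profile`: list with `sample_id`, `log2ratio` (NA on
#'   invalid bins), `valid`, `bins`.
#' @export
correct_counts <- function(counts, genome, sample_id = "sample",
                           n_gc_bins = 20, min_mappability = 0.5,
                           pseudocount = 0.5) {
  if (length(counts) != nrow(genome)) {
    stop("correct_counts: counts length does not match the genome bin frame")
  }
  if (all(counts == 0)) stop("correct_counts: all counts are zero")
  valid <- valid_bins(genome, min_mappability)
  x <- counts + pseudocount
  fit <- gc_median_fit(x[valid], genome$gc[valid], n_gc_bins)
  corr <- x / fit(genome$gc) / pmax(genome$mappability, 1e-6)
  med <- stats::median(corr[valid])
  l2 <- log2(corr / med)
  l2[!valid] <- NA_real_
  structure(list(sample_id = sample_id, log2ratio = l2, valid = valid,
                 bins = genome),
            class = "corrected_profile")
}

# local-median fit of count vs GC: medians in equal-frequency GC strata,
# linearly interpolated between stratum centres, flat beyond the range
gc_median_fit <- function(x, gc, n_bins) {
  if (diff(range(gc)) < 1e-9) {
    m <- stats::median(x)
    return(function(g) rep(m, length(g)))
  }
  breaks <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = n_bins + 1)))
  grp <- cut(gc, breaks, include.lowest = TRUE)
  centers <- tapply(gc, grp, stats::median)
  meds <- tapply(x, grp, stats::median)
  ok <- !is.na(centers) & !is.na(meds) & meds > 0
  if (sum(ok) < 2) {
    m <- stats::median(x)
    return(function(g) rep(m, length(g)))
  }
  stats::approxfun(centers[ok], meds[ok], rule = 2)
}

#' @export
print.corrected_profile <- function(x, ...) {
  cat(sprintf("corrected_profile '%s': %d bins (%d valid), log2 MAD %.3f\n",
              x$sample_id, length(x$log2ratio), sum(x$valid),
              stats::mad(x$log2ratio[x$valid])))
  invisible(x)
}

#' Export a corrected profile as a BED-style table
#'
#' @param profile a `corrected_profile`.
#' @return data.frame with `chrom`, `start`, `end`, `log2ratio`, `valid`.
#' @export
profile_table <- function(profile) {
  data.frame(chrom = profile$bins$chrom, start = profile$bins$start,
             end = profile$bins$end, log2ratio = profile$log2ratio,
             valid = profile$valid, stringsAsFactors = FALSE)
}
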