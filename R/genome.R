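#' Build a binned reference genome frame
#'
#' Creates the shared bin frame used by both the cohort simulator and the
#' copy-number pipeline: equal-width, non-overlapping autosomal bins with
#' per-bin GC fraction, mappability and a blacklist flag. Coordinates are
#' 0-based half-open (BED convention); bin identity is `(chrom, start)`.
#'
#' GC content is drawn from a smooth, spatially autocorrelated field rescaled
#' to `[0.3, 0.6]`, mimicking the slowly varying base composition seen along
#' real chromosomes. Mappability sits near 1 for most bins with a small
#' fraction of poorly mappable bins (< 0.5, excluded downstream), and roughly
#' 1\% of bins are flagged blacklisted (the ENCODE-style exclusion list).
#'
#' @param n_chrom number of (autosomal) chromosomes.
#' @param bins_per_chrom bins per chromosome.
#' @param bin_width bin width in bp (default 1 Mb).
#' @param seed integer seed; the same seed always yields a byte-identical
#'   bin table.
#' @param blacklist_frac expected fraction of blacklisted bins.
#' @return a `genome_bins` data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `mappability`, `blacklisted`.
#' @examples
#' g <- make_genome(n_chrom = 2, bins_per_chrom = 10, seed = 1)
#' all(g$end - g$start == 1e6)
#' @export
make_genome <- function(n_chrom = 22L, bins_per_chrom = 130L, bin_width = 1e6,
                        seed = 1L, blacklist_frac = 0.01) {
  if (n_chrom < 1 || bins_per_chrom < 1 || bin_width <= 0) {
    stop("make_genome: n_chrom, bins_per_chrom and bin_width must be positive")
  }
  with_seed(seed, {
    per_chrom <- lapply(seq_len(n_chrom), function(ch) {
      start <- (seq_len(bins_per_chrom) - 1) * bin_width
      gc <- smooth_field(bins_per_chrom, lo = 0.3, hi = 0.6)
      mapp <- pmin(1, pmax(0, 1 - stats::rexp(bins_per_chrom, rate = 40)))
      low <- stats::runif(bins_per_chrom) < 0.02
      if (any(low)) mapp[low] <- stats::runif(sum(low), 0.1, 0.45)
      data.frame(
        chrom = paste0("chr", ch),
        start = start,
        end = start + bin_width,
        gc = gc,
        mappability = mapp,
        blacklisted = FALSE,
        stringsAsFactors = FALSE
      )
    })
    bins <- do.call(rbind, per_chrom)
    rownames(bins) <- NULL
    bins$blacklisted <- stats::runif(nrow(bins)) < blacklist_frac
    class(bins) <- c("genome_bins", "data.frame")
    bins
  })
}

# smooth autocorrelated field rescaled into [lo, hi]: integrated white noise
# passed through a short moving average
smooth_field <- function(n, lo, hi) {
  z <- cumsum(stats::rnorm(n))
  if (n >= 5) z <- as.numeric(stats::filter(z, rep(1 / 5, 5), circular = TRUE))
  r <- range(z)
  if (diff(r) < 1e-12) return(rep((lo + hi) / 2, n))
  lo + (z - r[1]) / diff(r) * (hi - lo)
}

# bins usable for copy-number analysis
valid_bins <- function(genome, min_mappability = 0.5) {
  !genome$blacklisted & genome$mappability >= min_mappability
}
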