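# shared fixtures and independent oracles, built in code at test time

# idealised genome: uniform GC and mappability, nothing blacklisted, so
# correction is a no-op and profiles can be constructed exactly
flat_genome <- function(n_chrom = 1, bins_per_chrom = 100, bin_width = 1e6) {
  g <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    start <- (seq_len(bins_per_chrom) - 1) * bin_width
    data.frame(chrom = paste0("chr", ch), start = start, end = start + bin_width,
               gc = 0.45, mappability = 1, blacklisted = FALSE,
               stringsAsFactors = FALSE)
  }))
  class(g) <- c("genome_bins", "data.frame")
  g
}

# wrap a log2-ratio vector as a corrected_profile without going through counts
as_profile <- function(log2ratio, genome = flat_genome(1, length(log2ratio)),
                       sample_id = "test", valid = rep(TRUE, length(log2ratio))) {
  structure(list(sample_id = sample_id, log2ratio = log2ratio, valid = valid,
                 bins = genome), class = "corrected_profile")
}

# exhaustive best-split recursive changepoint oracle for noiseless profiles:
# at each region, enumerate every circular arc (i, j] and take the one with
# the largest residual-sum-of-squares reduction when fit with two means;
# split whenever the reduction is materially positive, recurse. Independent
# of the package CBS code path.
oracle_breakpoints <- function(x, min_width = 2, tol = 1e-9) {
  recurse <- function(x, offset) {
    n <- length(x)
    if (n < 2 * min_width) return(integer(0))
    best <- NULL; best_red <- tol
    for (i in 0:(n - 1)) {
      for (j in (i + 1):n) {
        k <- j - i
        if (k < min_width || (n - k) < min_width) next
        arc <- x[(i + 1):j]; rest <- x[-((i + 1):j)]
        red <- sum((x - mean(x))^2) -
          sum((arc - mean(arc))^2) - sum((rest - mean(rest))^2)
        if (red > best_red) { best_red <- red; best <- c(i, j) }
      }
    }
    if (is.null(best)) return(integer(0))
    bps <- best[best > 0 & best < n]
    out <- offset + bps
    bounds <- c(0, sort(bps), n)
    for (s in seq_len(length(bounds) - 1)) {
      lo <- bounds[s] + 1; hi <- bounds[s + 1]
      out <- c(out, recurse(x[lo:hi], offset + lo - 1))
    }
    sort(unique(out))
  }
  recurse(x, 0)
}

# random noiseless piecewise-constant profile with distinct segment levels
random_step_profile <- function(n_seg, min_seg = 8, total = 60) {
  widths <- rep(min_seg, n_seg)
  extra <- total - sum(widths)
  if (extra > 0) {
    add <- table(factor(sample.int(n_seg, extra, replace = TRUE),
                        levels = seq_len(n_seg)))
    widths <- widths + as.integer(add)
  }
  levels <- sample(c(-1.1, -0.6, 0, 0.58, 1.2))[seq_len(n_seg)]
  list(x = rep(levels, widths), breaks = cumsum(widths)[-n_seg])
}

# hand product-limit / log-rank oracles (direct risk-table arithmetic)
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  g1 <- levels(group)[1]
  O_E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O_E <- O_E + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O_E^2 / V
}

small_cohort <- function(seed = 2, run_cna = FALSE) {
  sc <- cohort_scenario(n_patients = 6, n_recurrers = 3,
                        genome = make_genome(4, 30, seed = seed + 1),
                        seed = seed)
  list(scenario = sc, cohort = simulate_cohort(sc))
}
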