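#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion from Beta quantiles:
#' lower = `qbeta(a/2, k, n-k+1)` (0 when k = 0), upper =
#' `qbeta(1-a/2, k+1, n-k)` (1 when k = n), with `a = 1 - conf`.
#'
#' @param k successes (0..n).
#' @param n trials (>= 1).
#' @param conf confidence level.
#' @return numeric `c(lower, upper)`.
#' @examples
#' clopper_pearson(5, 6)  # c(0.359, 0.996): prints as 36-100%
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("clopper_pearson: require integer 0 <= k <= n, n >= 1")
  }
  a <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Detection-vs-outcome contingency metrics
#'
#' Sensitivity, specificity, PPV and NPV of a binary detection rule against a
#' binary outcome, from the 2x2 counts, each with an exact Clopper-Pearson
#' confidence interval. A metric whose denominator is zero is flagged
#' undefined (`NA` estimate, `defined = FALSE`) rather than silently set
#' to 0.
#'
#' @param tp,fp,fn,tn the 2x2 counts (detected/not x outcome/not).
#' @param conf confidence level for the intervals.
#' @return a `contingency_metrics` list: `counts`, `conf`, and per-metric
#'   sublists (`estimate`, `lower`, `upper`, `k`, `n`, `defined`).
#' @examples
#' m <- contingency_metrics(tp = 5, fp = 0, fn = 1, tn = 6)
#' round(100 * m$sensitivity$estimate, 1)  # 83.3
#' @export
contingency_metrics <- function(tp, fp, fn, tn, conf = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency_metrics: counts must be non-negative integers")
  }
  prop <- function(k, n) {
    if (n == 0) {
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  k = k, n = n, defined = FALSE))
    }
    ci <- clopper_pearson(k, n, conf)
    list(estimate = k / n, lower = ci[["lower"]], upper = ci[["upper"]],
         k = k, n = n, defined = TRUE)
  }
  structure(list(
    counts = counts, conf = conf,
    sensitivity = prop(tp, tp + fn),
    specificity = prop(tn, tn + fp),
    ppv = prop(tp, tp + fp),
    npv = prop(tn, tn + fn)
  ), class = "contingency_metrics")
}

#' @export
print.contingency_metrics <- function(x, ...) {
  cat(sprintf("2x2 counts: tp=%d fp=%d fn=%d tn=%d (conf %.0f%%)\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"],
              100 * x$conf))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    if (!v$defined) {
      cat(sprintf("  %-12s undefined (0 denominator)\n", m))
    } else {
      cat(sprintf("  %-12s %s%% (%d/%d; CI %.0f-%.0f%%)\n", m,
                  fmt_pct(v$estimate), v$k, v$n,
                  round_half_up(100 * v$lower), round_half_up(100 * v$upper)))
    }
  }
  invisible(x)
}

#' Kaplan-Meier curves by group
#'
#' Product-limit estimate of recurrence-free survival per group (right
#' censoring), via `survival::survfit`. Returned tidy: one row per step and
#' group.
#'
#' @param time follow-up time in days (> 0).
#' @param event 1/TRUE = event (recurrence), 0/FALSE = censored.
#' @param group group label per subject (e.g. mutDNA present/absent).
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(time, event, group) {
  if (any(time <= 0)) stop("km_curve: times must be > 0")
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("km_curve: empty group")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance, p-value from
#' chi-square(1); wraps `survival::survdiff`.
#'
#' @inheritParams km_curve
#' @return list with `chisq`, `p`, `n`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("logrank_test: exactly two non-empty groups required")
  }
  if (sum(event) < 1) stop("logrank_test: at least one event required")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = length(time), observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Compare AF distributions between outcome groups (Kolmogorov-Smirnov)
#'
#' Two-sample KS test on the empirical cumulative AF distributions of two
#' groups (e.g. recurrers vs non-recurrers).
#'
#' @param af numeric allele fractions.
#' @param group two-level grouping.
#' @return list with `statistic`, `p`, group sizes.
#' @export
ks_af_by_group <- function(af, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) stop("ks_af_by_group: exactly two groups required")
  sp <- split(af, group)
  kt <- suppressWarnings(stats::ks.test(sp[[1]], sp[[2]]))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       n = vapply(sp, length, integer(1)))
}

#' Per-timepoint detection-rate comparison with Bonferroni correction
#'
#' At each timepoint, a 2x2 chi-squared test (no continuity correction, see
#' `correct`) of detected/not-detected counts between two outcome groups;
#' p-values Bonferroni-adjusted over the timepoints tested.
#'
#' @param detected logical detection outcomes (one per analysis).
#' @param group two-level outcome group per analysis.
#' @param timepoint timepoint index per analysis.
#' @param correct continuity correction (default FALSE).
#' @return data.frame `timepoint`, `chisq`, `p_raw`, `p_bonferroni`.
#' @export
detection_rate_by_timepoint <- function(detected, group, timepoint,
                                        correct = FALSE) {
  tps <- sort(unique(timepoint))
  rows <- lapply(tps, function(tp) {
    sel <- timepoint == tp
    tab <- table(factor(group[sel]), factor(detected[sel], levels = c(FALSE, TRUE)))
    if (nrow(tab) < 2) {
      return(data.frame(timepoint = tp, chisq = NA_real_, p_raw = NA_real_))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    data.frame(timepoint = tp, chisq = unname(ct$statistic),
               p_raw = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * sum(!is.na(out$p_raw)))
  out
}

#' Compare AFs across sample types (Kruskal-Wallis + Dunn)
#'
#' Kruskal-Wallis rank-sum test across the peripheral sample types, followed
#' by Dunn's pairwise z-tests on mean ranks with Bonferroni family-wise
#' adjustment over the pairs.
#'
#' @param af numeric allele fractions.
#' @param sample_type grouping (PLS/UCP/USN).
#' @return list with `kruskal` (statistic, df, p) and `dunn` (data.frame of
#'   pairwise comparisons).
#' @export
af_by_sample_type_test <- function(af, sample_type) {
  g <- droplevels(as.factor(sample_type))
  if (nlevels(g) < 2) stop("af_by_sample_type_test: need >= 2 sample types")
  if (diff(range(af)) < 1e-300) stop("af_by_sample_type_test: all values tied")
  kw <- stats::kruskal.test(af, g)
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       dunn = dunn_test(af, g))
}

#' Dunn's post-hoc test on mean ranks
#'
#' Pairwise z statistics on group mean ranks with the tie-corrected variance
#' `(N(N+1)/12 - T)(1/n_i + 1/n_j)` where
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups; two-sided p-values
#' adjusted by the chosen family-wise method.
#'
#' @param x numeric values.
#' @param g grouping factor.
#' @param p_adjust adjustment method (default "bonferroni").
#' @return data.frame `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(x, g, p_adjust = "bonferroni") {
  g <- droplevels(as.factor(g))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_raw = p_raw,
             p_adj = stats::p.adjust(p_raw, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Median time to event, with range
#'
#' Sample median (mean of the middle pair for even n), rounded half-up to
#' whole days, plus the min/max.
#'
#' @param times event times in days (non-empty).
#' @return list with `median_days`, `min_days`, `max_days`.
#' @examples
#' median_time_to_event(c(1, 2, 3, 4))$median_days  # 3 (2.5 rounds half-up)
#' @export
median_time_to_event <- function(times) {
  if (!length(times)) stop("median_time_to_event: empty input")
  list(median_days = round_half_up(stats::median(times)),
       min_days = min(times), max_days = max(times))
}
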