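#' Pool germline samples into a control profile
#'
#' Sums raw per-bin counts across germline (buffy coat) sWGS samples and
#' corrects the pooled counts as a single sample. Pooling raw counts is
#' order-free, and the pooled control shares the bin frame of every test
#' sample.
#'
#' @param count_list named list of raw count vectors (one per germline
#'   sample), all aligned to `genome`.
#' @param genome a `genome_bins` frame.
#' @param ... passed to [correct_counts()].
#' @return a `control_profile` (also a `corrected_profile`) with a `members`
#'   field recording the pooled sample ids.
#' @export
pool_controls <- function(count_list, genome, ...) {
  if (!length(count_list)) stop("pool_controls: no control samples supplied")
  lens <- vapply(count_list, length, integer(1))
  if (any(lens != nrow(genome))) {
    stop("pool_controls: control counts do not match the genome bin frame")
  }
  pooled <- Reduce(`+`, count_list)
  prof <- correct_counts(pooled, genome, sample_id = "pooled_control", ...)
  prof$members <- names(count_list) %||% as.character(seq_along(count_list))
  class(prof) <- c("control_profile", class(prof))
  prof
}

#' Fit a test profile against the pooled control
#'
#' Ordinary least squares of the test sample's log2-adjusted bin values on
#' the control's, over the autosomal bins valid in both. The affine fit
#' absorbs global scale/offset differences between libraries; what remains in
#' the residuals is copy-number imbalance (plus noise).
#'
#' @param test a `corrected_profile`.
#' @param control a `corrected_profile`/`control_profile` on the same bin
#'   frame.
#' @return list with `residuals` (signed, on shared valid bins), `slope`,
#'   `intercept`, `shared` (logical mask over bins), `n`.
#' @export
fit_against_control <- function(test, control) {
  stopifnot(inherits(test, "corrected_profile"),
            inherits(control, "corrected_profile"))
  if (nrow(test$bins) != nrow(control$bins)) {
    stop("fit_against_control: bin frames differ")
  }
  shared <- test$valid & control$valid
  if (sum(shared) < 10) {
    stop("fit_against_control: fewer than 10 shared valid bins")
  }
  x <- control$log2ratio[shared]
  y <- test$log2ratio[shared]
  if (diff(range(x)) < 1e-12) {
    stop("fit_against_control: control profile is constant (degenerate fit)")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  list(residuals = unname(fit$residuals),
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       shared = shared, n = length(y))
}

#' Genome-wide imbalance score
#'
#' Summarises how far a sample's copy-number profile departs from the pooled
#' germline control: after the affine fit of [fit_against_control()], the
#' score is the sum of squared residuals over the 5\% of shared valid bins
#' with the largest squared residuals (`ceil` for fractional counts; ties at
#' the cutoff broken by bin order). Restricting to the extreme tail makes the
#' score insensitive to baseline noise around copy-number-neutral bins.
#'
#' @inheritParams fit_against_control
#' @param frac fraction of most-extreme residuals retained (default 0.05).
#' @return an `imbalance_result`: list with `score`, `n_extreme`,
#'   `residuals`, `slope`, `intercept`, `n`.
#' @export
imbalance_score <- function(test, control, frac = 0.05) {
  ft <- fit_against_control(test, control)
  sc <- score_from_residuals(ft$residuals, frac)
  structure(list(score = sc$score, n_extreme = sc$n_extreme,
                 residuals = ft$residuals, slope = ft$slope,
                 intercept = ft$intercept, n = ft$n),
            class = "imbalance_result")
}

#' Score a residual vector by its extreme tail
#'
#' @param residuals signed residual vector.
#' @param frac fraction of bins retained (ceil of `frac * length`).
#' @return list with `score` (sum of the retained squared residuals),
#'   `n_extreme`, and `which` (indices retained, ties broken by position).
#' @export
score_from_residuals <- function(residuals, frac = 0.05) {
  n <- length(residuals)
  if (!n) stop("score_from_residuals: empty residual vector")
  n_extreme <- ceiling(frac * n)
  o <- order(-(residuals^2), seq_len(n))
  keep <- o[seq_len(n_extreme)]
  list(score = sum(residuals[keep]^2), n_extreme = n_extreme, which = keep)
}

#' Control-derived imbalance-score threshold
#'
#' Leave-one-out calibration on the germline controls: each control sample is
#' scored against the pool of the remaining controls, and the maximum score
#' observed is returned. A test sample scoring above this value shows more
#' imbalance than any germline-only comparison did. This threshold is a
#' pragmatic artifact of the pipeline, not an estimate published with the
#' assay.
#'
#' @param count_list named list of germline raw count vectors.
#' @param genome a `genome_bins` frame.
#' @param frac passed to [imbalance_score()].
#' @return numeric threshold (max leave-one-out score).
#' @export
imbalance_threshold <- function(count_list, genome, frac = 0.05) {
  if (length(count_list) < 3) {
    stop("imbalance_threshold: need at least 3 control samples")
  }
  scores <- vapply(seq_along(count_list), function(k) {
    ctrl <- pool_controls(count_list[-k], genome)
    test <- correct_counts(count_list[[k]], genome,
                           sample_id = names(count_list)[k] %||% paste0("ctrl", k))
    imbalance_score(test, ctrl, frac)$score
  }, numeric(1))
  max(scores)
}

#' Concordance of two copy-number profiles
#'
#' Adjusted R-squared of the OLS fit of profile `b`'s log2 ratios on profile
#' `a`'s over their shared valid bins:
#' `1 - (1 - R^2) * (n - 1) / (n - 2)`. Values near 1 indicate the two
#' samples carry the same copy-number signal; null comparisons give values
#' near (possibly slightly below) 0.
#'
#' @param a,b `corrected_profile`s on the same bin frame.
#' @return list with `r2_adj`, `r2`, `n`.
#' @export
concordance_r2 <- function(a, b) {
  stopifnot(inherits(a, "corrected_profile"), inherits(b, "corrected_profile"))
  if (nrow(a$bins) != nrow(b$bins)) stop("concordance_r2: bin frames differ")
  shared <- a$valid & b$valid
  n <- sum(shared)
  if (n < 10) stop("concordance_r2: fewer than 10 shared valid bins")
  x <- a$log2ratio[shared]
  y <- b$log2ratio[shared]
  if (diff(range(x)) < 1e-12) stop("concordance_r2: constant predictor profile")
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-300) 1 else 1 - rss / tss
  list(r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2), r2 = r2, n = n)
}

#' @export
print.imbalance_result <- function(x, ...) {
  cat(sprintf("imbalance score %.4f over %d extreme bins (of %d; slope %.3f)\n",
              x$score, x$n_extreme, x$n, x$slope))
  invisible(x)
}
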