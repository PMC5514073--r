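#' Reference clinical cohort summary counts
#'
#' The published summary counts of the 17-patient MIBC neoadjuvant-chemo
#' cohort this pipeline was designed around, used by
#' [verify_reference_cohort()] to check the statistics layer against the
#' printed values. These are inputs (counts read off the published tables),
#' not results of this package:
#' \describe{
#'   \item{cycle2_table}{2x2 detection-at-cycle-2 vs recurrence counts
#'     (tp = 5, fp = 0, fn = 1, tn = 6) among the 12 evaluable patients.}
#'   \item{recurrence_days}{days from TUR to recurrence for the 8 recurrers,
#'     named by patient id.}
#'   \item{pre_nac_detect}{per sample type, c(detected, tested) at the
#'     pre-treatment visit.}
#'   \item{reported}{the printed values those counts reproduce: percentages
#'     to one decimal, CI bounds as integer percent, median/range in days.}
#' }
#' @format a list.
#' @export
reference_cohort <- list(
  cycle2_table = c(tp = 5L, fp = 0L, fn = 1L, tn = 6L),
  recurrence_days = c(P09 = 378, P12 = 269, P13 = 507, P15 = 293,
                      P18 = 264, P21 = 466, P24 = 265, P26 = 472),
  pre_nac_detect = list(PLS = c(detected = 6L, tested = 17L),
                        UCP = c(detected = 8L, tested = 17L),
                        USN = c(detected = 9L, tested = 17L)),
  reported = list(
    sensitivity_pct = 83.3, specificity_pct = 100,
    ppv_pct = 100, npv_pct = 85.7,
    sensitivity_ci_pct = c(36, 100),
    median_recurrence_days = 336, recurrence_range_days = c(264, 507),
    pre_nac_pct = c(PLS = 35.3, UCP = 47.1, USN = 52.9)
  )
)

#' Recompute the reference cohort's published statistics
#'
#' Recomputes, from the reference cohort's summary counts, the cycle-2
#' contingency metrics with exact binomial CIs, the median/range of time to
#' recurrence, and the pre-treatment detection fractions, and compares each
#' against the published value at its printed precision.
#'
#' @param quiet suppress printing.
#' @return (invisibly) a data.frame `quantity`, `computed`, `reference`,
#'   `pass`.
#' @export
verify_reference_cohort <- function(quiet = FALSE) {
  ref <- reference_cohort
  tab <- ref$cycle2_table
  m <- contingency_metrics(tab["tp"], tab["fp"], tab["fn"], tab["tn"])
  med <- median_time_to_event(ref$recurrence_days)
  pre <- vapply(ref$pre_nac_detect,
                function(v) 100 * v[["detected"]] / v[["tested"]], numeric(1))
  rows <- rbind(
    data.frame(quantity = "sensitivity_pct",
               computed = round(100 * m$sensitivity$estimate, 1),
               reference = ref$reported$sensitivity_pct),
    data.frame(quantity = "specificity_pct",
               computed = round(100 * m$specificity$estimate, 1),
               reference = ref$reported$specificity_pct),
    data.frame(quantity = "ppv_pct",
               computed = round(100 * m$ppv$estimate, 1),
               reference = ref$reported$ppv_pct),
    data.frame(quantity = "npv_pct",
               computed = round(100 * m$npv$estimate, 1),
               reference = ref$reported$npv_pct),
    data.frame(quantity = "sensitivity_ci_lower_pct",
               computed = round_half_up(100 * m$sensitivity$lower),
               reference = ref$reported$sensitivity_ci_pct[1]),
    data.frame(quantity = "sensitivity_ci_upper_pct",
               computed = round_half_up(100 * m$sensitivity$upper),
               reference = ref$reported$sensitivity_ci_pct[2]),
    data.frame(quantity = "median_recurrence_days",
               computed = med$median_days,
               reference = ref$reported$median_recurrence_days),
    data.frame(quantity = "min_recurrence_days",
               computed = med$min_days,
               reference = ref$reported$recurrence_range_days[1]),
    data.frame(quantity = "max_recurrence_days",
               computed = med$max_days,
               reference = ref$reported$recurrence_range_days[2]),
    data.frame(quantity = paste0("pre_nac_", names(pre), "_pct"),
               computed = round(unname(pre), 1),
               reference = unname(ref$reported$pre_nac_pct))
  )
  rows$pass <- rows$computed == rows$reference
  rownames(rows) <- NULL
  if (!quiet) {
    cat("Reference cohort verification\n")
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("  %-26s computed %7.1f  reference %7.1f  [%s]\n",
                  rows$quantity[i], rows$computed[i], rows$reference[i],
                  if (rows$pass[i]) "PASS" else "FAIL"))
    }
  }
  invisible(rows)
}
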