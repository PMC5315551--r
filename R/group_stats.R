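#' Paired within-subject comparison of a measure between conditions
#'
#' Two-sided paired t-test (t distribution with n - 1 df) or Wilcoxon
#' signed-rank test (exact null for n <= 25, normal approximation above) on
#' per-subject ON vs OFF values. P-values are reported uncorrected. A
#' zero-variance difference vector makes the paired t statistic undefined;
#' it is reported as 0 with a missing p-value and `degenerate = TRUE`.
#'
#' @param values_on,values_off equal-length numeric vectors paired by
#'   subject, no missing pairs.
#' @param test "paired_t" or "wilcoxon".
#' @param measure label stored in the result.
#' @return one-row data.frame: measure, n, mean_on, mean_off, statistic,
#'   p_value, test, degenerate.
#' @export
paired_compare <- function(values_on, values_off,
                           test = c("paired_t", "wilcoxon"), measure = "") {
  test <- match.arg(test)
  if (length(values_on) != length(values_off))
    stop("values_on and values_off must have equal length")
  n <- length(values_on)
  if (n < 2) stop("need at least 2 pairs")
  if (anyNA(values_on) || anyNA(values_off)) stop("missing pairs not allowed")
  d <- values_on - values_off
  degenerate <- FALSE
  if (test == "paired_t") {
    if (sd(d) == 0) {
      statistic <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p_value <- NA_real_
      degenerate <- TRUE
    } else {
      ht <- t.test(values_on, values_off, paired = TRUE)
      statistic <- unname(ht$statistic)
      p_value <- ht$p.value
    }
  } else {
    ht <- suppressWarnings(
      wilcox.test(values_on, values_off, paired = TRUE, exact = n <= 25))
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
  }
  data.frame(measure = measure, n = n,
             mean_on = mean(values_on), mean_off = mean(values_off),
             statistic = statistic, p_value = p_value, test = test,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Paired comparisons over a cohort behavior table
#'
#' Joins the ON and OFF rows of a [cohort_behavior()] table by subject and
#' runs [paired_compare()] for each requested measure.
#'
#' @param summary data.frame from [cohort_behavior()].
#' @param measures column names to compare (default: all behavioral indices).
#' @param test statistical test, see [paired_compare()].
#' @return data.frame with one row per measure.
#' @export
compare_conditions <- function(summary,
                               measures = c("gort", "gcrt", "gfrt", "usrt",
                                            "mean_ssd", "ssrt", "pc", "oe"),
                               test = "paired_t") {
  on <- summary[summary$condition == "ON", ]
  off <- summary[summary$condition == "OFF", ]
  on <- on[order(on$subject), ]
  off <- off[order(off$subject), ]
  if (!identical(on$subject, off$subject))
    stop("ON and OFF rows are not paired by subject")
  do.call(rbind, lapply(measures, function(m)
    paired_compare(on[[m]], off[[m]], test = test, measure = m)))
}
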