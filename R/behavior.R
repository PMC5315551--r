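#' Estimate the stop-signal reaction time by the integration method
#'
#' Under the independent-race model, the finishing-time distribution of the
#' Go process is observed on Go trials; the Stop process finishes, on
#' average, at the Go-distribution quantile corresponding to the observed
#' probability of responding on stop trials. The estimator sorts the Go RTs,
#' takes the `ceiling(p_respond * n)`-th order statistic as the finishing
#' time that the Stop process beats, and subtracts the mean SSD.
#'
#' @param go_rts reaction times of responded Go trials, ms.
#' @param mean_ssd mean stop-signal delay over stop trials, ms.
#' @param p_respond observed fraction of stop trials with a response,
#'   strictly inside (0, 1).
#' @return SSRT estimate in ms. Can be negative for ill-behaved inputs, in
#'   which case a warning is raised and the value returned as-is.
#' @export
#' @examples
#' estimate_ssrt(c(400, 500, 600, 700), mean_ssd = 300, p_respond = 0.5)
estimate_ssrt <- function(go_rts, mean_ssd, p_respond) {
  if (length(go_rts) == 0) stop("go_rts must be non-empty")
  if (!is.finite(p_respond) || p_respond <= 0 || p_respond >= 1)
    stop("p_respond must be strictly inside (0, 1)")
  k <- ceiling(p_respond * length(go_rts))
  quantile_rt <- sort(go_rts)[k]
  ssrt <- quantile_rt - mean_ssd
  if (ssrt <= 0)
    warning("non-positive SSRT estimate (", round(ssrt, 1),
            " ms); returned as-is")
  ssrt
}

class_mean_rt <- function(trials, type) {
  rts <- trials$rt_ms[trials$trial_type == type & trials$responded]
  if (length(rts) == 0) NA_real_ else mean(rts)
}

#' Behavioral summary of one session
#'
#' Computes the study's behavioral indices from a trial table: mean RT of
#' responded trials per class (GORT, GCRT, GFRT and USRT — the
#' signal-respond RT of unsuccessful stop trials), mean SSD, stop-trial
#' success rate, Go-family omission (task error) rate, the SSRT by the
#' integration method, the preparation cost PC = GORT - GFRT (proactive
#' inhibition) and the oddball effect OE = GCRT - GORT (rare-cue context).
#' A class with no responded trial yields NA for its mean, not zero.
#'
#' @param session an `sst_session`, or a trial-table data frame in the
#'   layout written by [write_trials()] restricted to one session.
#' @param subject_id,condition labels used when `session` is a bare trial
#'   table; ignored otherwise.
#' @return one-row data.frame with columns subject, condition, gort, gcrt,
#'   gfrt, usrt, mean_ssd, ssrt, pc, oe, stop_success_rate, error_rate and
#'   per-class trial counts.
#' @export
summarize_session <- function(session, subject_id = NULL, condition = NULL) {
  if (inherits(session, "sst_session")) {
    trials <- session$trials
    subject_id <- session$subject_id
    condition <- session$condition
  } else {
    trials <- session
    if (is.null(subject_id)) subject_id <- trials$subject[1]
    if (is.null(condition)) condition <- trials$condition[1]
  }
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  is_stop <- trials$trial_type == "STOP"
  gort <- class_mean_rt(trials, "GO")
  gcrt <- class_mean_rt(trials, "GO_CERTAIN")
  gfrt <- class_mean_rt(trials, "GO_FAST")
  usrt <- {
    rts <- trials$rt_ms[is_stop & trials$responded]
    if (length(rts) == 0) NA_real_ else mean(rts)
  }
  n_stop <- sum(is_stop)
  stop_success_rate <- if (n_stop) mean(trials$stop_success[is_stop]) else NA_real_
  mean_ssd <- if (n_stop) mean(trials$ssd_ms[is_stop]) else NA_real_
  go_family <- trials$trial_type != "STOP"
  error_rate <- mean(!trials$responded[go_family])

  go_rts <- trials$rt_ms[trials$trial_type == "GO" & trials$responded]
  p_respond <- if (n_stop) 1 - stop_success_rate else NA_real_
  ssrt <- if (length(go_rts) && is.finite(p_respond) &&
              p_respond > 0 && p_respond < 1)
    estimate_ssrt(go_rts, mean_ssd, p_respond) else NA_real_

  data.frame(subject = subject_id, condition = condition,
             gort = gort, gcrt = gcrt, gfrt = gfrt, usrt = usrt,
             mean_ssd = mean_ssd, ssrt = ssrt,
             pc = gort - gfrt, oe = gcrt - gort,
             stop_success_rate = stop_success_rate,
             error_rate = error_rate,
             n_go = sum(trials$trial_type == "GO"),
             n_stop = n_stop,
             n_go_fast = sum(trials$trial_type == "GO_FAST"),
             n_go_certain = sum(trials$trial_type == "GO_CERTAIN"),
             stringsAsFactors = FALSE)
}

#' Behavioral summaries for a cohort of sessions
#'
#' @param sessions list of `sst_session` objects (e.g. from
#'   [simulate_cohort()]) or a full trial table covering several sessions.
#' @return data.frame with one row per (subject, condition).
#' @export
cohort_behavior <- function(sessions) {
  if (is.data.frame(sessions)) {
    keys <- unique(sessions[c("subject", "condition")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
      sub <- sessions[sessions$subject == keys$subject[i] &
                        sessions$condition == keys$condition[i], ]
      summarize_session(sub)
    })
  } else {
    stopifnot(length(sessions) >= 1)
    rows <- lapply(sessions, summarize_session)
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out[c("subject", "condition")]))
    stop("duplicate (subject, condition) pairs in cohort")
  rownames(out) <- NULL
  out
}
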