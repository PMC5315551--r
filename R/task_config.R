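#' Stop-signal task configuration
#'
#' Defines the trial mix and staircase of the stop-signal task (SST). The
#' defaults reproduce the study design: 100-trial blocks; GO trials 52.6% of
#' the mix; STOP trials kept rare (15.8%, below 16%) with the remainder split
#' evenly between Go-Fast (GF, never followed by a stop cue) and Go-Certain
#' (GC) trials; a +/-50 ms staircase on the stop-signal delay (SSD) that
#' drives stop-trial success towards 50%.
#'
#' @param n_blocks number of blocks (2-4 in the task; default 3).
#' @param trials_per_block trials per block (default 100).
#' @param proportions named fractions for GO, STOP, GO_FAST, GO_CERTAIN;
#'   must sum to 1 and the STOP fraction must not exceed 0.16.
#' @param staircase_step SSD change after each STOP trial, ms (default 50).
#' @param initial_ssd SSD of the first STOP trial of block 1, ms.
#' @param ssd_bounds numeric length-2; SSD is clipped into this range, ms.
#' @param deadline response deadline, ms; Go finishing times beyond it are
#'   recorded as omissions (task errors).
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_blocks = 3,
                        trials_per_block = 100,
                        proportions = c(GO = 0.526, STOP = 0.158,
                                        GO_FAST = 0.158, GO_CERTAIN = 0.158),
                        staircase_step = 50,
                        initial_ssd = 300,
                        ssd_bounds = c(50, 900),
                        deadline = 1200) {
  required <- c("GO", "STOP", "GO_FAST", "GO_CERTAIN")
  if (!all(required %in% names(proportions)))
    stop_invalid("proportions must be named with ", paste(required, collapse = ", "))
  proportions <- proportions[required]
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_invalid("trial-type proportions must sum to 1 (got ", sum(proportions), ")")
  if (proportions[["STOP"]] > 0.16)
    stop_invalid("STOP fraction must be <= 0.16")
  if (staircase_step <= 0) stop_invalid("staircase_step must be > 0")
  if (ssd_bounds[1] < 0 || ssd_bounds[2] < ssd_bounds[1])
    stop_invalid("ssd_bounds must satisfy 0 <= min <= max")
  if (n_blocks < 1 || trials_per_block < 1)
    stop_invalid("n_blocks and trials_per_block must be positive")
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 proportions = proportions,
                 staircase_step = staircase_step,
                 initial_ssd = initial_ssd,
                 ssd_bounds = ssd_bounds,
                 deadline = deadline),
            class = "task_config")
}

#' Generative race-model parameters
#'
#' Parameters of the independent-race (horse-race) model of the SST: the Go
#' process finishing time is ex-Gaussian (mu, sigma, tau, ms); the Stop
#' process finishing time is SSD + a Normal(ssrt_true, ssrt_sd) latency
#' truncated at 0; with probability `p_trigger_failure` the Stop process
#' never starts and the trial is always responded. GF/GC trials shift the Go
#' finishing time additively (GF faster, GC slower), which is what produces
#' the preparation-cost and oddball behavioral indices.
#'
#' Defaults land near the OFF-stimulation group means of the study this
#' package emulates: mean Go RT = mu + tau = 650 ms, GF mean 565 ms, GC mean
#' 708 ms, SSRT about 190 ms.
#'
#' @param go_mu,go_sigma,go_tau ex-Gaussian Go parameters, ms.
#' @param ssrt_true,ssrt_sd Stop-latency mean and sd, ms.
#' @param p_trigger_failure probability the stop process never launches.
#' @param gf_offset,gc_offset additive Go-finishing-time shifts for GO_FAST
#'   (negative) and GO_CERTAIN (positive) trials, ms.
#' @return an object of class `race_params`.
#' @export
race_params <- function(go_mu = 450, go_sigma = 60, go_tau = 200,
                        ssrt_true = 190, ssrt_sd = 25,
                        p_trigger_failure = 0.02,
                        gf_offset = -85, gc_offset = 58) {
  if (go_sigma <= 0) stop_invalid("go_sigma must be > 0")
  if (go_tau < 0) stop_invalid("go_tau must be >= 0")
  if (ssrt_true <= 0) stop_invalid("ssrt_true must be > 0")
  if (ssrt_sd < 0) stop_invalid("ssrt_sd must be >= 0")
  if (p_trigger_failure < 0 || p_trigger_failure > 1)
    stop_invalid("p_trigger_failure must be in [0, 1]")
  structure(list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
                 ssrt_true = ssrt_true, ssrt_sd = ssrt_sd,
                 p_trigger_failure = p_trigger_failure,
                 gf_offset = gf_offset, gc_offset = gc_offset),
            class = "race_params")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Stop-signal task config:", x$n_blocks, "blocks x",
      x$trials_per_block, "trials\n")
  cat("  mix:", paste(sprintf("%s %.1f%%", names(x$proportions),
                              100 * x$proportions), collapse = ", "), "\n")
  cat("  staircase +/-", x$staircase_step, "ms from", x$initial_ssd,
      "ms, SSD in [", x$ssd_bounds[1], ",", x$ssd_bounds[2], "] ms\n")
  invisible(x)
}

#' @export
print.race_params <- function(x, ...) {
  cat(sprintf("Race params: Go exGauss(%g, %g, %g) ms; SSRT %g +/- %g ms; P(trigger failure) %g\n",
              x$go_mu, x$go_sigma, x$go_tau, x$ssrt_true, x$ssrt_sd,
              x$p_trigger_failure))
  invisible(x)
}
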