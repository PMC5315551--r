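TRIAL_TYPES <- c("GO", "STOP", "GO_FAST", "GO_CERTAIN")

# Largest-remainder (Hamilton) apportionment of n trials over the trial-type
# proportions; ties broken by declaration order. Exactly reproduces the
# design fractions whenever proportion * n is integral (e.g. 526 GO in 1000).
allocate_counts <- function(proportions, n) {
  exact <- proportions * n
  counts <- floor(exact)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Build the randomized trial-type sequence of a session
#'
#' Allocates per-block trial counts deterministically from the configured
#' proportions (largest-remainder rule) and permutes each block with the
#' given seed under the constraint that no two STOP trials are adjacent
#' (avoids carry-over of the SSD staircase between consecutive stop cues).
#'
#' @param config a [task_config()].
#' @param seed integer seed for the permutation.
#' @return character vector of trial types, length `n_blocks * trials_per_block`.
#' @export
#' @examples
#' table(build_trial_sequence(task_config(n_blocks = 1,
#'                                        trials_per_block = 1000), seed = 1))
build_trial_sequence <- function(config, seed) {
  stopifnot(inherits(config, "task_config"))
  set.seed(derive_seed(seed, "trial_sequence"))
  counts <- allocate_counts(config$proportions, config$trials_per_block)
  out <- character(0)
  for (b in seq_len(config$n_blocks)) {
    forbid_first <- length(out) > 0 && out[length(out)] == "STOP"
    out <- c(out, permute_block(counts, forbid_first))
  }
  out
}

# Permute one block's trial types with no two adjacent STOPs (also not in
# first position when the previous block ended on one). Rejection sampling
# first; if the mix makes rejection slow, fall back to spreading the STOP
# trials over evenly spaced slots of a permuted non-STOP sequence.
permute_block <- function(counts, forbid_first = FALSE) {
  types <- rep(names(counts), counts)
  n_stop <- counts[["STOP"]]
  for (i in seq_len(500)) {
    perm <- sample(types)
    if (n_stop == 0) return(perm)
    adjacent <- n_stop >= 2 &&
      any(perm[-1] == "STOP" & perm[-length(perm)] == "STOP")
    if (!adjacent && !(forbid_first && perm[1] == "STOP")) return(perm)
  }
  non_stop <- sample(rep(names(counts)[names(counts) != "STOP"],
                         counts[names(counts) != "STOP"]))
  gap <- (length(non_stop) - 1) / n_stop
  stop_pos <- 2L + round((seq_len(n_stop) - 1) * (gap + 1))
  out <- character(length(types))
  out[stop_pos] <- "STOP"
  out[-stop_pos] <- non_stop
  out
}

#' Simulate one stop-signal-task session under the race model
#'
#' Each trial's Go finishing time is drawn from the ex-Gaussian (shifted by
#' the GF/GC offset on those trial types). On STOP trials an independent Stop
#' finishing time SSD + s, s ~ Normal(ssrt_true, ssrt_sd) truncated at 0,
#' races the Go process: the subject responds iff the Go process finishes
#' first or the stop process failed to trigger. After every STOP trial the
#' SSD moves by +step on successful inhibition and -step on failure (clipped
#' to the configured bounds); the first STOP trial of block b > 1 starts at
#' the mean SSD of the last four STOP trials of block b - 1. Go finishing
#' times beyond the response deadline are recorded as omissions.
#'
#' @param config a [task_config()].
#' @param params a [race_params()].
#' @param seed integer seed; identical (config, params, seed) give
#'   bit-identical sessions.
#' @param subject_id,condition session labels (condition "ON" or "OFF").
#' @return an object of class `sst_session`: list with `subject_id`,
#'   `condition`, `trials` (one row per trial: index, block, trial_type,
#'   ssd_ms, responded, rt_ms, stop_success, and the latent generator
#'   ground-truth `go_finish_ms`), `config`, `params`.
#' @export
simulate_session <- function(config, params, seed,
                             subject_id = "S01", condition = "OFF") {
  stopifnot(inherits(config, "task_config"), inherits(params, "race_params"))
  condition <- match.arg(condition, c("ON", "OFF"))
  types <- build_trial_sequence(config, seed)
  n <- length(types)
  set.seed(derive_seed(seed, "race"))

  offsets <- c(GO = 0, STOP = 0, GO_FAST = params$gf_offset,
               GO_CERTAIN = params$gc_offset)
  g <- rexgauss(n, params$go_mu, params$go_sigma, params$go_tau) +
    unname(offsets[types])

  ssd <- rep(NA_real_, n)
  responded <- g <= config$deadline
  stop_success <- rep(NA, n)

  si <- which(types == "STOP")
  if (length(si)) {
    tf <- runif(length(si)) < params$p_trigger_failure
    s <- rtnorm0(length(si), params$ssrt_true, params$ssrt_sd)
    blocks_of <- ceiling(si / config$trials_per_block)
    cur <- config$initial_ssd
    prev_block <- 1L
    for (k in seq_along(si)) {
      b <- blocks_of[k]
      if (b != prev_block) {
        prev <- which(blocks_of == prev_block)
        cur <- mean(ssd[si[tail(prev, 4)]])
        prev_block <- b
      }
      ssd[si[k]] <- cur
      i <- si[k]
      go_wins <- tf[k] || g[i] < cur + s[k]
      responded[i] <- go_wins && g[i] <= config$deadline
      stop_success[i] <- !responded[i]
      cur <- clip(cur + if (stop_success[i]) config$staircase_step else
                    -config$staircase_step, config$ssd_bounds)
    }
  }

  trials <- data.frame(
    index = seq_len(n),
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    trial_type = types,
    ssd_ms = ssd,
    responded = responded,
    rt_ms = ifelse(responded, g, NA_real_),
    stop_success = stop_success,
    go_finish_ms = g,
    stringsAsFactors = FALSE
  )
  structure(list(subject_id = subject_id, condition = condition,
                 trials = trials, config = config, params = params),
            class = "sst_session")
}

#' @export
print.sst_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("SST session %s [%s]: %d trials (%d STOP, stop success %.1f%%)\n",
              x$subject_id, x$condition, nrow(tr),
              sum(tr$trial_type == "STOP"),
              100 * mean(tr$stop_success[tr$trial_type == "STOP"])))
  invisible(x)
}

#' Simulate a paired ON/OFF cohort
#'
#' Per-subject race parameters are jittered lognormally around `off_params`
#' (10% coefficient of variation on `go_mu` and `ssrt_true`, mean-preserving).
#' The ON-stimulation session of each subject uses the same subject-level
#' parameters with `go_mu` reduced by `rt_shift` (response speeding) and
#' `ssrt_true` increased by `ssrt_shift` (inhibition worsening), the
#' direction of the deep-brain-stimulation effects the generator emulates.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param config a [task_config()] shared by all sessions.
#' @param off_params OFF-stimulation [race_params()] around which subjects
#'   are jittered.
#' @param on_effects list with `rt_shift` and `ssrt_shift` in ms; both 0
#'   gives an exchangeable (null) ON/OFF cohort.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param cv between-subject coefficient of variation of the lognormal jitter.
#' @return list of `2 * n_subjects` sessions (OFF and ON per subject), class
#'   `sst_cohort`.
#' @export
simulate_cohort <- function(n_subjects, config, off_params,
                            on_effects = list(rt_shift = 50, ssrt_shift = 53),
                            seed = 1, cv = 0.10) {
  if (n_subjects < 2) stop_invalid("n_subjects must be >= 2")
  stopifnot(inherits(config, "task_config"), inherits(off_params, "race_params"))
  sdlog <- sqrt(log(1 + cv^2))
  sessions <- vector("list", 2L * n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    set.seed(derive_seed(seed, paste0("jitter/", sid)))
    p_off <- off_params
    p_off$go_mu <- off_params$go_mu * rlnorm(1, -sdlog^2 / 2, sdlog)
    p_off$ssrt_true <- off_params$ssrt_true * rlnorm(1, -sdlog^2 / 2, sdlog)
    p_on <- p_off
    p_on$go_mu <- p_off$go_mu - on_effects$rt_shift
    p_on$ssrt_true <- p_off$ssrt_true + on_effects$ssrt_shift
    sessions[[2L * i - 1L]] <- simulate_session(
      config, p_off, derive_seed(seed, paste0("session/", sid, "/OFF")),
      subject_id = sid, condition = "OFF")
    sessions[[2L * i]] <- simulate_session(
      config, p_on, derive_seed(seed, paste0("session/", sid, "/ON")),
      subject_id = sid, condition = "ON")
  }
  structure(sessions, class = "sst_cohort")
}
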