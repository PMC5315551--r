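#' Channel labels of the simulated high-density montage
#'
#' A 96-entry extended 10-10/10-5 label set matching the active-electrode cap
#' the study design assumes (reference FCz and ground AFz are not data
#' channels and are excluded). F4 — the sensor carrying the inhibition
#' components of interest — is among the first 16 labels so that reduced
#' montages used in examples still expose it.
#'
#' @param n number of channels (<= 96), default 96.
#' @return character vector of `n` labels.
#' @export
montage_labels <- function(n = 96) {
  labs <- c(
    "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10", "O1", "Oz", "O2",
    "AFF5h", "AFF1h", "AFF2h", "AFF6h",
    "FFC5h", "FFC3h", "FFC1h", "FFC2h", "FFC4h", "FFC6h",
    "FCC5h", "FCC3h", "FCC1h", "FCC2h", "FCC4h", "FCC6h",
    "CCP5h", "CCP3h", "CCP1h", "CCP2h", "CCP4h", "CCP6h",
    "CPP5h", "CPP3h", "CPP1h", "CPP2h", "CPP4h", "CPP6h",
    "PPO1h", "PPO2h")
  if (n > length(labs)) stop_invalid("montage supports at most ", length(labs),
                                     " channels")
  labs[seq_len(n)]
}

# Smooth unimodal topography over channel index, peaking at `center` with
# index spread `spread`; a stylized scalp field, max weight 1.
index_topography <- function(n_channels, center, spread = 12) {
  exp(-((seq_len(n_channels) - center)^2) / (2 * spread^2))
}

#' Evoked-component templates of the EEG generator
#'
#' Defines the deterministic components summed into every synthetic epoch:
#' stop-cue-locked N100, N200 and P300 (the inhibition readouts; negative,
#' negative and positive Gaussian bumps with right-frontal topographies
#' peaking at F4) and a Go-locked motor component (GO_MOTOR) whose latency
#' rides on the trial's Go finishing time (peak `latency` ms before the
#' response), so stop-trial epochs contain Go-process activity at
#' -SSD-shifted latencies exactly as the race model predicts.
#'
#' `condition_effects` holds per-condition multiplicative amplitude factors
#' and additive latency shifts per component. The ON defaults emulate the
#' stimulation effects the generator is meant to carry: P300 amplitude x0.82
#' and latency +17 ms, N200 amplitude x0.88 and latency -11 ms.
#' `us_attenuation` scales N200/P300 on unsuccessful stop trials, where
#' inhibition ran but lost the race.
#'
#' @param n_channels channel count (default 96; must fit [montage_labels()]).
#' @param srate sampling rate, Hz (default 250).
#' @param us_attenuation amplitude factor on N200/P300 in unsuccessful stops.
#' @param condition_effects named list per condition of per-component
#'   `list(amp = factor, lat = shift_ms)` entries.
#' @return an object of class `erp_templates`.
#' @export
erp_templates <- function(n_channels = 96, srate = 250, us_attenuation = 0.5,
                          condition_effects = list(
                            OFF = list(),
                            ON = list(
                              N200 = list(amp = 0.88, lat = -11),
                              P300 = list(amp = 0.82, lat = 17)))) {
  if (srate <= 0) stop_invalid("srate must be > 0")
  labels <- montage_labels(n_channels)
  f4 <- match("F4", labels)
  if (is.na(f4)) f4 <- 1L
  c3 <- match("C3", labels)
  if (is.na(c3)) c3 <- max(1L, n_channels %/% 2L)
  fc1 <- match("FC1", labels)
  if (is.na(fc1)) fc1 <- 1L
  components <- list(
    list(name = "N100", latency = 100, half_width = 60, amplitude = -3,
         alignment = "STOP",
         topography = index_topography(n_channels, fc1, 10)),
    list(name = "N200", latency = 200, half_width = 70, amplitude = -5,
         alignment = "STOP",
         topography = index_topography(n_channels, f4, 9)),
    list(name = "P300", latency = 297, half_width = 110, amplitude = 6.5,
         alignment = "STOP",
         topography = index_topography(n_channels, f4, 14)),
    list(name = "GO_MOTOR", latency = -50, half_width = 120, amplitude = 5,
         alignment = "GO",
         topography = index_topography(n_channels, c3, 10))
  )
  for (cmp in components) {
    if (length(cmp$topography) != n_channels)
      stop_invalid("topography length must equal n_channels")
    if (cmp$half_width <= 0) stop_invalid("half_width must be > 0")
  }
  structure(list(n_channels = as.integer(n_channels), srate = srate,
                 labels = labels, components = components,
                 us_attenuation = us_attenuation,
                 condition_effects = condition_effects),
            class = "erp_templates")
}

# Gaussian bump time course; half_width is the full width at half maximum.
component_bump <- function(times, latency, half_width, amplitude) {
  sigma <- half_width / (2 * sqrt(2 * log(2)))
  amplitude * exp(-((times - latency)^2) / (2 * sigma^2))
}

# amplitude factor / latency shift for a component under a condition
condition_adjust <- function(templates, condition, name) {
  eff <- templates$condition_effects[[condition]][[name]]
  list(amp = if (is.null(eff$amp)) 1 else eff$amp,
       lat = if (is.null(eff$lat)) 0 else eff$lat)
}

#' Epoched multichannel EEG container
#'
#' @param data numeric array `[trial, channel, sample]`, microvolts.
#' @param srate sampling rate, Hz.
#' @param times sample times in ms relative to the alignment cue
#'   (inclusive endpoints; the t = 0 sample is part of the grid).
#' @param alignment "GO_CUE" or "STOP_CUE".
#' @param labels channel labels.
#' @param trials per-epoch trial metadata (one row per epoch).
#' @return object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, srate, times, alignment, labels, trials) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[2] != length(labels))
    stop("channel dimension does not match labels")
  if (dim(data)[3] != length(times))
    stop("sample dimension does not match times")
  if (dim(data)[1] != nrow(trials))
    stop("trial dimension does not match trial metadata")
  structure(list(data = data, srate = srate, times = times,
                 alignment = match.arg(alignment, c("GO_CUE", "STOP_CUE")),
                 labels = labels, trials = trials),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EEG epochs [%s]: %d trials x %d channels x %d samples, %g Hz, (%g, %g) ms\n",
              x$alignment, d[1], d[2], d[3], x$srate,
              min(x$times), max(x$times)))
  invisible(x)
}

epoch_times <- function(window, srate) seq(window[1], window[2], by = 1000 / srate)

#' Synthesize EEG epochs for a simulated session
#'
#' Builds Go-cue-locked epochs for the responded GO trials (motor component
#' only) and Stop-cue-locked epochs for the STOP trials. Stop epochs contain
#' the Go-locked motor component placed at the trial's latent Go finishing
#' time minus the SSD (the overlapping Go process), plus the stop-locked
#' N100/N200/P300 inhibition components — at full amplitude on successful
#' stops, with N200/P300 attenuated on unsuccessful stops. Condition effects
#' from the templates are applied, and i.i.d. Gaussian noise of sd
#' `noise_sd` is added per channel and sample.
#'
#' The noiseless condition-adjusted inhibition template (N100 + N200 + P300
#' at successful-stop amplitude) is attached to the stop epochs as attribute
#' `"ground_truth"` (channels x samples) for recovery testing.
#'
#' @param session an `sst_session` from [simulate_session()].
#' @param templates an [erp_templates()] object.
#' @param noise_sd white-noise standard deviation, microvolts.
#' @param seed integer seed for the noise.
#' @param stop_window,go_window epoch windows in ms around the respective
#'   cue. The Go window extends to 1000 ms so that Go-locked activity can be
#'   realigned into stop-cue time (Go-time = stop-time + SSD) during the
#'   Go-process correction.
#' @param labels optional channel labels; must match the template channel
#'   count.
#' @return list with elements `go` and `stop`, both [eeg_epochs()].
#' @export
synthesize_eeg <- function(session, templates, noise_sd = 1, seed = 1,
                           stop_window = c(-200, 500),
                           go_window = c(-200, 1000),
                           labels = NULL) {
  stopifnot(inherits(session, "sst_session"), inherits(templates, "erp_templates"))
  if (is.null(labels)) labels <- templates$labels
  if (length(labels) != templates$n_channels)
    stop("montage has ", length(labels), " channels but templates have ",
         templates$n_channels)
  set.seed(derive_seed(seed, paste0("eeg/", session$subject_id, "/",
                                    session$condition)))
  srate <- templates$srate
  nch <- templates$n_channels
  cond <- session$condition
  tr <- session$trials

  t_go <- epoch_times(go_window, srate)
  t_stop <- epoch_times(stop_window, srate)

  comp <- function(name) Filter(function(cc) cc$name == name,
                                templates$components)[[1]]
  motor <- comp("GO_MOTOR")
  stop_comps <- Filter(function(cc) cc$alignment == "STOP", templates$components)

  go_rows <- which(tr$trial_type == "GO" & tr$responded)
  go_data <- array(0, c(length(go_rows), nch, length(t_go)))
  adj_m <- condition_adjust(templates, cond, "GO_MOTOR")
  for (j in seq_along(go_rows)) {
    rt <- tr$rt_ms[go_rows[j]]
    bump <- component_bump(t_go, rt + motor$latency + adj_m$lat,
                           motor$half_width, motor$amplitude * adj_m$amp)
    go_data[j, , ] <- outer(motor$topography, bump)
  }
  if (noise_sd > 0)
    go_data <- go_data + rnorm(length(go_data), 0, noise_sd)

  stop_rows <- which(tr$trial_type == "STOP")
  stop_data <- array(0, c(length(stop_rows), nch, length(t_stop)))
  gt <- matrix(0, nch, length(t_stop))
  for (cc in stop_comps) {
    adj <- condition_adjust(templates, cond, cc$name)
    bump <- component_bump(t_stop, cc$latency + adj$lat, cc$half_width,
                           cc$amplitude * adj$amp)
    gt <- gt + outer(cc$topography, bump)
  }
  for (j in seq_along(stop_rows)) {
    i <- stop_rows[j]
    m <- matrix(0, nch, length(t_stop))
    # overlapping Go process: motor bump at latent finish time, in stop time
    go_peak <- tr$go_finish_ms[i] - tr$ssd_ms[i] + motor$latency + adj_m$lat
    m <- m + outer(motor$topography,
                   component_bump(t_stop, go_peak, motor$half_width,
                                  motor$amplitude * adj_m$amp))
    att <- if (isTRUE(tr$stop_success[i])) 1 else templates$us_attenuation
    for (cc in stop_comps) {
      adj <- condition_adjust(templates, cond, cc$name)
      a <- cc$amplitude * adj$amp * if (cc$name %in% c("N200", "P300")) att else 1
      m <- m + outer(cc$topography,
                     component_bump(t_stop, cc$latency + adj$lat,
                                    cc$half_width, a))
    }
    stop_data[j, , ] <- m
  }
  if (noise_sd > 0)
    stop_data <- stop_data + rnorm(length(stop_data), 0, noise_sd)

  go <- eeg_epochs(go_data, srate, t_go, "GO_CUE", labels, tr[go_rows, ])
  stp <- eeg_epochs(stop_data, srate, t_stop, "STOP_CUE", labels, tr[stop_rows, ])
  attr(stp, "ground_truth") <- gt
  list(go = go, stop = stp)
}
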