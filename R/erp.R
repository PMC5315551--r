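#' Averaged event-related potential container
#'
#' @param data channels x samples matrix, microvolts.
#' @param srate sampling rate, Hz.
#' @param times sample times, ms.
#' @param labels channel labels.
#' @param alignment alignment cue of the underlying epochs.
#' @param n_trials number of trials averaged.
#' @param condition free-text tag ("SS", "US", ...).
#' @return object of class `erp`.
#' @export
new_erp <- function(data, srate, times, labels, alignment, n_trials,
                    condition = "") {
  stopifnot(is.matrix(data), nrow(data) == length(labels),
            ncol(data) == length(times))
  structure(list(data = data, srate = srate, times = times, labels = labels,
                 alignment = alignment, n_trials = n_trials,
                 condition = condition),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("ERP [%s%s]: %d channels x %d samples, %g Hz, n = %d trials\n",
              x$alignment, if (nzchar(x$condition)) paste0("/", x$condition) else "",
              nrow(x$data), ncol(x$data), x$srate, x$n_trials))
  invisible(x)
}

# Zero-phase filtering with odd (endpoint-reflected) padding so that edge
# transients of the IIR filter decay inside the padding, not in the data;
# `pad` is sized by the caller to several time constants of the band edge.
filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  p <- min(n - 1L, pad)
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(p + 1):(p + n)]
}

filtfilt_mat <- function(flt, x, pad) {
  # x: trials x channels x samples; zero-phase filter along samples
  d <- dim(x)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      x[i, j, ] <- filtfilt_padded(flt, x[i, j, ], pad)
  x
}

#' Filter and downsample epochs
#'
#' Zero-phase (forward-backward Butterworth) filtering followed by
#' anti-aliased decimation. The high-pass and low-pass halves of the band
#' are applied as separate filters (order 2 high-pass, order 4 low-pass),
#' which keeps the narrow-band design numerically stable at high sampling
#' rates. Use `band = c(0, h)` or `c(NA, h)` for a pure low-pass (e.g. the
#' 30 Hz low-pass applied after epoching).
#'
#' @param epochs an [eeg_epochs()] object.
#' @param band length-2 numeric: high-pass and low-pass edges in Hz; each
#'   may be 0/NA/Inf to skip that half. Both edges must lie below Nyquist.
#' @param target_srate optional new sampling rate; must divide the current
#'   rate (e.g. 2500 -> 250 Hz).
#' @return filtered (and possibly decimated) [eeg_epochs()].
#' @export
preprocess <- function(epochs, band = c(1, 45), target_srate = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  nyq <- epochs$srate / 2
  lo <- band[1]; hi <- band[2]
  if (!is.na(lo) && lo > 0) {
    if (lo >= nyq) stop("high-pass edge at or above Nyquist")
    epochs$data <- filtfilt_mat(signal::butter(2, lo / nyq, type = "high"),
                                epochs$data,
                                pad = ceiling(1.2 * epochs$srate / lo))
  }
  if (!is.na(hi) && is.finite(hi)) {
    if (hi >= nyq) stop("low-pass edge at or above Nyquist")
    epochs$data <- filtfilt_mat(signal::butter(4, hi / nyq, type = "low"),
                                epochs$data,
                                pad = ceiling(1.2 * epochs$srate / hi))
  }
  if (!is.null(target_srate) && target_srate != epochs$srate) {
    q <- epochs$srate / target_srate
    if (abs(q - round(q)) > 1e-9)
      stop("target_srate must divide the current sampling rate")
    q <- as.integer(round(q))
    d <- dim(epochs$data)
    keep <- seq(1, d[3], by = q)
    out <- array(0, c(d[1], d[2], length(keep)))
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        out[i, j, ] <- signal::decimate(epochs$data[i, j, ], q)
    epochs$data <- out
    epochs$times <- epochs$times[keep]
    epochs$srate <- target_srate
  }
  epochs
}

common_average <- function(mat) sweep(mat, 2, colMeans(mat))

#' Average epochs into an ERP
#'
#' Trial mean per channel and sample, re-referenced to the common average
#' (the scalp-wide mean is subtracted at every sample, so channel means are
#' zero) and baseline-corrected by subtracting each channel's mean over the
#' baseline window.
#'
#' @param epochs an [eeg_epochs()] object with at least one trial.
#' @param baseline length-2 window in ms, inside the epoch extent
#'   (default -150 to -50 ms before the cue).
#' @param condition tag stored on the result.
#' @return an [new_erp()] object.
#' @export
average_erp <- function(epochs, baseline = c(-150, -50), condition = "") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[1] < 1) stop("cannot average zero epochs")
  if (baseline[1] < min(epochs$times) || baseline[2] > max(epochs$times))
    stop("baseline window outside the epoch extent")
  m <- apply(epochs$data, c(2, 3), mean)
  m <- common_average(m)
  bi <- epochs$times >= baseline[1] & epochs$times <= baseline[2]
  m <- m - rowMeans(m[, bi, drop = FALSE])
  new_erp(m, epochs$srate, epochs$times, epochs$labels, epochs$alignment,
          n_trials = dim(epochs$data)[1], condition = condition)
}

# Mean of selected go epochs realigned from Go-cue time to Stop-cue time:
# stop-time t corresponds to go-time t + ssd; samples outside the available
# go window contribute zero (the motor component has died off there).
shift_go_mean <- function(go_flat, rows, nch, go_times, stop_times, ssd) {
  if (length(rows) == 0) return(matrix(0, nch, length(stop_times)))
  avg <- if (length(rows) == 1) go_flat[rows, ] else colMeans(go_flat[rows, , drop = FALSE])
  avg <- matrix(avg, nch)
  idx <- round((stop_times + ssd - go_times[1]) / (go_times[2] - go_times[1])) + 1L
  ok <- idx >= 1L & idx <= length(go_times)
  out <- matrix(0, nch, length(stop_times))
  out[, ok] <- avg[, idx[ok]]
  out
}

#' Go-process correction of stop-trial epochs
#'
#' Under the horse-race model the Go and Stop processes overlap on STOP
#' trials, so the raw stop-locked average confounds inhibition activity
#' with Go-process activity. This correction subtracts, from each stop
#' epoch, an estimate of the overlapping Go activity built from Go-trial
#' epochs and realigned into stop-cue time (shifted by -SSD, rounded to the
#' nearest sample):
#' \itemize{
#'   \item unsuccessful stops (a response occurred): the mean of Go epochs
#'     whose RT lies within `rt_tol` ms of the stop trial's signal-respond
#'     RT — the Go processes that plausibly generated that response;
#'   \item successful stops (no response): the mean of Go epochs with
#'     RT > SSD + SSRT — the Go processes slow enough to have lost the race,
#'     whose activity is the part that leaked into the epoch.
#' }
#' Stop trials with no matching Go trial are corrected with the grand Go
#' average and a warning is raised. Corrected epochs are then averaged per
#' class (common-average reference, baseline correction).
#'
#' @param stop_epochs stop-cue-locked [eeg_epochs()] with `ssd_ms`, `rt_ms`,
#'   `stop_success` in their trial metadata.
#' @param go_epochs Go-cue-locked [eeg_epochs()] with `rt_ms` metadata.
#' @param session the `sst_session` (or its trial table) used to estimate
#'   the session SSRT for the successful-stop branch; alternatively pass
#'   `ssrt` directly.
#' @param ssrt session SSRT in ms; estimated from `session` when NULL.
#' @param rt_tol RT-matching tolerance for unsuccessful stops, ms.
#' @param baseline baseline window passed to [average_erp()].
#' @return list with `erp_ss`, `erp_us` (either may be NULL if the class is
#'   empty), the `ssrt` used, and `n_fallback`, the number of stop trials
#'   corrected with the grand Go average.
#' @export
go_correction <- function(stop_epochs, go_epochs, session = NULL, ssrt = NULL,
                          rt_tol = 50, baseline = c(-150, -50)) {
  stopifnot(inherits(stop_epochs, "eeg_epochs"), inherits(go_epochs, "eeg_epochs"))
  if (go_epochs$alignment != "GO_CUE" || stop_epochs$alignment != "STOP_CUE")
    stop("go_epochs must be GO_CUE-aligned and stop_epochs STOP_CUE-aligned")
  if (is.null(ssrt)) {
    if (is.null(session)) stop("provide either session or ssrt")
    ssrt <- summarize_session(session)$ssrt
  }
  tr <- stop_epochs$trials
  go_rt <- go_epochs$trials$rt_ms
  d <- dim(stop_epochs$data)
  nch <- d[2]
  go_flat <- matrix(go_epochs$data, dim(go_epochs$data)[1])

  corrected <- stop_epochs$data
  n_fallback <- 0L
  for (i in seq_len(d[1])) {
    rows <- if (isTRUE(tr$stop_success[i])) {
      which(go_rt > tr$ssd_ms[i] + ssrt)
    } else {
      which(abs(go_rt - tr$rt_ms[i]) <= rt_tol)
    }
    if (length(rows) == 0) {
      rows <- seq_along(go_rt)
      n_fallback <- n_fallback + 1L
    }
    sub <- shift_go_mean(go_flat, rows, nch, go_epochs$times,
                         stop_epochs$times, tr$ssd_ms[i])
    corrected[i, , ] <- corrected[i, , ] - sub
  }
  if (n_fallback > 0)
    warning(n_fallback, " stop trial(s) had no matching Go trials; ",
            "corrected with the grand Go average")

  avg_class <- function(success, tag) {
    rows <- which(tr$stop_success == success)
    if (length(rows) == 0) return(NULL)
    ep <- eeg_epochs(corrected[rows, , , drop = FALSE], stop_epochs$srate,
                     stop_epochs$times, "STOP_CUE", stop_epochs$labels,
                     tr[rows, ])
    average_erp(ep, baseline = baseline, condition = tag)
  }
  list(erp_ss = avg_class(TRUE, "SS"), erp_us = avg_class(FALSE, "US"),
       ssrt = ssrt, n_fallback = n_fallback)
}

#' Global field power of an ERP
#'
#' Per-sample scalar defined as the sum over electrodes of the absolute
#' deviation of the ERP from the scalp-wide average:
#' GFP(t) = sum_c | x_c(t) - mean_c x_c(t) |. Note this is the
#' absolute-deviation variant, not the conventional RMS global field power.
#' Invariant under any channel-constant offset; zero whenever all channels
#' are equal.
#'
#' @param erp an [new_erp()] object with at least two channels.
#' @return object of class `gfp_series` with `values`, `times`, `srate`.
#' @export
compute_gfp <- function(erp) {
  stopifnot(inherits(erp, "erp"))
  if (nrow(erp$data) < 2) stop("GFP is undefined for a single channel")
  dev <- sweep(erp$data, 2, colMeans(erp$data))
  structure(list(values = colSums(abs(dev)), times = erp$times,
                 srate = erp$srate, condition = erp$condition),
            class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("GFP series: %d samples, max %.2f at %g ms\n",
              length(x$values), max(x$values), x$times[which.max(x$values)]))
  invisible(x)
}

#' Windowed peak amplitude and latency measures
#'
#' Within each component's search window, returns the largest strict local
#' extremum of the requested polarity (neighbors taken from the full series,
#' so a window-edge sample can still qualify as a local extremum; plateaus
#' take their earliest sample; ties in height break to the earliest
#' latency). If the window contains no local extremum, the window-edge
#' maximum is returned with `edge = TRUE`.
#'
#' @param series numeric signal values, a `gfp_series`, or an `erp` (in
#'   which case `channel` selects the electrode, e.g. "F4").
#' @param times sample times in ms (ignored when `series` carries its own).
#' @param windows named list of length-2 search windows in ms; defaults to
#'   the canonical component windows N100 75-125, N200 175-225,
#'   P300 275-325 ms.
#' @param polarity named signs per component (+1 positive peak, -1 negative
#'   trough). GFP series are always searched for positive peaks.
#' @param channel electrode label when `series` is an `erp`.
#' @return data.frame with component, latency_ms, amplitude, window bounds
#'   and the `edge` flag.
#' @export
measure_peaks <- function(series, times = NULL,
                          windows = list(N100 = c(75, 125),
                                         N200 = c(175, 225),
                                         P300 = c(275, 325)),
                          polarity = c(N100 = -1, N200 = -1, P300 = 1),
                          channel = NULL) {
  if (inherits(series, "gfp_series")) {
    values <- series$values
    times <- series$times
    polarity[] <- 1
  } else if (inherits(series, "erp")) {
    if (is.null(channel)) stop("supply channel= to measure peaks on an ERP")
    ci <- match(channel, series$labels)
    if (is.na(ci)) stop("channel ", channel, " not in ERP")
    values <- series$data[ci, ]
    times <- series$times
  } else {
    values <- as.numeric(series)
    if (is.null(times)) stop("supply times= for a bare numeric series")
  }
  n <- length(values)
  out <- lapply(names(windows), function(name) {
    w <- windows[[name]]
    if (w[1] < min(times) || w[2] > max(times))
      stop("search window for ", name, " outside the series extent")
    pol <- if (name %in% names(polarity)) polarity[[name]] else 1
    s <- pol * values
    idx <- which(times >= w[1] & times <= w[2])
    is_peak <- vapply(idx, function(i) {
      left <- if (i > 1) s[i] > s[i - 1] else TRUE
      right <- if (i < n) s[i] >= s[i + 1] else TRUE
      left && right
    }, logical(1))
    cand <- idx[is_peak]
    if (length(cand)) {
      best <- cand[which.max(s[cand])]   # which.max -> earliest on ties
      edge <- FALSE
    } else {
      best <- idx[which.max(s[idx])]
      edge <- TRUE
    }
    data.frame(component = name, latency_ms = times[best],
               amplitude = values[best], window_lo = w[1], window_hi = w[2],
               edge = edge, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
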