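make_epochs <- function(data, srate = 250, t0 = -200) {
  d <- dim(data)
  times <- seq(t0, by = 1000 / srate, length.out = d[3])
  eeg_epochs(data, srate, times, "STOP_CUE", paste0("ch", seq_len(d[2])),
             data.frame(index = seq_len(d[1])))
}

test_that("band-pass removes DC and the low-pass preserves in-band tones", {
  # DC epochs through a 1-45 Hz band-pass vanish
  dc <- make_epochs(array(5, c(2, 3, 500)))
  out <- preprocess(dc, band = c(1, 45))
  expect_lt(max(abs(out$data)), 0.05)

  # a 10 Hz tone survives a 30 Hz low-pass within 1%
  t <- seq(0, 1.996, by = 1 / 250)
  tone <- sin(2 * pi * 10 * t)
  ep <- make_epochs(array(rep(tone, each = 1), c(1, 1, length(t))))
  out <- preprocess(ep, band = c(NA, 30))
  mid <- 150:350
  expect_equal(max(abs(out$data[1, 1, mid])), 1, tolerance = 0.01)

  expect_error(preprocess(ep, band = c(1, 200)), "Nyquist")
})

test_that("decimation from 2500 to 250 Hz yields 10x fewer samples", {
  t <- seq(0, 0.9996, by = 1 / 2500)
  ep <- make_epochs(array(sin(2 * pi * 5 * t), c(1, 2, length(t))),
                    srate = 2500, t0 = 0)
  out <- preprocess(ep, band = c(NA, 30), target_srate = 250)
  expect_equal(out$srate, 250)
  expect_equal(dim(out$data)[3], 250)
  expect_error(preprocess(ep, band = c(NA, 30), target_srate = 300),
               "divide")
})

test_that("averaging re-references and baseline-corrects as specified", {
  set.seed(1)
  data <- array(rnorm(4 * 5 * 176), c(4, 5, 176))
  ep <- make_epochs(data)
  erp <- average_erp(ep, baseline = c(-150, -50))
  # channel mean at every sample is zero after common-average referencing
  expect_lt(max(abs(colMeans(erp$data))), 1e-9)
  # single trial -> referenced, baseline-subtracted copy of that trial
  ep1 <- make_epochs(data[1, , , drop = FALSE])
  e1 <- average_erp(ep1)
  m <- data[1, , ]
  m <- sweep(m, 2, colMeans(m))
  bi <- ep1$times >= -150 & ep1$times <= -50
  m <- m - rowMeans(m[, bi])
  expect_equal(e1$data, m, tolerance = 1e-12)
  # adding a channel-constant offset to all trials changes nothing
  erp2 <- average_erp(make_epochs(data + 5), baseline = c(-150, -50))
  expect_equal(erp2$data, erp$data, tolerance = 1e-10)
  expect_error(average_erp(ep, baseline = c(-300, -250)), "baseline")
})

test_that("GFP matches hand arithmetic and its invariances", {
  erp2 <- new_erp(matrix(c(1, -1), 2, 1), 250, 0, c("a", "b"), "STOP_CUE", 1)
  expect_equal(compute_gfp(erp2)$values, 2)
  erp3 <- new_erp(matrix(c(1, 2, 6), 3, 1), 250, 0, c("a", "b", "c"),
                  "STOP_CUE", 1)
  expect_equal(compute_gfp(erp3)$values, 6)
  # all channels equal -> zero everywhere
  erpc <- new_erp(matrix(3, 4, 10), 250, 1:10, paste0("c", 1:4), "STOP_CUE", 1)
  expect_true(all(compute_gfp(erpc)$values == 0))
  # channel-constant offsets leave GFP unchanged; values are non-negative
  set.seed(2)
  m <- matrix(rnorm(40), 4, 10)
  e <- new_erp(m, 250, 1:10, paste0("c", 1:4), "STOP_CUE", 1)
  e_off <- new_erp(m + 7, 250, 1:10, paste0("c", 1:4), "STOP_CUE", 1)
  expect_equal(compute_gfp(e)$values, compute_gfp(e_off)$values)
  expect_true(all(compute_gfp(e)$values >= 0))
  e1 <- new_erp(m[1, , drop = FALSE], 250, 1:10, "c1", "STOP_CUE", 1)
  expect_error(compute_gfp(e1), "single channel")
})

test_that("peak detection picks windowed local extrema with tie rules", {
  times <- seq(0, 400, by = 4)
  bump <- function(lat, h, w = 15) h * exp(-((times - lat)^2) / (2 * w^2))
  # single bump at 200
  p <- measure_peaks(bump(200, 3), times,
                     windows = list(N200 = c(175, 225)),
                     polarity = c(N200 = 1))
  expect_equal(p$latency_ms, 200)
  expect_equal(p$amplitude, 3, tolerance = 1e-6)
  expect_false(p$edge)
  # two bumps at 190 and 210, heights 1 and 2 -> 210 wins
  t2 <- seq(0, 400, by = 2)
  bump2 <- function(lat, h, w) h * exp(-((t2 - lat)^2) / (2 * w^2))
  p2 <- measure_peaks(bump2(190, 1, 6) + bump2(210, 2, 6), t2,
                      windows = list(N200 = c(175, 225)),
                      polarity = c(N200 = 1))
  expect_equal(p2$latency_ms, 210)
  # negative polarity finds the trough
  p3 <- measure_peaks(-bump(100, 4), times, windows = list(N100 = c(75, 125)),
                      polarity = c(N100 = -1))
  expect_equal(p3$latency_ms, 100)
  expect_equal(p3$amplitude, -4, tolerance = 1e-6)
  # monotone signal in the window -> edge maximum with flag
  p4 <- measure_peaks(times / 100, times, windows = list(X = c(100, 200)),
                      polarity = c(X = 1))
  expect_true(p4$edge)
  expect_equal(p4$latency_ms, 200)
  expect_error(measure_peaks(bump(200, 1), times,
                             windows = list(X = c(-100, 50))), "outside")
})

test_that("Go-process correction recovers the inhibition template", {
  s <- simulate_session(task_config(), race_params(), seed = 6)
  tmpl <- tiny_templates()
  eeg <- synthesize_eeg(s, tmpl, noise_sd = 0.3, seed = 6)
  corr <- go_correction(eeg$stop, eeg$go, session = s)
  gt <- attr(eeg$stop, "ground_truth")
  gt <- sweep(gt, 2, colMeans(gt))
  bi <- eeg$stop$times >= -150 & eeg$stop$times <= -50
  gt <- gt - rowMeans(gt[, bi])
  expect_gt(cor(as.vector(corr$erp_ss$data), as.vector(gt)), 0.95)
  # the corrected average must beat the uncorrected one
  ss_rows <- which(eeg$stop$trials$stop_success)
  raw <- average_erp(eeg_epochs(eeg$stop$data[ss_rows, , , drop = FALSE],
                                eeg$stop$srate, eeg$stop$times, "STOP_CUE",
                                eeg$stop$labels, eeg$stop$trials[ss_rows, ]))
  expect_gt(cor(as.vector(corr$erp_ss$data), as.vector(gt)),
            cor(as.vector(raw$data), as.vector(gt)))
})

test_that("correction branches differ by success status and scale linearly", {
  s <- simulate_session(task_config(), race_params(), seed = 7)
  tmpl <- tiny_templates()
  eeg <- synthesize_eeg(s, tmpl, noise_sd = 0.3, seed = 7)
  corr <- go_correction(eeg$stop, eeg$go, session = s)

  # swapping the success flags changes the subtrahend sets
  swapped <- eeg$stop
  swapped$trials$stop_success <- !swapped$trials$stop_success
  swapped$trials$rt_ms <- ifelse(is.na(swapped$trials$rt_ms),
                                 mean(eeg$go$trials$rt_ms),
                                 swapped$trials$rt_ms)
  corr_sw <- suppressWarnings(go_correction(swapped, eeg$go, session = s))
  expect_false(isTRUE(all.equal(corr$erp_ss$data, corr_sw$erp_us$data)))

  # zero Go epochs -> correction is the identity on the SS average
  go0 <- eeg$go
  go0$data[] <- 0
  corr0 <- go_correction(eeg$stop, go0, session = s)
  ss_rows <- which(eeg$stop$trials$stop_success)
  raw <- average_erp(eeg_epochs(eeg$stop$data[ss_rows, , , drop = FALSE],
                                eeg$stop$srate, eeg$stop$times, "STOP_CUE",
                                eeg$stop$labels, eeg$stop$trials[ss_rows, ]),
                     condition = "SS")
  expect_equal(corr0$erp_ss$data, raw$data, tolerance = 1e-12)

  # linearity: scaling both inputs scales the output
  sc <- function(ep, a) { ep$data <- ep$data * a; ep }
  corr2 <- go_correction(sc(eeg$stop, 2), sc(eeg$go, 2), ssrt = corr$ssrt)
  expect_equal(corr2$erp_ss$data, 2 * corr$erp_ss$data, tolerance = 1e-9)
})
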