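pure_theta <- function(duration = 10, seed = 1)
  generate_lfp(sim_config(duration = duration, swr_rate = 0, ds_rate = 0,
                          noise_sd = 0, seed = seed))

test_that("zero-phase band-pass preserves passband and rejects stopband", {
  fs <- 1250
  t <- (0:(10 * fs - 1)) / fs
  x8 <- sin(2 * pi * 8 * t)
  y8 <- bandpass_filter(x8, 4, 12, fs)
  core <- (2 * fs):(8 * fs)
  expect_lt(max(abs(y8[core] - x8[core])), 0.01)
  # peak times shift less than one sample (compare within one cycle)
  win <- (5 * fs):(5 * fs + fs / 8)
  pk_in <- which.max(x8[win]); pk_out <- which.max(y8[win])
  expect_lt(abs(pk_in - pk_out), 1.5)

  x50 <- sin(2 * pi * 50 * t)
  y50 <- bandpass_filter(x50, 4, 12, fs)
  expect_lt(max(abs(y50[core])), 0.01)

  # forward-backward impulse response is symmetric about its center
  imp <- numeric(4 * fs); imp[2 * fs] <- 1
  h <- bandpass_filter(imp, 4, 12, fs)
  i <- which.max(abs(h))
  w <- 300
  expect_equal(h[(i - w):(i + w)], rev(h[(i - w):(i + w)]), tolerance = 1e-6)

  expect_error(bandpass_filter(x8, 4, 700, fs), "Nyquist")
})

test_that("theta epochs cover oscillatory segments and reject noise", {
  sim <- pure_theta(10)
  ep <- detect_theta_epochs(sim$lfp)
  expect_equal(nrow(ep), 1)
  expect_gt(sum(ep$offset_s - ep$onset_s), 9.5)

  set.seed(2)
  noise <- lfp_recording(matrix(rnorm(10 * 1250, sd = 50), 1), 1250, "CA1-SP")
  expect_equal(nrow(detect_theta_epochs(noise)), 0)

  # 5 s theta then 5 s noise: boundary recovered within 0.25 s
  set.seed(3)
  fs <- 1250
  t <- (0:(5 * fs - 1)) / fs
  x <- c(100 * cos(2 * pi * 8 * t) + rnorm(5 * fs, sd = 20),
         rnorm(5 * fs, sd = 300))
  mixed <- lfp_recording(matrix(x, 1), fs, "CA1-SP")
  ep2 <- detect_theta_epochs(mixed)
  expect_equal(nrow(ep2), 1)
  expect_lt(abs(ep2$offset_s - 5), 0.25)
  expect_lt(ep2$onset_s, 0.25)

  expect_error(detect_theta_epochs(sim$lfp, channel = "CA2"), "absent")
})

test_that("theta cycles are segmented peak-to-peak with anchored phase", {
  sim <- pure_theta(10)
  fs <- sim$lfp$sampling_rate
  ep <- detect_theta_epochs(sim$lfp)
  seg <- segment_theta_cycles(sim$lfp, ep)
  n_cyc <- nrow(seg$events)
  expect_true(abs(n_cyc - 80) <= 2)
  durations <- seg$events$offset_s - seg$events$onset_s
  expect_true(all(abs(durations - 0.125) <= 1.5 / fs))

  # phase convention: 0 at waveform maxima, 180 at minima
  sp <- sim$lfp$samples["CA1-SP", ]
  n <- length(sp)
  pk <- which(sp[2:(n - 1)] >= sp[1:(n - 2)] & sp[2:(n - 1)] > sp[3:n]) + 1L
  tr <- which(sp[2:(n - 1)] <= sp[1:(n - 2)] & sp[2:(n - 1)] < sp[3:n]) + 1L
  pk <- pk[seg$phases$valid[pk]]; tr <- tr[seg$phases$valid[tr]]
  expect_lt(max(ang_diff(seg$phases$phase_deg[pk], 0)), 5)
  expect_lt(max(ang_diff(seg$phases$phase_deg[tr], 180)), 5)
})

test_that("SWR detection pairs ripples with sharp waves at ground truth times", {
  cfg <- sim_config(duration = 60, swr_rate = 0.1, ds_rate = 0, seed = 21)
  sim <- generate_lfp(cfg)
  swr <- detect_swr(sim$lfp)
  truth <- sim$truth$event_times$swr
  expect_equal(nrow(swr), length(truth))
  err <- vapply(truth, function(t) min(abs(swr$peak_s - t)), numeric(1))
  expect_lt(max(err), 0.010)
  expect_true(all(swr$peak_amplitude >= 3))

  # ripple burst without a radiatum sharp wave is not an SWR
  cfg2 <- sim_config(duration = 60, swr_rate = 0.1, ds_rate = 0, seed = 22,
                     sharpwave_amp = 0)
  sim2 <- generate_lfp(cfg2)
  expect_equal(nrow(detect_swr(sim2$lfp)), 0)

  # pure noise at a 5 SD threshold stays silent
  for (s in 1:5) {
    set.seed(s)
    noise <- lfp_recording(matrix(rnorm(2 * 30 * 1250, sd = 30), 2),
                           1250, c("CA1-SP", "CA1-SR"))
    expect_equal(nrow(detect_swr(noise, threshold_sd = 5)), 0)
  }
  expect_error(detect_swr(sim$lfp, threshold_sd = 10), "threshold_sd")
})

test_that("DS detection recovers hilar deflections and rejects degenerate input", {
  cfg <- sim_config(duration = 120, swr_rate = 0, ds_rate = 0.2, seed = 31)
  sim <- generate_lfp(cfg)
  ds <- detect_ds(sim$lfp)
  truth <- sim$truth$event_times$ds
  hits <- vapply(truth, function(t) any(abs(ds$peak_s - t) < 0.02), logical(1))
  expect_gte(mean(hits), 0.95)
  expect_true(all(diff(ds$peak_s) > 0))
  expect_true(all(ds$onset_s[-1] >= ds$offset_s[-nrow(ds)]))

  flat <- lfp_recording(matrix(0, 1, 1000), 1000, "hilus")
  expect_error(detect_ds(flat), "zero SD")
})

test_that("detection is equivariant to circular time shifts", {
  cfg <- sim_config(duration = 60, swr_rate = 0.1, ds_rate = 0.1, seed = 41)
  sim <- generate_lfp(cfg)
  fs <- sim$lfp$sampling_rate
  k <- 5 * fs  # 5 s shift
  shifted <- sim$lfp
  shifted$samples <- shifted$samples[, c((k + 1):ncol(shifted$samples), 1:k),
                                     drop = FALSE]
  ds_a <- detect_ds(sim$lfp)$peak_s
  ds_b <- detect_ds(shifted)$peak_s
  # interior events (away from the wrap point) shift by exactly k samples
  dur <- ncol(sim$lfp$samples) / fs
  interior <- ds_a[ds_a > k / fs + 1 & ds_a < dur - 1]
  expected <- interior - k / fs
  for (e in expected)
    expect_lt(min(abs(ds_b - e)), 1.5 / fs)
})
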