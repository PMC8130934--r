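make_phase_series <- function(duration = 10, seed = 1) {
  sim <- generate_lfp(sim_config(duration = duration, swr_rate = 0,
                                 ds_rate = 0, noise_sd = 0, seed = seed))
  ep <- detect_theta_epochs(sim$lfp)
  list(sim = sim, seg = segment_theta_cycles(sim$lfp, ep), epochs = ep)
}

test_that("spike phases hit the anchoring convention at peaks and troughs", {
  ps <- make_phase_series()
  f <- 8
  peak_times <- (5:60) / f          # sine maxima
  trough_times <- (5:60) / f + 1 / (2 * f)
  expect_lt(max(ang_diff(spike_phases(peak_times, ps$seg$phases), 0)), 5)
  expect_lt(max(ang_diff(spike_phases(trough_times, ps$seg$phases), 180)), 5)
})

test_that("generator phase preference is recovered through the phase series", {
  ps <- make_phase_series(duration = 120)
  spk <- generate_spikes(list(u = unit_spec(baseline_rate = 10, kappa = 4,
                                            pref_phase_deg = 90)),
                         ps$sim$truth, seed = 7)
  ph <- spike_phases(spk$spikes$time_s, ps$seg$phases)
  expect_gt(length(ph), 1000)
  cm <- circular_mean_mvl(ph)
  expect_lt(ang_diff(cm$mu_deg, 90), 5)
})

test_that("circular mean and MVL match closed-form cases", {
  res <- circular_mean_mvl(c(10, 350), min_n = 2)
  expect_equal(res$mu_deg, 0)
  expect_equal(res$r, cos(pi * 10 / 180))

  expect_equal(circular_mean_mvl(rep(123, 30))$r, 1)
  expect_equal(circular_mean_mvl(rep(123, 30))$mu_deg, 123)

  unif <- circular_mean_mvl(c(0, 90, 180, 270), min_n = 4)
  expect_true(unif$undefined)
  expect_equal(unif$r, 0)

  low_n <- circular_mean_mvl(c(1, 2, 3))
  expect_true(low_n$undefined)
  expect_match(low_n$reason, "below minimum")
})

test_that("phase statistics are rotation-equivariant and unit-invariant", {
  set.seed(8)
  ph <- hippophen:::rvonmises_deg(500, 120, 3)
  base <- circular_mean_mvl(ph)
  for (delta in c(45, 180, 300)) {
    rot <- circular_mean_mvl(wrap360(ph + delta))
    expect_lt(ang_diff(rot$mu_deg, base$mu_deg + delta), 1e-6)
    expect_equal(rot$r, base$r)
  }
  # duplicating the phase list changes n but not r
  expect_equal(circular_mean_mvl(c(ph, ph))$r, base$r)
})

test_that("event ratio recovers no-modulation, silencing and generator gain", {
  set.seed(9)
  span <- c(0, 600)
  events <- data.frame(onset_s = seq(20, 590, by = 28),
                       peak_s = seq(20, 590, by = 28) + 0.02,
                       offset_s = seq(20, 590, by = 28) + 0.05)
  pois <- sort(runif(60000, 0, 600))
  r0 <- event_ratio(pois, events, span)
  expect_equal(r0$ratio, 1, tolerance = 0.1)

  half <- 0.025
  silenced <- pois[vapply(pois, function(s)
    all(abs(s - events$peak_s) > half), logical(1))]
  expect_equal(event_ratio(silenced, events, span)$ratio, 0)

  cfg <- sim_config(duration = 600, ds_rate = 0, seed = 10)
  truth <- generate_lfp(cfg)$truth
  spk <- generate_spikes(list(u = unit_spec(baseline_rate = 8, kappa = 0,
                                            swr_gain = 4)), truth, seed = 11)
  ev <- data.frame(onset_s = truth$event_times$swr - 0.05,
                   peak_s = truth$event_times$swr,
                   offset_s = truth$event_times$swr + 0.05)
  r4 <- event_ratio(spk$spikes$time_s, ev, span)
  expect_equal(r4$ratio, 4, tolerance = 0.125)
  expect_false(r4$undefined)

  few <- event_ratio(pois, events[1:3, ], span)
  expect_true(few$undefined)
})

test_that("event ratio is invariant to uniform time rescaling", {
  set.seed(12)
  times <- sort(runif(500, 0, 100))
  events <- data.frame(onset_s = c(10, 40, 70), peak_s = c(10.1, 40.1, 70.1),
                       offset_s = c(10.2, 40.2, 70.2))
  a <- event_ratio(times, events, c(0, 100), min_events = 3)
  k <- 3.7
  ev_k <- events * k
  b <- event_ratio(times * k, ev_k, c(0, 100 * k),
                   peak_window_ms = 50 * k, baseline_pad_s = 0.1 * k,
                   min_events = 3)
  expect_equal(a$ratio, b$ratio)
})

test_that("interval membership matches the naive definition", {
  set.seed(33)
  for (i in 1:30) {
    n_iv <- sample(1:8, 1)
    lo <- sort(runif(n_iv, 0, 10))
    hi <- lo + runif(n_iv, 0.05, 2)  # may overlap
    x <- c(runif(50, -1, 12), lo, hi)  # include exact boundary points
    naive <- vapply(x, function(s) any(s >= lo & s <= hi), logical(1))
    expect_identical(hippophen:::in_intervals(x, lo, hi), naive)
  }
})

test_that("bursting index counts complex-spike members per the ISI rule", {
  epochs <- data.frame(onset_s = 0, offset_s = 100)
  sparse <- seq(1, 10, by = 1)
  expect_equal(bursting_index(sparse, epochs)$index, 0)

  with_triplet <- c(1, 2, 3, 4, 5, 6, 7, 50, 50.004, 50.008)
  expect_equal(bursting_index(with_triplet, epochs)$index, 0.3)

  all_burst <- seq(0, by = 0.004, length.out = 12)
  expect_equal(bursting_index(all_burst, epochs)$index, 1)

  # a pair (2 spikes < 8 ms) is not a complex spike
  with_pair <- c(1, 2, 3, 50, 50.004)
  expect_equal(bursting_index(with_pair, epochs)$index, 0)

  none <- bursting_index(c(200, 201), epochs)
  expect_true(none$undefined)
})

test_that("autocorrelogram is symmetric with peaks at the train period", {
  per <- seq(0, 5, by = 0.1)
  ac <- autocorrelogram(per, bin_ms = 2.5, window_ms = 250)
  peaks <- ac$lag_ms[ac$counts > 0]
  expect_true(all(abs(abs(peaks) %% 100) < 2.6 |
                    abs(abs(peaks) %% 100 - 100) < 2.6))
  expect_equal(ac$counts, rev(ac$counts))

  set.seed(13)
  rnd <- sort(runif(300, 0, 60))
  ac2 <- autocorrelogram(rnd)
  expect_equal(ac2$counts, rev(ac2$counts))

  expect_equal(sum(autocorrelogram(c(1))$counts), 0)
})

test_that("Poisson autocorrelograms are flat at the 1 percent level", {
  n_sig <- 0
  for (s in 1:20) {
    set.seed(s)
    times <- sort(runif(800, 0, 200))
    ac <- autocorrelogram(times, bin_ms = 2.5, window_ms = 100)
    keep <- ac$lag_ms > 0  # one side; the other is its mirror
    p <- suppressWarnings(stats::chisq.test(ac$counts[keep])$p.value)
    if (p < 0.01) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 2)
})

test_that("membrane biophysics recovers the generating cell parameters", {
  cell <- list(vrest_mV = -62, rin_Mohm = 40, tau_ms = 20,
               ap_threshold_mV = 7, ap_peak_trough_ms = 0.9, fahp_mV = 3)
  protocol <- data.frame(onset_s = c(0.5, 1.5, 2.5),
                         duration_ms = 500, current_nA = c(-0.2, 0.1, 0.3))
  mb <- membrane_biophysics(generate_vm(protocol, cell))
  expect_equal(mb$vrest_mV, -62, tolerance = 0.01)
  expect_equal(mb$rin_Mohm, 40, tolerance = 0.01)
  expect_equal(mb$tau_ms, 20, tolerance = 0.5)
  expect_true(mb$ap_defined)
  expect_equal(mb$ap_threshold_mV, 7, tolerance = 0.5)
  expect_equal(mb$ap_peak_trough_ms, 0.9, tolerance = 0.05)
  expect_equal(mb$fahp_mV, 3, tolerance = 0.7)

  # exact three-point regression
  flat <- membrane_biophysics(generate_vm(
    data.frame(onset_s = c(0.5, 1.5, 2.5), duration_ms = 500,
               current_nA = c(-0.2, 0, 0.2)),
    list(vrest_mV = -62, rin_Mohm = 40, tau_ms = 20, ap_threshold_mV = 50)))
  expect_equal(flat$vrest_mV, -62, tolerance = 1e-3)
  expect_equal(flat$rin_Mohm, 40, tolerance = 1e-2)
  expect_false(flat$ap_defined)

  one_level <- generate_vm(data.frame(onset_s = 0.5, duration_ms = 500,
                                      current_nA = 0.1),
                           list(ap_threshold_mV = 50))
  expect_error(membrane_biophysics(one_level), "2 distinct")
})
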