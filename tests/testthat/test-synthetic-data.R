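noise_free_cfg <- function(duration = 10, seed = 1, ...)
  sim_config(duration = duration, swr_rate = 0, ds_rate = 0, noise_sd = 0,
             seed = seed, ...)

test_that("noise-free theta is a pure sinusoid with the configured layer lags", {
  sim <- generate_lfp(noise_free_cfg())
  sp <- sim$lfp$samples["CA1-SP", ]
  fs <- sim$lfp$sampling_rate
  n <- length(sp)
  pk <- which(sp[2:(n - 1)] >= sp[1:(n - 2)] & sp[2:(n - 1)] > sp[3:n]) + 1L
  expect_equal(diff(pk) / fs, rep(0.125, length(pk) - 1L), tolerance = 0.01)
  expect_equal(max(sp), 100, tolerance = 1e-6)
  # SR configured at -60 degrees: cross-correlation lag is -60/360 cycle
  sr <- sim$lfp$samples["CA1-SR", ]
  lag <- which.max(stats::ccf(sp, sr, lag.max = fs / 8, plot = FALSE)$acf) -
    (fs / 8 + 1)
  expect_lt(abs(lag / fs - (-(60 / 360) * 0.125)), 2 / fs)
})

test_that("identical seeds give identical LFP and ground truth", {
  a <- generate_lfp(sim_config(duration = 12, seed = 9))
  b <- generate_lfp(sim_config(duration = 12, seed = 9))
  expect_identical(a$lfp$samples, b$lfp$samples)
  expect_identical(a$truth$event_times, b$truth$event_times)
  c <- generate_lfp(sim_config(duration = 12, seed = 10))
  expect_false(identical(a$lfp$samples, c$lfp$samples))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(duration = 0), "duration")
  expect_error(sim_config(sampling_rate = 500, swr_ripple_freq = 150),
               "4 x")
  expect_error(sim_config(swr_rate = -1), "rates")
  expect_error(unit_spec(kappa = -1), "kappa")
  expect_error(generate_lfp(sim_config(duration = 0.3, swr_rate = 20,
                                       seed = 1)),
               "too short")
})

test_that("spike phases follow the von Mises target", {
  truth <- generate_lfp(noise_free_cfg(duration = 1000))$truth
  # kappa = 0: uniform phases, MVL near zero
  spk0 <- generate_spikes(list(u = unit_spec(baseline_rate = 10, kappa = 0)),
                          truth, seed = 1)
  expect_gt(nrow(spk0$truth), 5000)
  expect_lt(circular_mean_mvl(spk0$truth$phase_deg)$r, 0.05)
  # kappa = 2: closed-form MVL I1(2)/I0(2)
  spk2 <- generate_spikes(list(u = unit_spec(baseline_rate = 10, kappa = 2,
                                             pref_phase_deg = 90)),
                          truth, seed = 2)
  cm <- circular_mean_mvl(spk2$truth$phase_deg)
  expect_equal(cm$r, vonmises_mvl(2), tolerance = 0.02)
  expect_lt(ang_diff(cm$mu_deg, 90), 3)
})

test_that("event gain modulates in-window firing by the configured factor", {
  cfg <- sim_config(duration = 600, ds_rate = 0, seed = 3)
  truth <- generate_lfp(cfg)$truth
  spk <- generate_spikes(list(u = unit_spec(baseline_rate = 8, kappa = 0,
                                            swr_gain = 4)), truth, seed = 4)
  ratio <- oracle_event_rate_ratio(spk$spikes$time_s,
                                   truth$event_times$swr, 0.025, c(0, 600))
  expect_equal(ratio, 4, tolerance = 0.6)
})

test_that("spike generation contracts: empty input, conservation, bursts", {
  truth <- generate_lfp(noise_free_cfg(duration = 20))$truth
  empty <- generate_spikes(list(), truth)
  expect_equal(nrow(empty$spikes), 0)

  spk <- generate_spikes(list(a = unit_spec(baseline_rate = 5),
                              b = unit_spec(baseline_rate = 2)),
                         truth, seed = 5)
  # conservation: every ground-truth spike reaches the written CSV
  p <- withr::local_tempfile(fileext = ".csv")
  write_spikes(spk$spikes, p)
  expect_equal(nrow(read_spikes(p)), nrow(spk$truth))

  spkb <- generate_spikes(list(a = unit_spec(baseline_rate = 5,
                                             burst_prob = 1,
                                             intra_burst_isi_ms = 4)),
                          truth, seed = 6)
  isi <- diff(spkb$spikes$time_s)
  expect_gt(mean(isi < 0.008), 0.5)  # dominated by intra-burst intervals
})

test_that("Vm traces obey Ohmic scaling and the configured time constant", {
  cell <- list(vrest_mV = -62, rin_Mohm = 40, tau_ms = 20,
               ap_threshold_mV = 50)  # no spikes
  vm0 <- generate_vm(data.frame(onset_s = 0.5, duration_ms = 500,
                                current_nA = 0), cell)
  expect_equal(stats::median(vm0$voltage_mV), -62, tolerance = 1e-9)

  vm <- generate_vm(data.frame(onset_s = 0.5, duration_ms = 500,
                               current_nA = 0.2), cell)
  i_end <- round((0.5 + 0.45) * vm$sampling_rate)
  expect_equal(vm$voltage_mV[i_end] - (-62), 8, tolerance = 0.01)

  # independent log-linear fit of the onset exponential recovers tau
  fs <- vm$sampling_rate
  seg <- (round(0.5 * fs) + 2):(round(0.56 * fs))
  y <- log(-54 - vm$voltage_mV[seg])
  t_ms <- (seg - seg[1]) / fs * 1000
  fit <- stats::lm(y ~ t_ms)
  expect_equal(-1 / unname(stats::coef(fit)[2]), 20, tolerance = 0.5)

  expect_error(generate_vm(data.frame(onset_s = 0.1, duration_ms = 500,
                                      current_nA = 0),
                           list(tau_ms = -1)), "tau")
  expect_error(generate_vm(data.frame(onset_s = c(0.1, 0.2),
                                      duration_ms = c(500, 500),
                                      current_nA = c(0, 0.1)), cell),
               "overlap")
})

test_that("evidence tables invert the site/convention map and are reproducible", {
  truth_tab <- default_type_truth()
  expect_equal(length(unique(truth_tab$type_id)), 35)

  ev1 <- generate_evidence_table(seed = 11)
  ev2 <- generate_evidence_table(seed = 11)
  expect_identical(ev1$value, ev2$value)

  # a 180-degree CA1-SP truth reported at CA3c (offset -180) reads 0
  one <- truth_tab[truth_tab$lfp_site == "CA3c", ][1, ]
  one$theta_sd_deg <- 1
  one$theta_deg <- 180
  one$n_cells <- 200
  evc <- generate_evidence_table(one, seed = 1)
  rep_phase <- evc$value[evc$variable == "theta_phase"]
  expect_lt(ang_diff(aggregate_digitized(rep_phase)$mu_deg, 0), 1)

  # full round trip through normalization recovers the truth exactly
  norm <- normalize_evidence(ev1)
  expect_equal(nrow(attr(norm, "rejected")), 0)
  i <- norm$variable == "theta_phase"
  expect_lt(max(ang_diff(norm$value[i], attr(ev1, "truth")[i])), 1e-9)

  bad <- truth_tab[1, ]
  bad$lfp_site <- "CA1-SO"
  expect_error(generate_evidence_table(bad), "unknown site")
})
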