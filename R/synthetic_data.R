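#' @title Synthetic hippocampal recordings with ground truth
#' @description Generators for layered theta LFP with sharp-wave ripples and
#'   dentate spikes, von Mises phase-locked spike trains with event-gain
#'   modulation and bursting, current-step membrane-potential traces, and
#'   literature-style evidence tables. Every generator is deterministic given
#'   its seed and returns the ground truth needed to score the downstream
#'   detectors and estimators.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe the benchmark conditions used throughout the test
#' suite: 1250 samples/s, 8 Hz theta with per-layer amplitude and phase
#' shifts (CA1-SP reference at 0 degrees, CA1-SR at -60, hilus at -170),
#' 0.2 SWR/s and 0.2 DS/s, broadband noise of 20 uV SD, and event
#' amplitudes five times the standard deviation of the event-free
#' detection trace.
#'
#' @param sampling_rate samples per second; must be at least 4 x
#'   `swr_ripple_freq`.
#' @param duration recording length in seconds.
#' @param theta_freq theta frequency, Hz.
#' @param layer_amplitude named numeric vector: theta amplitude (uV) per
#'   generated layer/channel.
#' @param layer_phase_deg named numeric vector: theta phase shift (degrees)
#'   of each layer relative to CA1-SP.
#' @param swr_rate sharp-wave-ripple rate, events/s.
#' @param swr_ripple_freq ripple carrier frequency, Hz.
#' @param swr_ripple_amp ripple burst amplitude on the CA1-SP channel, uV.
#' @param sharpwave_amp sharp-wave deflection amplitude on CA1-SR, uV
#'   (applied as a negative deflection).
#' @param ds_rate dentate-spike rate, events/s.
#' @param ds_amp dentate-spike amplitude on the hilus channel, uV.
#' @param noise_sd white-noise SD per channel, uV.
#' @param min_event_gap_s minimum within-class separation between event
#'   peaks, s.
#' @param seed integer seed; identical seed implies identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 1250, duration = 600, theta_freq = 8,
                       layer_amplitude = c("CA1-SP" = 100, "CA1-SR" = 80,
                                           "hilus" = 60),
                       layer_phase_deg = c("CA1-SP" = 0, "CA1-SR" = -60,
                                           "hilus" = -170),
                       swr_rate = 0.2, swr_ripple_freq = 150,
                       swr_ripple_amp = 100, sharpwave_amp = 300,
                       ds_rate = 0.2, ds_amp = 250,
                       noise_sd = 20, min_event_gap_s = 0.2, seed = 1) {
  if (duration <= 0) stopf("duration must be > 0")
  if (sampling_rate < 4 * swr_ripple_freq)
    stopf("sampling_rate must be >= 4 x swr_ripple_freq (%g < %g)",
          sampling_rate, 4 * swr_ripple_freq)
  if (swr_rate < 0 || ds_rate < 0) stopf("event rates must be >= 0")
  if (!identical(sort(names(layer_amplitude)), sort(names(layer_phase_deg))))
    stopf("layer_amplitude and layer_phase_deg must name the same layers")
  layers <- names(layer_amplitude)
  bad <- setdiff(layers, layer_labels())
  if (length(bad)) stopf("unknown layer label(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(layers)) stopf("conflicting channel map: duplicated layers")
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 theta_freq = theta_freq,
                 layer_amplitude = layer_amplitude,
                 layer_phase_deg = layer_phase_deg,
                 swr_rate = swr_rate, swr_ripple_freq = swr_ripple_freq,
                 swr_ripple_amp = swr_ripple_amp, sharpwave_amp = sharpwave_amp,
                 ds_rate = ds_rate, ds_amp = ds_amp, noise_sd = noise_sd,
                 min_event_gap_s = min_event_gap_s, seed = seed),
            class = "sim_config")
}

# Place events uniformly, rejecting peaks closer than min_gap within the
# class and peaks within `edge` of the recording boundaries.
place_events <- function(rate, duration, min_gap, edge = 0.5) {
  if (rate <= 0) return(numeric(0))
  n_target <- stats::rpois(1L, rate * duration)
  if (n_target == 0L) return(numeric(0))
  if (duration <= 2 * edge + min_gap)
    stopf("duration %g s too short to place requested events", duration)
  times <- numeric(0)
  for (attempt in seq_len(50L * n_target)) {
    if (length(times) >= n_target) break
    cand <- stats::runif(1L, edge, duration - edge)
    if (!length(times) || min(abs(times - cand)) >= min_gap)
      times <- c(times, cand)
  }
  if (!length(times))
    stopf("duration %g s too short to place requested events", duration)
  sort(times)
}

gauss_bump <- function(t, center, sd) exp(-0.5 * ((t - center) / sd)^2)

#' Generate a layered LFP recording with ground truth
#'
#' Each configured layer becomes one channel carrying the theta oscillation
#' at its configured amplitude and phase shift relative to CA1-SP (whose
#' theta peak defines 0 degrees), plus white noise. SWR events add a
#' Gaussian-windowed ripple burst (SD 10 ms) on the CA1-SP channel and a
#' coincident negative sharp-wave deflection (SD 20 ms) on CA1-SR; dentate
#' spikes add a brief positive deflection (SD 5 ms) on the hilus channel.
#'
#' @param config a [sim_config()].
#' @return list with elements `lfp` (an [lfp_recording()]) and `truth`
#'   (class `ground_truth`: theta phase per sample, event peak times per
#'   class, and the generating config).
#' @export
generate_lfp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  layers <- names(config$layer_amplitude)

  swr_times <- if (config$swr_rate > 0) {
    if (!all(c("CA1-SP", "CA1-SR") %in% layers))
      stopf("SWR generation needs CA1-SP and CA1-SR channels")
    place_events(config$swr_rate, config$duration, config$min_event_gap_s)
  } else numeric(0)
  ds_times <- if (config$ds_rate > 0) {
    if (!("hilus" %in% layers))
      stopf("DS generation needs a hilus channel")
    place_events(config$ds_rate, config$duration, config$min_event_gap_s)
  } else numeric(0)

  samples <- matrix(0, nrow = length(layers), ncol = n,
                    dimnames = list(layers, NULL))
  omega <- 2 * pi * config$theta_freq
  for (i in seq_along(layers)) {
    ph <- deg2rad(config$layer_phase_deg[[layers[i]]])
    samples[i, ] <- config$layer_amplitude[[layers[i]]] * cos(omega * t + ph)
    if (config$noise_sd > 0)
      samples[i, ] <- samples[i, ] + stats::rnorm(n, sd = config$noise_sd)
  }
  for (tc in swr_times) {
    w <- which(abs(t - tc) < 0.1)
    env <- gauss_bump(t[w], tc, 0.010)
    samples["CA1-SP", w] <- samples["CA1-SP", w] +
      config$swr_ripple_amp * env * sin(2 * pi * config$swr_ripple_freq * (t[w] - tc))
    samples["CA1-SR", w] <- samples["CA1-SR", w] -
      config$sharpwave_amp * gauss_bump(t[w], tc, 0.020)
  }
  for (tc in ds_times) {
    w <- which(abs(t - tc) < 0.05)
    samples["hilus", w] <- samples["hilus", w] +
      config$ds_amp * gauss_bump(t[w], tc, 0.005)
  }

  truth <- structure(list(sampling_rate = fs, duration = config$duration,
                          theta_freq = config$theta_freq,
                          theta_phase_deg = wrap360(rad2deg(omega * t)),
                          event_times = list(swr = swr_times, ds = ds_times),
                          config = config),
                     class = "ground_truth")
  list(lfp = lfp_recording(samples, fs, layers), truth = truth)
}

#' Specification of one simulated unit
#'
#' Generative counterpart of the per-cell oscillatory phenotype: preferred
#' theta phase and von Mises concentration, firing-rate gains inside SWR and
#' DS peak windows, and complex-spike bursting.
#'
#' @param baseline_rate mean firing rate, spikes/s.
#' @param pref_phase_deg preferred theta phase, degrees (CA1-SP reference).
#' @param kappa von Mises concentration (>= 0; 0 means no phase preference).
#' @param swr_gain rate multiplier within +/-25 ms of SWR peaks (>= 0;
#'   1 means no modulation).
#' @param ds_gain rate multiplier within +/-25 ms of DS peaks.
#' @param burst_prob probability that a spike seeds a 3-spike burst.
#' @param intra_burst_isi_ms inter-spike interval inside a burst, ms.
#' @return a `unit_spec` list.
#' @export
unit_spec <- function(baseline_rate = 5, pref_phase_deg = 0, kappa = 1,
                      swr_gain = 1, ds_gain = 1, burst_prob = 0,
                      intra_burst_isi_ms = 4) {
  if (kappa < 0) stopf("kappa must be >= 0")
  if (swr_gain < 0 || ds_gain < 0) stopf("event gains must be >= 0")
  if (burst_prob < 0 || burst_prob > 1) stopf("burst_prob must be in [0, 1]")
  if (baseline_rate < 0) stopf("baseline_rate must be >= 0")
  structure(list(baseline_rate = baseline_rate,
                 pref_phase_deg = pref_phase_deg, kappa = kappa,
                 swr_gain = swr_gain, ds_gain = ds_gain,
                 burst_prob = burst_prob,
                 intra_burst_isi_ms = intra_burst_isi_ms),
            class = "unit_spec")
}

# Rate multiplier from event gains: gain applies within +/- half_window of
# each event peak; overlapping windows take the larger multiplier.
event_gain_at <- function(times, swr_times, ds_times, swr_gain, ds_gain,
                          half_window = 0.025) {
  g <- rep(1, length(times))
  near <- function(ev) {
    if (!length(ev)) return(rep(FALSE, length(times)))
    idx <- findInterval(times, ev)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(ev))
    pmin(abs(times - ev[lo]), abs(times - ev[hi])) <= half_window
  }
  in_swr <- near(swr_times)
  in_ds <- near(ds_times)
  g[in_swr] <- swr_gain
  both <- in_swr & in_ds
  g[in_ds & !both] <- ds_gain
  g[both] <- pmax(swr_gain, ds_gain)
  g
}

#' Generate phase-locked spike trains by Poisson thinning
#'
#' Spikes follow an inhomogeneous Poisson process whose rate is the
#' baseline rate times the von Mises phase kernel
#' exp(kappa * cos(theta - mu)) / I0(kappa) evaluated on the ground-truth
#' theta phase, times the SWR/DS gain inside +/-25 ms of event peaks.
#' Bursts are inserted post hoc as 3-spike groups at the configured
#' intra-burst interval and the train re-sorted.
#'
#' @param units list of [unit_spec()] objects (named, or auto-named u1..uN).
#' @param lfp_truth `ground_truth` from [generate_lfp()].
#' @param duration seconds of spiking to generate (defaults to the truth's
#'   duration).
#' @param seed integer seed.
#' @return list with `spikes` (data.frame `unit_id`, `time_s`) and `truth`
#'   (data.frame `unit_id`, `time_s`, `phase_deg` plus the unit parameters
#'   as attribute `units`).
#' @export
generate_spikes <- function(units, lfp_truth, duration = NULL, seed = 1) {
  stopifnot(inherits(lfp_truth, "ground_truth"))
  duration <- duration %||% lfp_truth$duration
  if (!length(units))
    return(list(spikes = data.frame(unit_id = character(0), time_s = numeric(0)),
                truth = data.frame(unit_id = character(0), time_s = numeric(0),
                                   phase_deg = numeric(0))))
  if (is.null(names(units)) || any(names(units) == ""))
    names(units) <- sprintf("u%d", seq_along(units))
  set.seed(seed)
  f <- lfp_truth$theta_freq
  phase_at <- function(tt) wrap360(360 * f * tt)
  swr_t <- lfp_truth$event_times$swr
  ds_t <- lfp_truth$event_times$ds

  out <- lapply(names(units), function(uid) {
    u <- units[[uid]]
    if (u$baseline_rate == 0)
      return(data.frame(unit_id = character(0), time_s = numeric(0),
                        phase_deg = numeric(0)))
    gmax <- max(1, u$swr_gain, u$ds_gain)
    lambda_max <- u$baseline_rate * exp(u$kappa) /
      besselI(u$kappa, 0) * gmax
    n_cand <- stats::rpois(1L, lambda_max * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    th <- phase_at(cand)
    kern <- exp(u$kappa * (cos(deg2rad(th - u$pref_phase_deg)) - 1))
    gain <- event_gain_at(cand, swr_t, ds_t, u$swr_gain, u$ds_gain)
    keep <- stats::runif(n_cand) < kern * gain / gmax
    times <- cand[keep]
    if (u$burst_prob > 0 && length(times)) {
      seeds <- stats::runif(length(times)) < u$burst_prob
      isi <- u$intra_burst_isi_ms / 1000
      extra <- c(times[seeds] + isi, times[seeds] + 2 * isi)
      times <- sort(c(times, extra))
      times <- times[times <= duration]
      times <- times[!duplicated(times)]
    }
    data.frame(unit_id = rep(uid, length(times)), time_s = times,
               phase_deg = phase_at(times))
  })
  truth <- do.call(rbind, out)
  rownames(truth) <- NULL
  attr(truth, "units") <- units
  list(spikes = truth[, c("unit_id", "time_s")], truth = truth)
}

#' Generate a current-step membrane-potential trace
#'
#' Passive RC response: each current step drives Vm toward
#' Vrest + I * Rin with exponential time constant tau; when the passive
#' voltage exceeds the spike threshold a stereotyped action-potential
#' template (linear rise, fall through a fast afterhyperpolarization
#' trough at the configured peak-trough delay) is added at the configured
#' suprathreshold firing rate.
#'
#' @param protocol data.frame with columns `onset_s`, `duration_ms`,
#'   `current_nA`; steps must not overlap.
#' @param cell list of cell parameters: `vrest_mV`, `rin_Mohm`, `tau_ms`,
#'   `ap_threshold_mV` (above resting baseline), `ap_amp_mV`, `fahp_mV`,
#'   `ap_peak_trough_ms`, `firing_rate_hz`.
#' @param seed integer seed (used when `noise_sd_mV > 0`).
#' @param sampling_rate samples/s of the trace.
#' @param noise_sd_mV additive Gaussian noise SD, mV.
#' @param total_duration_s trace length; defaults to the last step offset
#'   plus 0.5 s.
#' @return a `vm_trace` list: `voltage_mV`, `sampling_rate`, `steps`.
#' @export
generate_vm <- function(protocol, cell, seed = 1, sampling_rate = 10000,
                        noise_sd_mV = 0, total_duration_s = NULL) {
  defaults <- list(vrest_mV = -62, rin_Mohm = 40, tau_ms = 20,
                   ap_threshold_mV = 10, ap_amp_mV = 60, fahp_mV = 3,
                   ap_peak_trough_ms = 0.9, firing_rate_hz = 25)
  cell <- utils::modifyList(defaults, cell)
  if (cell$tau_ms <= 0) stopf("tau must be > 0")
  if (cell$rin_Mohm <= 0) stopf("Rin must be > 0")
  p <- protocol[order(protocol$onset_s), , drop = FALSE]
  off <- p$onset_s + p$duration_ms / 1000
  if (nrow(p) > 1 && any(p$onset_s[-1] < off[-nrow(p)]))
    stopf("protocol steps overlap")
  set.seed(seed)
  fs <- sampling_rate
  total <- total_duration_s %||% (max(off) + 0.5)
  n <- round(total * fs)
  t <- (seq_len(n) - 1L) / fs
  current <- numeric(n)
  for (i in seq_len(nrow(p))) {
    w <- t >= p$onset_s[i] & t < off[i]
    current[w] <- p$current_nA[i]
  }
  # exact exponential update toward the instantaneous steady state
  v <- numeric(n)
  v[1] <- cell$vrest_mV
  alpha <- exp(-1 / (fs * cell$tau_ms / 1000))
  vinf <- cell$vrest_mV + current * cell$rin_Mohm
  for (k in 2:n) v[k] <- vinf[k] + (v[k - 1] - vinf[k]) * alpha

  thr_abs <- cell$vrest_mV + cell$ap_threshold_mV
  above <- v >= thr_abs
  spike_times <- numeric(0)
  if (any(above)) {
    runs <- logical_runs(above)
    isi <- 1 / cell$firing_rate_hz
    for (r in seq_len(nrow(runs))) {
      t0 <- t[runs[r, "start"]]
      t1 <- t[runs[r, "end"]]
      spike_times <- c(spike_times, seq(t0, t1, by = isi))
    }
  }
  if (length(spike_times)) {
    tpl_t <- seq(0, 0.006, by = 1 / fs)
    rise <- 0.0004
    pt <- cell$ap_peak_trough_ms / 1000
    tpl <- numeric(length(tpl_t))
    up <- tpl_t <= rise
    tpl[up] <- cell$ap_amp_mV * tpl_t[up] / rise
    fall <- tpl_t > rise & tpl_t <= rise + pt
    tpl[fall] <- cell$ap_amp_mV -
      (cell$ap_amp_mV + cell$fahp_mV) * (tpl_t[fall] - rise) / pt
    rec <- tpl_t > rise + pt
    tpl[rec] <- -cell$fahp_mV * pmax(0, 1 - (tpl_t[rec] - rise - pt) / 0.003)
    for (st in spike_times) {
      i0 <- round(st * fs) + 1L
      idx <- i0:min(n, i0 + length(tpl) - 1L)
      v[idx] <- v[idx] + tpl[seq_along(idx)]
    }
  }
  if (noise_sd_mV > 0) v <- v + stats::rnorm(n, sd = noise_sd_mV)
  structure(list(voltage_mV = v, sampling_rate = fs,
                 steps = data.frame(onset_s = p$onset_s,
                                    duration_ms = p$duration_ms,
                                    current_nA = p$current_nA),
                 spike_times = spike_times, cell = cell),
            class = "vm_trace")
}

# Fisher's approximation to the von Mises concentration giving resultant r.
kappa_from_r <- function(r) {
  if (r < 0) r <- 0
  if (r >= 0.999) r <- 0.999
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

# Best-Fisher rejection sampler for von Mises (degrees).
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa <= 1e-9) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r0 * z) / (r0 + z)
    cc <- kappa * (r0 - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap360(mu_deg + rad2deg(sign(u[3] - 0.5) * acos(f)))
      i <- i + 1L
    }
  }
  out
}

#' Default neuron-type truth table for evidence simulation
#'
#' Thirty-five hippocampal-formation neuron-type strata emulating the
#' structure of a literature compilation: per-type true theta phase
#' (CA1-SP peak reference) with circular spread, mean vector length,
#' SWR/DS ratios and firing rate, together with the reporting conditions
#' (LFP site, phase convention, behavioral state, recording method,
#' species). The CA1 pyramidal urethane stratum carries n = 19 cells with
#' true phase 206 degrees (circular SD 30) and resting potential
#' -61.6 +/- 5.6 mV; the three CA1 PV-marked interneuron types total 28
#' cells with both theta-phase and SWR-ratio records. This is a synthetic
#' stand-in whose summary structure mirrors a curated corpus; it contains
#' no measured literature values beyond those summary parameters.
#'
#' @return data.frame, one row per (type, state) stratum.
#' @export
default_type_truth <- function() {
  row <- function(id, name, region, marker, state, method, species, n,
                  site, conv, theta, sd, mvl, swr, ds, rate, vrest = NA) {
    data.frame(type_id = id, type_name = name, region = region,
               marker = marker, state = state, method = method,
               species = species, n_cells = n, lfp_site = site,
               phase_convention = conv, theta_deg = theta, theta_sd_deg = sd,
               mvl = mvl, swr_ratio = swr, ds_ratio = ds,
               firing_rate_hz = rate, vrest_mV = vrest,
               stringsAsFactors = FALSE)
  }
  an <- "anesthesia"; fm <- "awake-freely-moving"; hf <- "awake-head-fixed"
  jx <- "juxtacellular"; sh <- "sharp"; sp <- "silicon-probe"; ot <- "optotag"
  rbind(
    row("1000", "DG Granule", "DG", "Prox1", an, sh, "rat", 3, "DG-GC", "trough0", 116, 39, 0.25, 2.0, 11.7, 0.8),
    row("1002", "DG Mossy", "DG", "PCP4", an, sh, "rat", 1, "hilus", "peak0", 339, 20, 0.33, 0.1, 0.1, 2.1),
    row("1010", "DG Basket", "DG", "PV", an, jx, "rat", 4, "DG-GC", "peak0", 180, 35, 0.30, 2.5, 4.0, 9.0),
    row("1020", "DG HIPP", "DG", "SOM", an, jx, "rat", 3, "DG-GC", "trough0", 230, 40, 0.22, 0.6, 0.5, 3.0),
    row("1030", "DG MOPP", "DG", "NPY", an, jx, "rat", 2, "DG-GC", "peak0", 150, 45, 0.18, 0.8, 1.2, 2.0),
    row("2000", "CA3 Pyramidal", "CA3", "none", an, sh, "rat", 7, "CA3b", "peak0", 181, 63, 0.31, 1.1, 0.7, 1.5),
    row("2004", "CA3c Pyramidal", "CA3", "none", an, sh, "rat", 4, "CA3c", "peak0", 168, 31, 0.28, 1.7, 0.7, 1.8),
    row("2010", "CA3 Basket CCK+", "CA3", "CCK", fm, jx, "rat", 2, "CA3b", "peak0", 155, 40, 0.25, 1.4, NA, 8.0),
    row("2020", "CA3 Basket", "CA3", "PV", an, jx, "rat", 3, "CA3b", "peak0", 100, 30, 0.35, 3.5, NA, 12.0),
    row("2030", "CA3 O-LM", "CA3", "SOM", an, jx, "rat", 2, "CA3b", "trough0", 200, 35, 0.28, 0.5, NA, 4.0),
    row("2040", "CA3 Bistratified", "CA3", "PV", an, jx, "rat", 2, "CA3b", "peak0", 120, 30, 0.32, 2.8, NA, 10.0),
    row("3000", "CA2 Pyramidal", "CA2", "PCP4", an, sh, "rat", 5, "CA2", "peak0", 184, 79, 0.34, 0.5, 2.2, 1.2),
    row("3010", "CA2 Basket", "CA2", "PV", an, jx, "rat", 2, "CA2", "peak0", 95, 25, 0.30, 3.0, NA, 11.0),
    row("4000", "CA1 Pyramidal", "CA1", "none", an, sh, "rat", 19, "CA1-SP", "peak0", 206, 30, 0.39, 2.7, 0.9, 1.4, -61.6),
    row("4000", "CA1 Pyramidal", "CA1", "none", hf, sh, "mouse", 6, "CA1-SP", "peak0", 45, 68, 0.23, 2.5, NA, 1.6),
    row("4099", "CA1 Pyramidal deep", "CA1", "CB-", an, sh, "rat", 8, "CA1-SP", "peak0", 222, 22, 0.40, 0.6, 0.5, 1.3, -58.8),
    row("4098", "CA1 Pyramidal superficial", "CA1", "CB+", an, sh, "rat", 11, "CA1-SP", "peak0", 195, 32, 0.39, 4.2, 1.2, 1.5, -63.6),
    row("4078", "CA1 PV Basket", "CA1", "PV", fm, jx, "rat", 12, "CA1-SP", "peak0", 270, 25, 0.19, 4.3, 0.4, 21.0, -49.1),
    row("4079", "CA1 Axo-axonic", "CA1", "PV", fm, jx, "rat", 9, "CA1-SP", "peak0", 10, 25, 0.25, 0.4, NA, 17.0),
    row("4080", "CA1 Bistratified", "CA1", "PV", fm, jx, "rat", 7, "CA1-SP", "peak0", 180, 25, 0.30, 3.0, NA, 14.0),
    row("4050", "CA1 O-LM", "CA1", "SOM", an, jx, "rat", 4, "CA1-SP", "trough0", 195, 30, 0.35, 0.4, NA, 6.0),
    row("4060", "CA1 Basket CCK+", "CA1", "CCK", an, jx, "rat", 3, "CA1-SP", "peak0", 155, 35, 0.22, 1.2, NA, 7.0),
    row("4061", "CA1 Ivy", "CA1", "nNOS", fm, jx, "rat", 3, "CA1-SP", "peak0", 220, 40, 0.15, 1.1, NA, 2.5),
    row("4062", "CA1 Neurogliaform", "CA1", "RLN", an, jx, "rat", 2, "CA1-SLM", "peak0", 240, 40, 0.20, 0.9, NA, 3.0),
    row("4063", "CA1 Radiatum giant", "CA1", "none", an, sh, "rat", 1, "CA1-SR", "peak0", 200, 30, 0.25, 1.5, NA, 2.0),
    row("4064", "CA1 SCA", "CA1", "CB1", an, jx, "rat", 2, "CA1-SR", "trough0", 170, 35, 0.24, 0.8, NA, 5.0),
    row("4065", "CA1 Trilaminar", "CA1", "Mus2R", fm, jx, "rat", 1, "CA1-SP", "peak0", 130, 30, 0.28, 2.2, NA, 9.0),
    row("5000", "Sub Pyramidal", "Sub", "none", fm, sp, "rat", 6, "CA1-SP", "peak0", 210, 45, 0.20, 1.8, NA, 3.5),
    row("6000", "MEC LII Stellate", "EC", "RLN", hf, jx, "mouse", 8, "EC2", "peak0", 340, 35, 0.25, 1.2, NA, 2.8),
    row("6010", "MEC LII Pyramidal", "EC", "CB+", hf, jx, "mouse", 5, "EC2", "peak0", 320, 40, 0.22, 1.0, NA, 2.2),
    row("6020", "MEC LIII Pyramidal", "EC", "none", an, jx, "rat", 4, "EC3", "peak0", 160, 45, 0.20, 0.8, NA, 3.0),
    row("6030", "EC LI Interneuron", "EC", "none", an, jx, "rat", 2, "EC1", "peak0", 140, 40, 0.18, 0.9, NA, 6.0),
    row("6040", "MEC LV Pyramidal", "EC", "none", an, jx, "rat", 3, "EC5", "peak0", 180, 50, 0.15, 1.1, NA, 4.0),
    row("6050", "MEC PV Basket", "EC", "PV", hf, ot, "mouse", 4, "EC2", "peak0", 60, 30, 0.30, 2.0, NA, 15.0),
    row("7000", "Sub PV Basket", "Sub", "PV", hf, ot, "mouse", 5, "CA1-SP", "peak0", 265, 25, 0.21, 4.0, NA, 19.0),
    row("8000", "DG Semilunar", "DG", "none", an, sh, "rat", 2, "DG-GC", "peak0", 130, 40, 0.20, 1.3, 5.0, 0.9)
  )
}

#' Generate a literature-style evidence table
#'
#' Draws per-cell values from the per-type truth and re-expresses theta
#' phases in each stratum's reporting site and peak/trough convention, so
#' that normalization back to the CA1-SP peak reference recovers the truth
#' exactly (the reported phase is the truth minus the site offset, minus
#' 180 degrees under the trough convention). Non-phase variables are
#' emitted unchanged by site or convention.
#'
#' @param type_truth data.frame as returned by [default_type_truth()].
#' @param seed integer seed.
#' @param offsets layer-offset table, as from [default_layer_offsets()].
#' @return data.frame of evidence records with columns `neuron_type`,
#'   `type_name`, `region`, `marker`, `variable`, `value`, `dispersion`,
#'   `n`, `lfp_site`, `phase_convention`, `state`, `method`, `species`,
#'   `sex`, `age`, `citation_key`, plus attribute `truth` holding the
#'   per-record true (CA1-SP peak0) values.
#' @export
generate_evidence_table <- function(type_truth = default_type_truth(),
                                    seed = 1,
                                    offsets = default_layer_offsets()) {
  set.seed(seed)
  bad <- setdiff(unique(type_truth$lfp_site), names(offsets))
  if (length(bad)) stopf("unknown site label(s): %s", paste(bad, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(type_truth))) {
    s <- type_truth[i, ]
    n <- s$n_cells
    kap <- kappa_from_r(exp(-(deg2rad(s$theta_sd_deg))^2 / 2))
    true_phase <- rvonmises_deg(n, s$theta_deg, kap)
    flip <- if (s$phase_convention == "trough0") 180 else 0
    reported <- wrap360(true_phase - offsets[[s$lfp_site]] - flip)
    mk <- function(variable, value, true_value) {
      data.frame(neuron_type = s$type_id, type_name = s$type_name,
                 region = s$region, marker = s$marker, variable = variable,
                 value = value, dispersion = NA_real_, n = 1L,
                 lfp_site = s$lfp_site, phase_convention = s$phase_convention,
                 state = s$state, method = s$method, species = s$species,
                 sex = sample(c("male", "female"), length(value), TRUE,
                              prob = c(0.8, 0.2)),
                 age = "adult",
                 citation_key = sprintf("%s_%s_%02d", s$type_id, s$state,
                                        seq_along(value)),
                 true_value = true_value, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- mk("theta_phase", reported, true_phase)
    rows[[length(rows) + 1L]] <-
      mk("firing_rate", pmax(0.05, stats::rnorm(n, s$firing_rate_hz,
                                                0.3 * s$firing_rate_hz)),
         rep(s$firing_rate_hz, n))
    if (!is.na(s$mvl))
      rows[[length(rows) + 1L]] <-
        mk("theta_mvl", pmin(1, pmax(0, stats::rnorm(n, s$mvl, 0.05))),
           rep(s$mvl, n))
    if (!is.na(s$swr_ratio))
      rows[[length(rows) + 1L]] <-
        mk("swr_ratio", pmax(0, stats::rnorm(n, s$swr_ratio,
                                             0.3 * max(s$swr_ratio, 0.2))),
           rep(s$swr_ratio, n))
    if (!is.na(s$ds_ratio))
      rows[[length(rows) + 1L]] <-
        mk("ds_ratio", pmax(0, stats::rnorm(n, s$ds_ratio,
                                            0.3 * max(s$ds_ratio, 0.2))),
           rep(s$ds_ratio, n))
  }
  ev <- do.call(rbind, rows)
  truth <- ev$true_value
  ev$true_value <- NULL
  rownames(ev) <- NULL
  attr(ev, "truth") <- truth
  ev
}
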