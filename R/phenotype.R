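#' @title Per-cell oscillatory and intrinsic phenotypes
#' @description Spike-phase extraction, circular mean and mean vector
#'   length, event-modulation (SWR/DS) ratios, bursting index,
#'   autocorrelogram, and membrane biophysics from current-step traces.
#'   Results that cannot be computed reliably carry an explicit
#'   `undefined` flag and reason rather than being dropped.
#' @name phenotype
NULL

undefined_result <- function(fields, reason) {
  out <- c(fields, list(undefined = TRUE, reason = reason))
  out
}

#' Theta phase of each spike
#'
#' Interpolates the instantaneous (unwrapped) theta phase at each spike
#' time; spikes outside detected theta epochs are excluded and counted in
#' the `n_excluded` attribute.
#'
#' @param times spike times, s.
#' @param phases a `phase_series` from [segment_theta_cycles()].
#' @return numeric vector of phases in `[0, 360)`, with attribute
#'   `n_excluded`; zero-length (with attribute `flag = "no_overlap"`) when
#'   no spike falls inside a theta epoch.
#' @export
spike_phases <- function(times, phases) {
  stopifnot(inherits(phases, "phase_series"))
  fs <- phases$sampling_rate
  idx <- round(times * fs) + 1L
  ok <- idx >= 1L & idx <= length(phases$valid)
  ok[ok] <- phases$valid[idx[ok]]
  ph <- rep(NA_real_, length(times))
  if (any(ok)) {
    vt <- which(phases$valid)
    ph[ok] <- stats::approx(phases$time_s[vt], phases$unwrapped_deg[vt],
                            xout = times[ok])$y
  }
  out <- wrap360(ph[ok & !is.na(ph)])
  attr(out, "n_excluded") <- length(times) - length(out)
  if (!length(out)) attr(out, "flag") <- "no_overlap"
  out
}

#' Circular mean and mean vector length
#'
#' mu is the angle of the resultant of unit vectors at each phase, mapped
#' to `[0, 360)`; r is the resultant length (0 = no phase locking,
#' 1 = perfect locking). With fewer than `min_n` phases, or with a
#' vanishing resultant (perfectly uniform phases), the result is flagged
#' undefined rather than raising an error.
#'
#' @param phase_deg phases in degrees.
#' @param min_n minimum number of phases for a defined result.
#' @return list with `mu_deg`, `r`, `n`, `undefined`, `reason`.
#' @export
circular_mean_mvl <- function(phase_deg, min_n = 20) {
  n <- length(phase_deg)
  if (n == 0)
    return(undefined_result(list(mu_deg = NA_real_, r = NA_real_, n = 0L),
                            "no phases"))
  rad <- deg2rad(phase_deg)
  c_bar <- mean(cos(rad)); s_bar <- mean(sin(rad))
  r <- sqrt(c_bar^2 + s_bar^2)
  mu <- wrap360(rad2deg(atan2(s_bar, c_bar)))
  if (n < min_n)
    return(undefined_result(list(mu_deg = mu, r = r, n = n),
                            sprintf("n = %d below minimum %d", n, min_n)))
  if (r < 1e-12)
    return(undefined_result(list(mu_deg = NA_real_, r = 0, n = n),
                            "uniform phase distribution (r = 0)"))
  list(mu_deg = mu, r = r, n = n, undefined = FALSE, reason = NA_character_)
}

#' Event-modulation ratio (SWR or DS)
#'
#' Firing rate inside +/- `peak_window_ms / 2` of each event peak divided
#' by the basal rate, computed on all time outside any event padded by
#' `baseline_pad_s` on each side. Ratio 0 means the unit is silent at
#' event peaks; results are flagged undefined with fewer than `min_events`
#' events or a zero basal rate.
#'
#' @param times spike times, s.
#' @param events data.frame of detected events (`onset_s`, `peak_s`,
#'   `offset_s`) of a single class.
#' @param span recording span `c(start, end)`, s.
#' @param peak_window_ms full width of the peak window, ms.
#' @param baseline_pad_s padding excluded around each event for the basal
#'   rate, s.
#' @param min_events minimum event count for a defined result.
#' @return list with `ratio`, `n_events`, `rate_peak`, `rate_basal`,
#'   `undefined`, `reason`.
#' @export
event_ratio <- function(times, events, span, peak_window_ms = 50,
                        baseline_pad_s = 0.1, min_events = 10) {
  n_ev <- nrow(events)
  half <- peak_window_ms / 2000
  if (n_ev == 0)
    return(undefined_result(list(ratio = NA_real_, n_events = 0L,
                                 rate_peak = NA_real_, rate_basal = NA_real_),
                            "no events"))
  win_lo <- events$peak_s - half
  win_hi <- events$peak_s + half
  in_win <- in_intervals(times, win_lo, win_hi)
  t_win <- n_ev * 2 * half
  excl_lo <- events$onset_s - baseline_pad_s
  excl_hi <- events$offset_s + baseline_pad_s
  in_excl <- in_intervals(times, excl_lo, excl_hi)
  t_excl <- sum(pmin(excl_hi, span[2]) - pmax(excl_lo, span[1]))
  t_basal <- diff(span) - t_excl
  rate_peak <- sum(in_win) / t_win
  rate_basal <- sum(!in_excl & times >= span[1] & times <= span[2]) / t_basal
  fields <- list(ratio = rate_peak / rate_basal, n_events = n_ev,
                 rate_peak = rate_peak, rate_basal = rate_basal)
  if (rate_basal == 0)
    return(undefined_result(`[[<-`(fields, "ratio", NA_real_),
                            "basal rate is zero"))
  if (n_ev < min_events)
    return(undefined_result(fields,
                            sprintf("%d events below minimum %d", n_ev, min_events)))
  c(fields, list(undefined = FALSE, reason = NA_character_))
}

#' Bursting index during theta
#'
#' Fraction of theta-epoch spikes that belong to complex-spike bursts:
#' maximal runs of at least 3 spikes whose consecutive inter-spike
#' intervals are all below 8 ms.
#'
#' @param times spike times, s.
#' @param theta_epochs data.frame with `onset_s`, `offset_s`.
#' @param max_isi_ms intra-burst inter-spike interval criterion, ms.
#' @param min_burst_spikes minimum spikes per burst.
#' @return list with `index`, `n_spikes`, `n_burst_spikes`, `undefined`,
#'   `reason`.
#' @export
bursting_index <- function(times, theta_epochs, max_isi_ms = 8,
                           min_burst_spikes = 3) {
  in_theta <- in_intervals(times, theta_epochs$onset_s,
                           theta_epochs$offset_s)
  ts <- sort(times[in_theta])
  if (!length(ts))
    return(undefined_result(list(index = NA_real_, n_spikes = 0L,
                                 n_burst_spikes = 0L),
                            "no spikes inside theta epochs"))
  short <- diff(ts) < max_isi_ms / 1000
  n_burst <- 0L
  if (any(short)) {
    r <- rle(short)
    # a run of k consecutive short ISIs spans k + 1 spikes
    run_spikes <- r$lengths + 1L
    n_burst <- sum(run_spikes[r$values & run_spikes >= min_burst_spikes])
  }
  list(index = n_burst / length(ts), n_spikes = length(ts),
       n_burst_spikes = n_burst, undefined = FALSE, reason = NA_character_)
}

#' Spike-train autocorrelogram
#'
#' Counts of spike-pair lags in bins of `bin_ms` over `+/- window_ms`,
#' excluding zero-lag self pairs; symmetric about lag zero by
#' construction.
#'
#' @param times spike times, s.
#' @param bin_ms bin width, ms.
#' @param window_ms half-width of the lag window, ms.
#' @return list with `lag_ms` (bin centers) and `counts`; empty when the
#'   train has fewer than 2 spikes.
#' @export
autocorrelogram <- function(times, bin_ms = 2.5, window_ms = 500) {
  ts <- sort(times)
  n_half <- ceiling(window_ms / bin_ms)
  centers_pos <- (seq_len(n_half) - 0.5) * bin_ms
  centers <- c(-rev(centers_pos), centers_pos)
  if (length(ts) < 2)
    return(list(lag_ms = centers, counts = integer(2L * n_half)))
  w <- n_half * bin_ms / 1000
  lags <- numeric(0)
  for (i in seq_along(ts)) {
    k <- i + 1L
    while (k <= length(ts) && ts[k] - ts[i] < w) {
      lags <- c(lags, ts[k] - ts[i])
      k <- k + 1L
    }
  }
  # bin positive lags on [0, window) and mirror, so the histogram is
  # symmetric by construction
  idx <- pmin(n_half, floor(1000 * lags / bin_ms) + 1L)
  counts_pos <- tabulate(idx, nbins = n_half)
  list(lag_ms = centers, counts = as.integer(c(rev(counts_pos), counts_pos)))
}

# Single-exponential fit to a step-onset segment; returns tau in ms.
fit_tau_ms <- function(t_ms, v, v0, vinf_guess) {
  dv <- vinf_guess - v0
  if (abs(dv) < 1e-9) return(NA_real_)
  st <- list(vinf = vinf_guess, tau = 20)
  fit <- try(minpack.lm::nlsLM(v ~ vinf + (v0 - vinf) * exp(-t_ms / tau),
                               start = st, data = data.frame(t_ms = t_ms, v = v),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NA_real_)
  unname(stats::coef(fit)[["tau"]])
}

#' Membrane biophysics from a current-step trace
#'
#' Resting potential and input resistance come from the linear regression
#' of per-step baseline (steady-state) potential on holding current
#' (intercept at I = 0 and slope, mV/nA = megaohm). The membrane time
#' constant is a single-exponential fit to the onset of a subthreshold
#' step. Action-potential metrics are taken from the first spike of the
#' first suprathreshold depolarizing step: threshold is the voltage
#' (relative to the pre-step baseline) at which dV/dt first exceeds
#' `dvdt_threshold` V/s, fAHP is the threshold-to-trough depth after the
#' spike, and peak-trough is the time from the AP peak to the following
#' trough.
#'
#' @param trace a `vm_trace` (see [generate_vm()]).
#' @param dvdt_threshold AP threshold slope criterion, V/s.
#' @return list with `vrest_mV`, `rin_Mohm`, `tau_ms`, `ap_threshold_mV`,
#'   `fahp_mV`, `ap_peak_trough_ms`, `ap_defined`, `reason`.
#' @export
membrane_biophysics <- function(trace, dvdt_threshold = 10) {
  stopifnot(inherits(trace, "vm_trace"))
  fs <- trace$sampling_rate
  v <- trace$voltage_mV
  steps <- trace$steps
  n_steps <- nrow(steps)
  idx_of <- function(s) pmin(length(v), pmax(1L, round(s * fs) + 1L))

  dvdt <- c(0, diff(v)) * fs / 1000  # V/s
  has_spike <- steady <- prestep <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    on <- steps$onset_s[i]; off <- on + steps$duration_ms[i] / 1000
    seg <- idx_of(on):idx_of(off)
    has_spike[i] <- any(dvdt[seg] > 5 * dvdt_threshold)
    tail_seg <- idx_of(off - min(0.1, steps$duration_ms[i] / 2000)):idx_of(off)
    steady[i] <- mean(v[tail_seg])
    pre <- idx_of(on - 0.05):idx_of(on - 1 / fs)
    prestep[i] <- mean(v[pre])
  }
  sub <- which(!has_spike)
  if (length(unique(steps$current_nA[sub])) < 2)
    stopf("need at least 2 distinct subthreshold holding currents for the Vrest/Rin regression")
  fit <- stats::lm(steady[sub] ~ steps$current_nA[sub])
  vrest <- unname(stats::coef(fit)[1])
  rin <- unname(stats::coef(fit)[2])

  tau <- NA_real_
  tau_steps <- sub[steps$current_nA[sub] != 0]
  if (length(tau_steps)) {
    i <- tau_steps[1]
    on <- steps$onset_s[i]
    seg <- idx_of(on):idx_of(on + min(0.2, steps$duration_ms[i] / 1000))
    t_ms <- (seg - seg[1]) / fs * 1000
    tau <- fit_tau_ms(t_ms, v[seg], prestep[i], steady[i])
  }

  ap <- list(ap_threshold_mV = NA_real_, fahp_mV = NA_real_,
             ap_peak_trough_ms = NA_real_, ap_defined = FALSE,
             reason = "no suprathreshold depolarizing step")
  supra <- which(has_spike & steps$current_nA > 0)
  if (length(supra)) {
    i <- supra[1]
    on <- steps$onset_s[i]; off <- on + steps$duration_ms[i] / 1000
    seg <- idx_of(on):idx_of(off)
    cross <- seg[which(dvdt[seg] >= dvdt_threshold)[1]]
    if (!is.na(cross)) {
      # voltage just before the slope criterion is met
      thr_v <- v[max(1L, cross - 1L)]
      # first spike only: peak within a few ms of the threshold crossing
      rest_of_step <- cross:min(idx_of(off), cross + round(0.005 * fs))
      pk <- rest_of_step[which.max(v[rest_of_step])]
      after_pk <- pk:min(idx_of(off), pk + round(0.01 * fs))
      tr <- after_pk[which.min(v[after_pk])]
      ap <- list(ap_threshold_mV = thr_v - prestep[i],
                 fahp_mV = thr_v - v[tr],
                 ap_peak_trough_ms = (tr - pk) / fs * 1000,
                 ap_defined = TRUE, reason = NA_character_)
    }
  }
  c(list(vrest_mV = vrest, rin_Mohm = rin, tau_ms = tau), ap)
}
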