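#' @title Theta, sharp-wave-ripple and dentate-spike detection
#' @description Zero-phase FIR filtering, theta epoch and cycle
#'   segmentation with a peak-anchored instantaneous phase (CA1-SP theta
#'   peak = 0 degrees), and SD-threshold detection of sharp-wave ripples
#'   (ripple-band envelope on the pyramidal-layer channel paired with a
#'   low-frequency sharp wave on the radiatum channel) and dentate spikes
#'   (hilar deflections).
#' @name lfp_events
NULL

# Windowed-sinc (Hamming) FIR kernel; order = n_cycles periods of the low
# cutoff, forced odd so the kernel is symmetric about an integer delay.
fir_kernel <- function(low, high, fs, n_cycles = 3) {
  cutoff_for_order <- if (is.na(low)) high else low
  ord <- round(n_cycles * fs / cutoff_for_order)
  if (ord %% 2L == 1L) ord <- ord + 1L  # fir1 order -> ord+1 taps, keep odd taps
  nyq <- fs / 2
  if (is.na(low)) signal::fir1(ord, high / nyq, type = "low")
  else signal::fir1(ord, c(low, high) / nyq, type = "pass")
}

# Forward-backward application of a FIR kernel (zero net phase shift) with
# edge-reflection padding.
apply_filtfilt <- function(x, h) {
  l <- length(h)
  xp <- reflect_pad(x, l)
  y <- conv_same(xp, h)
  y <- rev(conv_same(rev(y), h))
  y[(l + 1L):(l + length(x))]
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) FIR applied forward and backward, so the output
#' has zero net phase shift and unit passband gain.
#'
#' @param x numeric signal.
#' @param low,high passband edges, Hz; `low` may be `NA` for a low-pass.
#' @param sampling_rate samples/s.
#' @param n_cycles kernel length in periods of the low cutoff.
#' @return the filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, low, high, sampling_rate, n_cycles = 3) {
  if (!is.na(low) && (low <= 0 || low >= high))
    stopf("need 0 < low < high")
  if (high >= sampling_rate / 2)
    stopf("high cutoff %g Hz is not below the Nyquist frequency %g Hz",
          high, sampling_rate / 2)
  apply_filtfilt(x, fir_kernel(low, high, sampling_rate, n_cycles))
}

#' Detect theta epochs
#'
#' An epoch is a maximal interval in which the 4-12 Hz band dominates the
#' broadband (1-50 Hz) signal: the ratio of band power to broadband power,
#' both smoothed over a sliding window, exceeds `ratio_threshold`. Gaps
#' shorter than `merge_gap_s` are merged; epochs shorter than
#' `min_duration_s` are dropped.
#'
#' @param rec an [lfp_recording()].
#' @param channel layer label of the channel to analyze.
#' @param band theta band, Hz.
#' @param ratio_threshold band-power dominance threshold.
#' @param window_s smoothing window for the power estimates, s.
#' @param merge_gap_s gaps below this are merged, s.
#' @param min_duration_s minimum epoch length, s.
#' @return data.frame with columns `onset_s`, `offset_s`.
#' @export
detect_theta_epochs <- function(rec, channel = "CA1-SP", band = c(4, 12),
                                ratio_threshold = 0.4, window_s = 1,
                                merge_gap_s = 0.5, min_duration_s = 1) {
  x <- lfp_channel(rec, channel)
  fs <- rec$sampling_rate
  theta <- bandpass_filter(x, band[1], band[2], fs)
  broad <- bandpass_filter(x, 1, 50, fs)
  w <- round(window_s * fs)
  p_theta <- moving_average(theta^2, w)
  p_broad <- moving_average(broad^2, w)
  ratio <- p_theta / pmax(p_broad, .Machine$double.eps)
  mask <- ratio > ratio_threshold
  if (!any(mask)) return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  runs <- logical_runs(mask)
  on <- (runs[, "start"] - 1L) / fs
  off <- runs[, "end"] / fs
  # merge runs separated by short gaps
  if (length(on) > 1) {
    keep_on <- on[1]; merged_on <- c(); merged_off <- c()
    cur_off <- off[1]
    for (i in seq_along(on)[-1]) {
      if (on[i] - cur_off < merge_gap_s) {
        cur_off <- off[i]
      } else {
        merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, cur_off)
        keep_on <- on[i]; cur_off <- off[i]
      }
    }
    merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, cur_off)
    on <- merged_on; off <- merged_off
  }
  keep <- (off - on) >= min_duration_s
  data.frame(onset_s = on[keep], offset_s = off[keep])
}

#' Segment theta cycles and build the instantaneous phase series
#'
#' Within each theta epoch the 4-12 Hz filtered signal is segmented
#' peak-to-peak. The instantaneous phase is anchored to the waveform:
#' 0 degrees at each detected peak, 180 at the intervening trough, 360 at
#' the next peak, with piecewise-linear interpolation between anchors, so
#' the CA1-SP theta peak is at exactly 0 degrees by construction.
#'
#' @param rec an [lfp_recording()] (or a numeric vector already filtered).
#' @param epochs data.frame from [detect_theta_epochs()].
#' @param channel layer label used when `rec` is a recording.
#' @param band theta band, Hz.
#' @return list with `events` (data.frame of theta_cycle rows: onset at
#'   the starting peak, peak at the trough, offset at the ending peak) and
#'   `phases` (class `phase_series`: per-sample wrapped and unwrapped
#'   phase with a validity mask).
#' @export
segment_theta_cycles <- function(rec, epochs, channel = "CA1-SP",
                                 band = c(4, 12)) {
  if (inherits(rec, "lfp_recording")) {
    fs <- rec$sampling_rate
    theta <- bandpass_filter(lfp_channel(rec, channel), band[1], band[2], fs)
  } else stopf("rec must be an lfp_recording")
  n <- length(theta)
  d <- diff(theta)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  troughs <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  t_of <- function(i) (i - 1L) / fs

  unwrapped <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  events <- list()
  for (e in seq_len(nrow(epochs))) {
    lo <- epochs$onset_s[e] * fs + 1
    hi <- epochs$offset_s[e] * fs
    pk <- peaks[peaks >= lo & peaks <= hi]
    if (length(pk) < 2) {
      message(sprintf("segment_theta_cycles: epoch %d shorter than one cycle, skipped", e))
      next
    }
    anchors <- numeric(0); values <- numeric(0)
    for (ci in seq_len(length(pk) - 1L)) {
      tr <- troughs[troughs > pk[ci] & troughs < pk[ci + 1L]]
      if (!length(tr)) next
      tr <- tr[which.min(theta[tr])]
      base <- 360 * (ci - 1L)
      anchors <- c(anchors, pk[ci], tr)
      values <- c(values, base, base + 180)
      events[[length(events) + 1L]] <-
        data.frame(class = "theta_cycle", onset_s = t_of(pk[ci]),
                   peak_s = t_of(tr), offset_s = t_of(pk[ci + 1L]),
                   peak_amplitude = NA_real_)
    }
    if (length(anchors) < 2) next
    anchors <- c(anchors, pk[length(pk)])
    values <- c(values, 360 * (length(pk) - 1L))
    seg <- seq.int(pk[1], pk[length(pk)])
    unwrapped[seg] <- stats::approx(anchors, values, xout = seg)$y
    valid[seg] <- TRUE
  }
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(class = character(0), onset_s = numeric(0),
                  peak_s = numeric(0), offset_s = numeric(0),
                  peak_amplitude = numeric(0))
  phases <- structure(list(time_s = (seq_len(n) - 1L) / fs,
                           phase_deg = wrap360(unwrapped),
                           unwrapped_deg = unwrapped,
                           valid = valid, sampling_rate = fs),
                      class = "phase_series")
  list(events = events, phases = phases)
}

# SD-threshold event detection on a detection trace: candidates where the
# trace exceeds mean + threshold_sd * SD, boundaries expanded to the
# boundary_sd crossing, nearby candidates merged, short ones dropped.
threshold_events <- function(det, fs, threshold_sd, boundary_sd = 1,
                             min_duration_s = 0.02, merge_gap_s = 0.03) {
  mu <- mean(det); s <- stats::sd(det)
  if (s == 0) stopf("degenerate input: detection trace has zero SD")
  z <- (det - mu) / s
  core <- z > threshold_sd
  if (!any(core)) return(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                                    offset_s = numeric(0),
                                    peak_amplitude = numeric(0)))
  lowmask <- z > boundary_sd
  runs <- logical_runs(core)
  low_runs <- logical_runs(lowmask)
  # map each core run to its containing boundary run
  li <- findInterval(runs[, "start"], low_runs[, "start"])
  on <- low_runs[li, "start"]; off <- low_runs[li, "end"]
  ev <- unique(data.frame(start = on, end = off))
  # merge events closer than merge_gap_s
  if (nrow(ev) > 1) {
    merged <- ev[1, ]
    for (i in 2:nrow(ev)) {
      if ((ev$start[i] - merged$end[nrow(merged)]) / fs < merge_gap_s)
        merged$end[nrow(merged)] <- ev$end[i]
      else merged <- rbind(merged, ev[i, ])
    }
    ev <- merged
  }
  keep <- (ev$end - ev$start + 1L) / fs >= min_duration_s
  ev <- ev[keep, , drop = FALSE]
  if (!nrow(ev)) return(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                                   offset_s = numeric(0),
                                   peak_amplitude = numeric(0)))
  pk_idx <- mapply(function(a, b) a - 1L + which.max(z[a:b]), ev$start, ev$end)
  data.frame(onset_s = (ev$start - 1L) / fs, peak_s = (pk_idx - 1L) / fs,
             offset_s = (ev$end - 1L) / fs, peak_amplitude = z[pk_idx])
}

#' Detect sharp-wave ripples
#'
#' Candidate ripples are intervals where the smoothed (10 ms) magnitude of
#' the analytic signal of the 100-600 Hz band on the pyramidal-layer
#' channel exceeds `threshold_sd` standard deviations above its mean, with
#' boundaries at the 1 SD crossings. Candidate sharp waves are detected
#' analogously on the absolute deviation of the <100 Hz low-passed
#' radiatum channel. An SWR is emitted only when a ripple peak and a
#' sharp-wave peak coincide within `pairing_window_s`; the event peak is
#' the ripple-envelope maximum and `peak_amplitude` is its z-score.
#'
#' @param rec an [lfp_recording()].
#' @param sp_channel pyramidal-layer channel label.
#' @param sr_channel radiatum channel label.
#' @param threshold_sd detection threshold in SD units (2-5).
#' @param ripple_band ripple band, Hz.
#' @param pairing_window_s maximum ripple / sharp-wave peak separation, s.
#' @param min_duration_s,merge_gap_s candidate duration and merge rules.
#' @return data.frame of events with `class = "swr"`.
#' @export
detect_swr <- function(rec, sp_channel = "CA1-SP", sr_channel = "CA1-SR",
                       threshold_sd = 3, ripple_band = c(100, 600),
                       pairing_window_s = 0.05, min_duration_s = 0.02,
                       merge_gap_s = 0.03) {
  if (threshold_sd < 2 || threshold_sd > 5)
    stopf("threshold_sd must be in [2, 5]")
  fs <- rec$sampling_rate
  hi <- min(ripple_band[2], fs / 2 * 0.96)
  ripple <- bandpass_filter(lfp_channel(rec, sp_channel), ripple_band[1], hi, fs)
  env <- moving_average(Mod(analytic_signal(ripple)), round(0.010 * fs))
  ripples <- threshold_events(env, fs, threshold_sd,
                              min_duration_s = min_duration_s,
                              merge_gap_s = merge_gap_s)
  sw_raw <- bandpass_filter(lfp_channel(rec, sr_channel), NA, 100, fs)
  sw_det <- abs(sw_raw - mean(sw_raw))
  sharp_waves <- threshold_events(sw_det, fs, threshold_sd,
                                  min_duration_s = 0.01,
                                  merge_gap_s = merge_gap_s)
  if (!nrow(ripples) || !nrow(sharp_waves))
    return(data.frame(class = character(0), onset_s = numeric(0),
                      peak_s = numeric(0), offset_s = numeric(0),
                      peak_amplitude = numeric(0)))
  paired <- vapply(ripples$peak_s, function(p)
    any(abs(sharp_waves$peak_s - p) <= pairing_window_s), logical(1))
  out <- ripples[paired, , drop = FALSE]
  if (!nrow(out))
    return(data.frame(class = character(0), onset_s = numeric(0),
                      peak_s = numeric(0), offset_s = numeric(0),
                      peak_amplitude = numeric(0)))
  cbind(class = "swr", out)
}

#' Detect dentate spikes
#'
#' Single-channel deflection detector on the hilar channel, identical to
#' the sharp-wave branch of [detect_swr()] (absolute deviation of the
#' <100 Hz low-passed trace, SD thresholding) but without the pairing
#' requirement.
#'
#' @param rec an [lfp_recording()].
#' @param hilus_channel hilar channel label.
#' @param threshold_sd detection threshold in SD units.
#' @param min_duration_s,merge_gap_s candidate duration and merge rules.
#' @return data.frame of events with `class = "ds"`, sorted and
#'   non-overlapping.
#' @export
detect_ds <- function(rec, hilus_channel = "hilus", threshold_sd = 3,
                      min_duration_s = 0.005, merge_gap_s = 0.03) {
  fs <- rec$sampling_rate
  x <- lfp_channel(rec, hilus_channel)
  if (stats::sd(x) == 0) stopf("degenerate input: channel has zero SD")
  det <- bandpass_filter(x, NA, 100, fs)
  ev <- threshold_events(abs(det - mean(det)), fs, threshold_sd,
                         min_duration_s = min_duration_s,
                         merge_gap_s = merge_gap_s)
  if (!nrow(ev))
    return(data.frame(class = character(0), onset_s = numeric(0),
                      peak_s = numeric(0), offset_s = numeric(0),
                      peak_amplitude = numeric(0)))
  cbind(class = "ds", ev)
}
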