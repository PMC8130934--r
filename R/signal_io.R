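#' @title File formats for LFP, spike and event data
#' @description Flat-binary multichannel LFP with a JSON sidecar, and CSV
#'   schemas for spike trains and detected events. All readers are total on
#'   the corresponding writers' outputs.
#' @name signal_io
NULL

FORMAT_VERSION <- "1.0"

#' Controlled vocabulary of layer labels
#'
#' Channel labels accepted for layer-tagged LFP recordings: dentate gyrus
#' molecular and granule-cell layers, hilus, CA3 subregions, CA2, CA1 strata,
#' and entorhinal cortex layers I-VI.
#'
#' @return character vector of valid layer labels.
#' @export
layer_labels <- function() {
  c("DG-ML", "DG-GC", "hilus", "CA3a", "CA3b", "CA3c", "CA2",
    "CA1-SO", "CA1-SP", "CA1-SR", "CA1-SLM", paste0("EC", 1:6))
}

#' Construct a layer-labeled multichannel LFP recording
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param sampling_rate samples per second (> 0).
#' @param channel_layers character vector of layer labels, one per channel,
#'   drawn from [layer_labels()].
#' @return an object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, sampling_rate, channel_layers) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  if (length(channel_layers) != nrow(samples))
    stopf("channel_layers has %d labels for %d channels",
          length(channel_layers), nrow(samples))
  bad <- setdiff(channel_layers, layer_labels())
  if (length(bad))
    stopf("unknown layer label(s): %s (valid: %s)",
          paste(bad, collapse = ", "), paste(layer_labels(), collapse = ", "))
  if (anyDuplicated(channel_layers))
    stopf("conflicting channel map: duplicated layer label(s): %s",
          paste(unique(channel_layers[duplicated(channel_layers)]), collapse = ", "))
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be > 0")
  rownames(samples) <- channel_layers
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_layers = channel_layers),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  cat("  layers:", paste(x$channel_layers, collapse = ", "), "\n")
  invisible(x)
}

# Pull one channel by layer label, with a clear error.
lfp_channel <- function(rec, layer) {
  stopifnot(inherits(rec, "lfp_recording"))
  i <- match(layer, rec$channel_layers)
  if (is.na(i))
    stopf("channel '%s' absent (available: %s)", layer,
          paste(rec$channel_layers, collapse = ", "))
  rec$samples[i, ]
}

#' Write / read flat-binary LFP with JSON sidecar
#'
#' Samples are quantized to little-endian 16-bit integers at the declared
#' gain and stored sample-major (one frame of all channels per time point).
#' The sidecar records the sampling rate, channel count, layer labels and
#' gain; a round trip is lossless up to gain quantization.
#'
#' @param rec an [lfp_recording()].
#' @param data_path path for the binary samples.
#' @param sidecar_path path for the JSON sidecar.
#' @param gain_uV_per_bit microvolts per integer step.
#' @return `write_lfp` returns the paths invisibly; `read_lfp` returns an
#'   [lfp_recording()].
#' @export
write_lfp <- function(rec, data_path, sidecar_path, gain_uV_per_bit = 0.195) {
  stopifnot(inherits(rec, "lfp_recording"))
  q <- round(rec$samples / gain_uV_per_bit)
  if (any(abs(q) > 32767))
    stopf("samples exceed int16 range at gain %g uV/bit", gain_uV_per_bit)
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  sidecar <- list(format_version = FORMAT_VERSION,
                  sampling_rate = rec$sampling_rate,
                  n_channels = nrow(rec$samples),
                  n_samples = ncol(rec$samples),
                  channel_layers = rec$channel_layers,
                  gain_uV_per_bit = gain_uV_per_bit)
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_path, sidecar = sidecar_path))
}

#' @rdname write_lfp
#' @export
read_lfp <- function(data_path, sidecar_path) {
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("sampling_rate", "n_channels", "channel_layers", "gain_uV_per_bit"))
    if (is.null(sidecar[[key]]))
      stopf("sidecar %s is missing required key '%s'", sidecar_path, key)
  n_bytes <- file.size(data_path)
  n_values <- n_bytes / 2
  if (n_values %% sidecar$n_channels != 0)
    stopf("sample count %d not divisible by n_channels %d",
          n_values, sidecar$n_channels)
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, integer(), n = n_values, size = 2L,
                      signed = TRUE, endian = "little")
  samples <- matrix(raw_vals * sidecar$gain_uV_per_bit,
                    nrow = sidecar$n_channels)
  lfp_recording(samples, sidecar$sampling_rate, sidecar$channel_layers)
}

#' Write / read spike-time tables
#'
#' CSV schema: `unit_id,time_s` plus optional metadata columns
#' (`state`, `method`, `species`, `sex`, `age`). Times are seconds printed
#' with microsecond resolution. On read, trains are sorted per unit and
#' exact duplicate (unit, time) rows are dropped with a message.
#'
#' @param spikes data.frame with columns `unit_id` and `time_s`.
#' @param path CSV path.
#' @return data.frame of spikes, sorted by unit then time.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(all(c("unit_id", "time_s") %in% names(spikes)))
  out <- spikes[order(spikes$unit_id, spikes$time_s), , drop = FALSE]
  out$time_s <- sprintf("%.6f", out$time_s)
  out <- cbind(format_version = FORMAT_VERSION, out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stopf("spike CSV %s must have columns unit_id, time_s", path)
  df$format_version <- NULL
  if (nrow(df) == 0) return(df)
  df$time_s <- as.numeric(df$time_s)
  bad <- which(!is.finite(df$time_s))
  if (length(bad))
    stopf("unparseable time_s in rows: %s", paste(utils::head(bad, 5), collapse = ", "))
  if (any(df$time_s < 0))
    stopf("negative spike times in rows: %s",
          paste(utils::head(which(df$time_s < 0), 5), collapse = ", "))
  df <- df[order(df$unit_id, df$time_s), , drop = FALSE]
  dup <- duplicated(df[, c("unit_id", "time_s")])
  if (any(dup)) {
    message(sprintf("read_spikes: dropped %d duplicate (unit, time) rows", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write / read detected-event tables
#'
#' CSV schema: `class,onset_s,peak_s,offset_s,peak_amplitude` with
#' `class` in {theta_cycle, swr, ds}. Ordering `onset <= peak <= offset` is
#' enforced on read; events are sorted by peak time on write.
#'
#' @param events data.frame with columns `class`, `onset_s`, `peak_s`,
#'   `offset_s` and optionally `peak_amplitude`.
#' @param path CSV path.
#' @return data.frame of events.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("class", "onset_s", "peak_s", "offset_s") %in% names(events)))
  out <- events[order(events$peak_s), , drop = FALSE]
  for (col in c("onset_s", "peak_s", "offset_s"))
    out[[col]] <- sprintf("%.6f", out[[col]])
  out <- cbind(format_version = FORMAT_VERSION, out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "onset_s", "peak_s", "offset_s")
  if (!all(need %in% names(df)))
    stopf("event CSV %s must have columns %s", path, paste(need, collapse = ", "))
  df$format_version <- NULL
  for (col in c("onset_s", "peak_s", "offset_s")) df[[col]] <- as.numeric(df[[col]])
  bad_class <- setdiff(unique(df$class), c("theta_cycle", "swr", "ds"))
  if (length(bad_class))
    stopf("unknown event class(es): %s", paste(bad_class, collapse = ", "))
  viol <- which(df$onset_s > df$peak_s | df$peak_s > df$offset_s)
  if (length(viol))
    stopf("onset <= peak <= offset violated in row(s): %s",
          paste(utils::head(viol, 5), collapse = ", "))
  df <- df[order(df$peak_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}
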