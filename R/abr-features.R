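# From raw epoch sets to analyzable ABR features: artifact rejection,
# zero-phase bandpass filtering + averaging, windowed peak picking, and the
# derived wave I/V composites.

#' Reject high-amplitude artifact sweeps
#'
#' Marks as rejected every sweep whose maximum absolute value exceeds the
#' threshold (default 23.8 uV). The data are untouched; only `accepted_mask`
#' changes, so the operation is idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in uV (> 0).
#' @return the `epoch_set` with an updated `accepted_mask`.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 23.8) {
  if (!inherits(epochs, "epoch_set")) stop_input("epochs must be an 'epoch_set'")
  if (nrow(epochs$data) == 0) stop_input("empty epoch set")
  if (threshold_uv <= 0) stop_param("threshold_uv must be positive")
  peak <- apply(abs(epochs$data), 1, max)
  epochs$accepted_mask <- peak <= threshold_uv
  epochs
}

# zero-phase 4th-order Butterworth band-pass, implemented as cascaded
# high-pass and low-pass sections run forward-backward; the short epoch is
# zero-padded by its own length on each side to damp filtfilt edge transients
bandpass_zero_phase <- function(x, sampling_rate, band) {
  ny <- sampling_rate / 2
  if (band[1] <= 0 || band[2] >= ny || band[1] >= band[2])
    stop_param("filter band must satisfy 0 < low < high < Nyquist (",
               ny, " Hz)")
  n <- length(x)
  padded <- c(rep(0, n), x, rep(0, n))
  bh <- signal::butter(4, band[1] / ny, type = "high")
  bl <- signal::butter(4, band[2] / ny, type = "low")
  y <- signal::filtfilt(bl, signal::filtfilt(bh, padded))
  y[(n + 1):(2 * n)]
}

#' Average accepted sweeps and bandpass filter
#'
#' Computes the mean of the accepted sweeps and applies a zero-phase
#' 4th-order Butterworth bandpass (default 100-3000 Hz). Zero-phase filtering
#' leaves peak latencies unchanged. A warning (not an error) is emitted when
#' fewer than `min_sweeps` sweeps are accepted, so small test fixtures run.
#'
#' @param epochs an `epoch_set` (typically after [reject_artifacts()]).
#' @param band numeric length-2, filter corner frequencies in Hz.
#' @param min_sweeps advisory minimum accepted-sweep count.
#' @return object of class `abr_waveform`: `samples` (uV), `times` (ms),
#'   `sampling_rate`, `n_sweeps_accepted`, `filter_band`.
#' @export
average_and_filter <- function(epochs, band = c(100, 3000), min_sweeps = 2000) {
  if (!inherits(epochs, "epoch_set")) stop_input("epochs must be an 'epoch_set'")
  acc <- which(epochs$accepted_mask)
  if (length(acc) == 0) stop_input("no accepted sweeps to average")
  if (length(acc) < min_sweeps)
    warning(sprintf("only %d accepted sweeps (< %d)", length(acc), min_sweeps))
  avg <- colMeans(epochs$data[acc, , drop = FALSE])
  filt <- bandpass_zero_phase(avg, epochs$sampling_rate, band)
  structure(list(samples = filt, times = epochs$times,
                 sampling_rate = epochs$sampling_rate,
                 n_sweeps_accepted = length(acc),
                 filter_band = band),
            class = "abr_waveform")
}

#' Construct an ABR waveform directly from samples
#'
#' Wraps an already-averaged time series (uV, stimulus onset at the first
#' sample) as an `abr_waveform` without filtering, e.g. for externally
#' processed data or closed-form test signals.
#'
#' @param samples numeric vector, uV.
#' @param sampling_rate Hz.
#' @param n_sweeps_accepted count recorded in the object.
#' @param filter_band band recorded in the object.
#' @return an `abr_waveform`.
#' @export
abr_waveform <- function(samples, sampling_rate,
                         n_sweeps_accepted = 1L,
                         filter_band = c(100, 3000)) {
  if (sampling_rate <= 0) stop_param("sampling_rate must be positive")
  structure(list(samples = as.numeric(samples),
                 times = (seq_along(samples) - 1) / sampling_rate * 1000,
                 sampling_rate = sampling_rate,
                 n_sweeps_accepted = as.integer(n_sweeps_accepted),
                 filter_band = filter_band),
            class = "abr_waveform")
}

#' Pick a wave peak in a latency window
#'
#' Latency is the time of the maximum within the window; amplitude is the
#' peak value minus the following trough, where the trough is the first local
#' minimum after the peak searched up to `trough_horizon` ms past it, falling
#' back to the minimum over that span when no local minimum exists. QC flags:
#' `"clean"`, `"no-peak"` (flat window), `"boundary-peak"` (maximum on a
#' window edge sample).
#'
#' @param waveform an `abr_waveform`.
#' @param window numeric length-2, (low, high) ms.
#' @param trough_horizon ms searched after the peak for the trough.
#' @return list with `latency` (ms), `amplitude` (uV, >= 0), `qc` (character).
#' @export
pick_wave <- function(waveform, window, trough_horizon = 2) {
  if (!inherits(waveform, "abr_waveform")) stop_input("waveform must be an 'abr_waveform'")
  t <- waveform$times
  if (window[1] < t[1] || window[2] > t[length(t)] || window[1] >= window[2])
    stop_input(sprintf("window (%g, %g) ms outside waveform span (%g, %g) ms",
                       window[1], window[2], t[1], t[length(t)]))
  idx <- which(t >= window[1] & t <= window[2])
  seg <- waveform$samples[idx]
  if (max(seg) - min(seg) == 0) {
    return(list(latency = NA_real_, amplitude = 0, qc = "no-peak"))
  }
  pk_local <- which.max(seg)
  pk <- idx[pk_local]
  qc <- if (pk_local == 1L || pk_local == length(seg)) "boundary-peak" else "clean"
  # following trough: first local minimum within the horizon after the peak
  horizon_end <- min(length(t), pk + max(1L, round(trough_horizon / 1000 * waveform$sampling_rate)))
  tail_idx <- if (pk < horizon_end) (pk + 1L):horizon_end else integer(0)
  amplitude <- 0
  if (length(tail_idx) == 0) {
    qc <- "boundary-peak"
  } else {
    y <- waveform$samples[tail_idx]
    trough <- NA_real_
    if (length(y) >= 3) {
      # a trough must be a minimum over a +/- 0.5 ms neighbourhood
      # (commensurate with ABR trough width), so noise dips on the peak's
      # falling flank are not mistaken for the following trough
      w <- max(1L, round(0.5 / 1000 * waveform$sampling_rate))
      loc_min <- Filter(function(i) {
        nb <- y[max(1L, i - w):min(length(y), i + w)]
        y[i] <= min(nb)
      }, which(diff(sign(diff(y))) > 0) + 1L)
      if (length(loc_min)) trough <- y[loc_min[1]]
    }
    if (is.na(trough)) trough <- min(y)  # fallback: minimum over the span
    amplitude <- max(waveform$samples[pk] - trough, 0)
  }
  list(latency = t[pk], amplitude = amplitude, qc = qc)
}

#' Extract wave I and V features from an averaged waveform
#'
#' Runs [pick_wave()] in the wave I (1.3-2.3 ms) and wave V (5.1-6.4 ms)
#' windows and derives the I-V inter-peak latency difference and the natural
#' log of the V/I amplitude ratio (marked missing when either amplitude is
#' zero).
#'
#' @param waveform an `abr_waveform` spanning at least 6.4 ms post onset.
#' @param wave_i_window,wave_v_window latency search windows, ms.
#' @return data.frame (one row) with columns `wave_i_latency`,
#'   `wave_i_amplitude`, `wave_v_latency`, `wave_v_amplitude`,
#'   `iv_latency_difference`, `log_vi_amplitude_ratio`, `qc_wave_i`,
#'   `qc_wave_v`, `qc_ratio`.
#' @export
extract_features <- function(waveform, wave_i_window = c(1.3, 2.3),
                             wave_v_window = c(5.1, 6.4)) {
  if (!inherits(waveform, "abr_waveform")) stop_input("waveform must be an 'abr_waveform'")
  if (max(waveform$times) < wave_v_window[2])
    stop_input("waveform must span at least ", wave_v_window[2], " ms post onset")
  w1 <- pick_wave(waveform, wave_i_window)
  w5 <- pick_wave(waveform, wave_v_window)
  ratio_ok <- w1$amplitude > 0 && w5$amplitude > 0
  data.frame(
    wave_i_latency = w1$latency, wave_i_amplitude = w1$amplitude,
    wave_v_latency = w5$latency, wave_v_amplitude = w5$amplitude,
    iv_latency_difference = w5$latency - w1$latency,
    log_vi_amplitude_ratio = if (ratio_ok) log(w5$amplitude / w1$amplitude) else NA_real_,
    qc_wave_i = w1$qc, qc_wave_v = w5$qc,
    qc_ratio = if (ratio_ok) "clean" else "zero-amplitude",
    stringsAsFactors = FALSE
  )
}

#' Full epoch-to-features processing for one recording
#'
#' Convenience wrapper: [reject_artifacts()], [average_and_filter()],
#' [extract_features()].
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv artifact-rejection threshold, uV.
#' @param band bandpass corners, Hz.
#' @param min_sweeps advisory minimum accepted sweeps.
#' @return one-row features data.frame (see [extract_features()]) with an
#'   extra `n_sweeps_accepted` column.
#' @export
process_epoch_set <- function(epochs, threshold_uv = 23.8,
                              band = c(100, 3000), min_sweeps = 2000) {
  kept <- reject_artifacts(epochs, threshold_uv)
  wf <- average_and_filter(kept, band = band, min_sweeps = min_sweeps)
  out <- extract_features(wf)
  out$n_sweeps_accepted <- wf$n_sweeps_accepted
  out
}
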