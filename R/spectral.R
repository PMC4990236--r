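#' Construct a VF waveform record
#'
#' A uniformly sampled single-channel voltage trace in millivolts. Time is
#' measured in seconds from VF onset; `t0` is the time of the first sample.
#'
#' @param samples Numeric vector of voltages (mV). All values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Opaque subject label.
#' @param t0 Time of the first sample relative to VF onset (s).
#' @return An object of class `waveform_record` with fields `samples`, `fs`,
#'   `subject_id`, `t0`.
#' @export
waveform_record <- function(samples, fs, subject_id = "s1", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform must contain at least one sample")
  if (!is.finite(fs) || fs <= 0) stop("sampling rate 'fs' must be positive")
  bad <- which(!is.finite(samples))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite sample at index %d", bad[1L]))
  }
  structure(
    list(subject_id = as.character(subject_id), samples = samples,
         fs = fs, t0 = as.numeric(t0)),
    class = "waveform_record"
  )
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> subject=%s n=%d fs=%g Hz duration=%.2f s t0=%g s\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Spectral analysis configuration
#'
#' Parameters of the sliding-window amplitude-spectrum analysis: 2.1-s frames
#' stepped every 0.5 s, a Tukey (tapered-cosine) window, and the 2-48 Hz AMSA
#' band, inclusive at both edges.
#'
#' @param window_s Frame length in seconds (default 2.1).
#' @param step_s Hop between consecutive frames in seconds (default 0.5).
#' @param tukey_alpha Tukey taper fraction in \[0, 1\] (default 0.5);
#'   0 gives a rectangular window, 1 a Hann window. The taper fraction
#'   affects absolute AMSA values through the window normalization.
#' @param band_lo,band_hi AMSA band edges in Hz (defaults 2 and 48, both
#'   inclusive). `band_hi <= fs/2` must hold when the config is used.
#' @param detrend Remove each frame's mean before tapering (default `TRUE`);
#'   prevents DC leakage into the 2 Hz band edge.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 2.1, step_s = 0.5, tukey_alpha = 0.5,
                            band_lo = 2, band_hi = 48, detrend = TRUE) {
  if (window_s <= 0) stop("window_s must be positive")
  if (step_s <= 0) stop("step_s must be positive")
  if (tukey_alpha < 0 || tukey_alpha > 1) stop("tukey_alpha must be in [0, 1]")
  if (band_lo <= 0 || band_hi <= band_lo) stop("need 0 < band_lo < band_hi")
  structure(
    list(window_s = window_s, step_s = step_s, tukey_alpha = tukey_alpha,
         band_lo = band_lo, band_hi = band_hi, detrend = isTRUE(detrend)),
    class = "spectral_config"
  )
}

#' Tukey (tapered-cosine) window
#'
#' Symmetric tapered-cosine window of length `n` with taper fraction `alpha`:
#' cosine tapers over the first and last `alpha/2` fraction of the window and
#' a flat unit center. `alpha = 0` is rectangular, `alpha = 1` is Hann.
#'
#' @param n Window length in samples.
#' @param alpha Taper fraction in \[0, 1\].
#' @return Numeric vector of `n` window coefficients in \[0, 1\].
#' @export
tukey_window <- function(n, alpha = 0.5) {
  if (n < 1) stop("window length must be >= 1")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (n == 1L) return(1)
  if (alpha == 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Slice a record into overlapping analysis frames
#'
#' Frame `k` (k = 0, 1, ...) covers `[t0 + k*step_s, t0 + k*step_s + window_s)`.
#' The number of frames is `floor((T - window_s)/step_s) + 1` where `T` is the
#' record duration; each frame's timestamp is the window center.
#'
#' @param record A [waveform_record()].
#' @param config A [spectral_config()].
#' @return A list with `center_time` (numeric vector, s) and `segments`
#'   (list of numeric vectors, each `round(window_s * fs)` samples).
#' @export
extract_frames <- function(record, config = spectral_config()) {
  n <- length(record$samples)
  nwin <- round(config$window_s * record$fs)
  if (nwin < 1L) stop("window shorter than one sample at this fs")
  if (n < nwin) {
    stop(sprintf(
      "record too short: %.3f s < one %.3f s window", n / record$fs,
      config$window_s))
  }
  duration <- n / record$fs
  # tolerance absorbs float error in (T - window)/step at exact multiples
  n_frames <- floor((duration - config$window_s) / config$step_s + 1e-9) + 1L
  k <- seq_len(n_frames) - 1L
  starts <- pmin.int(round(k * config$step_s * record$fs), n - nwin)
  segments <- lapply(starts, function(s) record$samples[(s + 1L):(s + nwin)])
  list(
    center_time = record$t0 + k * config$step_s + config$window_s / 2,
    segments = segments
  )
}

#' One-sided amplitude spectrum of a frame
#'
#' The segment is mean-removed (if `detrend`), multiplied by a Tukey taper,
#' and transformed by the DFT. Amplitudes use coherent-gain normalization:
#' `A_i = (2/sum(w)) |X_i|` for interior bins and `(1/sum(w)) |X_i|` at DC and
#' Nyquist, so a unit-amplitude sinusoid at an exact bin under a rectangular
#' taper reads ~1 mV at its bin. Bin spacing is `fs/N` with `N` the segment
#' length (no zero-padding).
#'
#' @param segment Numeric vector of voltage samples (mV), length >= 4.
#' @param fs Sampling rate (Hz).
#' @param config A [spectral_config()].
#' @param center_time Optional timestamp (s) carried into the result.
#' @return An object of class `spectral_frame` with `center_time`, `freqs`
#'   (Hz, from 0 to Nyquist), `amplitudes` (mV), `valid`.
#' @export
amplitude_spectrum <- function(segment, fs, config = spectral_config(),
                               center_time = NA_real_) {
  n <- length(segment)
  if (n < 4L) stop("segment must have at least 4 samples")
  bad <- which(!is.finite(segment))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite sample at index %d", bad[1L]))
  }
  x <- as.numeric(segment)
  if (config$detrend) x <- x - mean(x)
  w <- tukey_window(n, config$tukey_alpha)
  X <- stats::fft(x * w)
  nyq <- floor(n / 2)
  idx <- 0:nyq
  amp <- 2 * Mod(X[idx + 1L]) / sum(w)
  amp[1L] <- amp[1L] / 2                      # DC
  if (n %% 2 == 0) amp[nyq + 1L] <- amp[nyq + 1L] / 2  # Nyquist bin
  structure(
    list(center_time = center_time, freqs = idx * fs / n,
         amplitudes = amp, valid = TRUE),
    class = "spectral_frame"
  )
}

#' Amplitude spectral area of one frame
#'
#' AMSA is the summed product of amplitude and frequency over all bins whose
#' frequency lies in `[band_lo, band_hi]` (both edges inclusive): the
#' amplitude-weighted area of the in-band spectrum, in mV*Hz.
#'
#' @param frame A `spectral_frame` from [amplitude_spectrum()].
#' @param config A [spectral_config()].
#' @return AMSA in mV*Hz (non-negative scalar).
#' @export
compute_amsa <- function(frame, config = spectral_config()) {
  if (max(frame$freqs) < config$band_hi) {
    stop(sprintf("frame spectrum ends at %.2f Hz, below band_hi = %g Hz",
                 max(frame$freqs), config$band_hi))
  }
  in_band <- frame$freqs >= config$band_lo & frame$freqs <= config$band_hi
  sum(frame$amplitudes[in_band] * frame$freqs[in_band])
}

#' Flag frames dominated by sub-band (pulsatile) energy
#'
#' A frame is invalid when the fraction of total spectral amplitude lying
#' below `band_lo` exceeds `ratio_threshold` — the signature of slow
#' pulsatile artifacts (e.g. from extracorporeal circulation) that swamp the
#' VF content. An all-zero frame has ratio 0 and is valid.
#'
#' @param frames List of `spectral_frame` objects (DC..Nyquist amplitudes).
#' @param ratio_threshold Invalidity threshold on the sub-band amplitude
#'   fraction (default 0.5).
#' @param band_lo Lower band edge in Hz (default 2).
#' @return Logical vector, `TRUE` where the frame is valid.
#' @export
flag_artifacts <- function(frames, ratio_threshold = 0.5, band_lo = 2) {
  vapply(frames, function(fr) {
    total <- sum(fr$amplitudes)
    if (total == 0) return(TRUE)
    sub <- sum(fr$amplitudes[fr$freqs < band_lo])
    (sub / total) <= ratio_threshold
  }, logical(1))
}

#' AMSA trajectory of a record
#'
#' Runs the full sliding-window analysis: frame extraction, amplitude
#' spectra, artifact flagging, per-frame AMSA, and 60-s averaging. Minute `m`
#' (1-based from VF onset) averages valid frames whose center time lies in
#' `[(m-1)*60, m*60)`; minutes are reported only while fully covered by the
#' record, and a trailing incomplete minute is reported separately in
#' `partial`. A covered minute with no valid frame gets `NA`.
#'
#' @param record A [waveform_record()].
#' @param config A [spectral_config()].
#' @param ratio_threshold Artifact threshold passed to [flag_artifacts()].
#' @return An object of class `amsa_series`: `subject_id`, `frame_times`,
#'   `frame_amsa` (mV*Hz), `valid`, `minute` (1-based indices of complete
#'   minutes), `minute_amsa`, `partial` (list with `minute`, `amsa` for the
#'   trailing incomplete minute, or `NULL`), `config`.
#' @export
amsa_timeseries <- function(record, config = spectral_config(),
                            ratio_threshold = 0.5) {
  if (config$band_hi > record$fs / 2) {
    stop("band_hi exceeds Nyquist frequency for this record")
  }
  fr <- extract_frames(record, config)
  # all frames at once: columns of one matrix through mvfft; numerically
  # identical to per-frame amplitude_spectrum()
  seg <- matrix(unlist(fr$segments), ncol = length(fr$segments))
  n <- nrow(seg)
  if (config$detrend) seg <- sweep(seg, 2L, colMeans(seg))
  w <- tukey_window(n, config$tukey_alpha)
  X <- stats::mvfft(seg * w)
  nyq <- floor(n / 2)
  amp <- 2 * Mod(X[1:(nyq + 1L), , drop = FALSE]) / sum(w)
  amp[1L, ] <- amp[1L, ] / 2
  if (n %% 2 == 0) amp[nyq + 1L, ] <- amp[nyq + 1L, ] / 2
  freqs <- (0:nyq) * record$fs / n

  sub_band <- freqs < config$band_lo
  total <- colSums(amp)
  sub <- colSums(amp[sub_band, , drop = FALSE])
  valid <- total == 0 | (sub / pmax(total, .Machine$double.xmin)) <= ratio_threshold
  in_band <- freqs >= config$band_lo & freqs <= config$band_hi
  amsa <- as.vector(freqs[in_band] %*% amp[in_band, , drop = FALSE])

  end_time <- record$t0 + length(record$samples) / record$fs
  n_complete <- floor(end_time / 60 + 1e-9)
  first_min <- floor(record$t0 / 60) + 1L
  minute <- if (n_complete >= first_min) seq.int(first_min, n_complete) else integer(0)
  minute_mean <- function(m) {
    in_min <- valid & fr$center_time >= (m - 1) * 60 & fr$center_time < m * 60
    if (!any(in_min)) NA_real_ else mean(amsa[in_min])
  }
  minute_amsa <- vapply(minute, minute_mean, numeric(1))

  partial <- NULL
  if (end_time > n_complete * 60 + 1e-9) {
    pm <- n_complete + 1L
    partial <- list(minute = pm, amsa = minute_mean(pm))
  }
  structure(
    list(subject_id = record$subject_id, frame_times = fr$center_time,
         frame_amsa = amsa, valid = valid, minute = minute,
         minute_amsa = minute_amsa, partial = partial, config = config),
    class = "amsa_series"
  )
}

#' @export
print.amsa_series <- function(x, ...) {
  cat(sprintf("<amsa_series> subject=%s frames=%d (%d valid) minutes=%d\n",
              x$subject_id, length(x$frame_amsa), sum(x$valid),
              length(x$minute)))
  if (length(x$minute) > 0) {
    cat("  minute means (mV*Hz):",
        paste(sprintf("%d: %.2f", x$minute, x$minute_amsa), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Tidy data frames from an AMSA series
#'
#' @param series An `amsa_series`.
#' @return A list of two data frames: `frames` with columns `subject_id`,
#'   `center_time_s`, `amsa_mvhz`, `valid`; and `minutes` with `subject_id`,
#'   `minute`, `amsa_mvhz`.
#' @export
amsa_tables <- function(series) {
  list(
    frames = data.frame(
      subject_id = series$subject_id, center_time_s = series$frame_times,
      amsa_mvhz = series$frame_amsa, valid = series$valid,
      stringsAsFactors = FALSE),
    minutes = data.frame(
      subject_id = series$subject_id, minute = series$minute,
      amsa_mvhz = series$minute_amsa, stringsAsFactors = FALSE)
  )
}
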