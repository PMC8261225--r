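# Objective acoustic measurements used to verify the synthesis: an
# autocorrelation pitch tracker, an envelope-modulation roughness index,
# sideband-spacing estimation and spectral centroid.

# Parabolic interpolation of a peak position given neighbouring values.
.parabolic_peak <- function(y_prev, y_peak, y_next) {
  denom <- y_prev - 2 * y_peak + y_next
  if (abs(denom) < 1e-12) return(0)
  0.5 * (y_prev - y_next) / denom
}

#' Track the fundamental frequency of a waveform
#'
#' Frame-wise autocorrelation pitch tracking with a 10 ms hop.  Within each
#' frame the normalized autocorrelation is evaluated over candidate lags in
#' the `f_range` search band; a frame is voiced when the best peak exceeds
#' `voicing_threshold`.  When several autocorrelation peaks are within
#' `octave_tol` of the best one — as happens for periodic signals, whose
#' autocorrelation peaks at every multiple of the period — the candidate
#' with the highest frequency (shortest such lag) is taken, i.e. the true
#' repetition rate.  A strong subharmonic component lengthens the true
#' period, so full-depth period-doubling is tracked at `f0 / g`.
#'
#' @param waveform Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param f_range Search range in Hz, default `c(40, 1000)`.
#' @param hop Hop in seconds (default 0.010).
#' @param window Analysis window in seconds (default 0.040).
#' @param voicing_threshold Minimum normalized autocorrelation for a voiced
#'   decision (default 0.45).
#' @param octave_tol Relative tolerance within which competing peaks are
#'   considered tied (default 0.05).
#' @return A [pitch_contour()] with `step = hop`; unvoiced frames have
#'   `f0 = 0`.
#' @export
track_pitch <- function(waveform, sample_rate, f_range = c(40, 1000),
                        hop = 0.010, window = 0.040,
                        voicing_threshold = 0.45, octave_tol = 0.05) {
  if (length(waveform) == 0) stop("empty waveform")
  win <- round(window * sample_rate)
  hop_n <- round(hop * sample_rate)
  lag_min <- max(2L, floor(sample_rate / f_range[2]))
  lag_max <- ceiling(sample_rate / f_range[1])
  starts <- seq(1L, max(1L, length(waveform) - win - lag_max), by = hop_n)
  f0 <- numeric(length(starts))
  voiced <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    x <- waveform[s:(s + win - 1)]
    if (stats::sd(x) < 1e-8) next
    x <- x - mean(x)
    e0 <- sum(x^2)
    lags <- lag_min:lag_max
    r <- vapply(lags, function(l) {
      y <- waveform[(s + l):(s + l + win - 1)]
      y <- y - mean(y)
      ey <- sum(y^2)
      if (ey < 1e-12) return(0)
      sum(x * y) / sqrt(e0 * ey)
    }, numeric(1))
    # local maxima of the autocorrelation over candidate lags
    is_peak <- c(FALSE, r[-c(1, length(r))] > r[-((length(r) - 1):length(r))] &
                   r[-c(1, length(r))] >= r[-(1:2)], FALSE)
    cand <- which(is_peak)
    if (!length(cand)) cand <- which.max(r)
    best <- max(r[cand])
    if (best < voicing_threshold) next
    # shortest lag among peaks tied (within octave_tol) with the best
    tied <- cand[r[cand] >= (1 - octave_tol) * best]
    j <- min(tied)
    lag <- lags[j]
    if (j > 1 && j < length(r)) {
      lag <- lag + .parabolic_peak(r[j - 1], r[j], r[j + 1])
    }
    f0[i] <- sample_rate / lag
    voiced[i] <- TRUE
  }
  pitch_contour(f0, voiced, hop)
}

# Amplitude envelope via the analytic signal (FFT Hilbert transform).
amplitude_envelope <- function(waveform) {
  n <- length(waveform)
  X <- stats::fft(waveform)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Power spectrum of the (windowed, detrended) amplitude envelope, i.e. the
# modulation spectrum; returns frequencies and power.
.modulation_spectrum <- function(waveform, sample_rate) {
  env <- amplitude_envelope(waveform)
  env <- env - mean(env)
  n <- length(env)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)) # Hann
  P <- Mod(stats::fft(env * w))^2
  half <- seq_len(floor(n / 2))
  list(freq = (half - 1) * sample_rate / n, power = P[half])
}

#' Roughness index of a waveform
#'
#' Fraction of amplitude-envelope modulation-spectrum power falling inside
#' the roughness band (default 30-150 Hz, the modulation range perceived as
#' rough).  An unmodulated tone has a flat envelope and an index near zero;
#' amplitude modulation or strong jitter raise it.
#'
#' @param waveform Numeric waveform, at least 100 ms long.
#' @param sample_rate Sampling rate in Hz.
#' @param band Roughness band edges in Hz, default `c(30, 150)`.
#' @return Fraction in `[0, 1]`.
#' @export
roughness_index <- function(waveform, sample_rate, band = c(30, 150)) {
  if (length(waveform) < 0.1 * sample_rate) {
    stop("waveform too short for roughness analysis (< 100 ms)")
  }
  ms <- .modulation_spectrum(waveform, sample_rate)
  keep <- ms$freq >= 2 # exclude DC / slow drift
  total <- sum(ms$power[keep])
  # regularizer tied to the mean envelope level: a flat envelope yields ~0
  mean_env <- mean(amplitude_envelope(waveform))
  reg <- 1e-6 * length(waveform) * mean_env^2
  in_band <- keep & ms$freq >= band[1] & ms$freq <= band[2]
  sum(ms$power[in_band]) / (total + reg)
}

#' Estimate the spacing of sidebands around the harmonics
#'
#' Amplitude modulation at rate M creates sidebands at `k*f0 +/- M` around
#' every harmonic; the sideband spacing equals the dominant
#' amplitude-envelope modulation frequency, which is estimated here from
#' the envelope modulation spectrum with parabolic interpolation.  Returns
#' `NA` when no modulation peak stands out (e.g. an unmodulated stimulus).
#'
#' @param waveform Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param f0 Known fundamental in Hz; envelope ripple at the voice
#'   fundamental itself (within 6%) is not counted as a sideband.
#' @param band Search band in Hz, default `c(30, 150)`.
#' @param prominence Required ratio of peak power to median in-band power
#'   (default 20).
#' @param min_rel_power Minimum ratio of the in-band peak to the strongest
#'   modulation component anywhere above 2 Hz (default 0.02); rejects
#'   incidental in-band leakage from the envelope ripple at f0.
#' @return Estimated spacing in Hz, or `NA_real_` if no sidebands detected.
#' @export
sideband_spacing <- function(waveform, sample_rate, f0, band = c(30, 150),
                             prominence = 20, min_rel_power = 0.02) {
  ms <- .modulation_spectrum(waveform, sample_rate)
  in_band <- ms$freq >= band[1] & ms$freq <= band[2]
  if (!is.null(f0) && is.finite(f0)) {
    in_band <- in_band & abs(ms$freq - f0) > 0.06 * f0
  }
  if (sum(in_band) < 5) return(NA_real_)
  idx <- which(in_band)
  j <- idx[which.max(ms$power[idx])]
  med <- stats::median(ms$power[idx])
  if (med <= 0 || ms$power[j] < prominence * med) return(NA_real_)
  if (ms$power[j] < min_rel_power * max(ms$power[ms$freq >= 2])) {
    return(NA_real_)
  }
  df <- ms$freq[2] - ms$freq[1]
  shift <- if (j > 1 && j < length(ms$power)) {
    .parabolic_peak(sqrt(ms$power[j - 1]), sqrt(ms$power[j]),
                    sqrt(ms$power[j + 1]))
  } else 0
  ms$freq[j] + shift * df
}

#' Spectral centroid
#' @param waveform Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @return Power-weighted mean frequency in Hz.
#' @export
spectral_centroid <- function(waveform, sample_rate) {
  n <- length(waveform)
  P <- Mod(stats::fft(waveform))^2
  half <- seq_len(floor(n / 2))
  f <- (half - 1) * sample_rate / n
  sum(f * P[half]) / sum(P[half])
}

#' Acoustic report for a set of stimuli
#'
#' One row per stimulus: median tracked f0, spectral centroid, roughness
#' index and estimated sideband spacing (NA when absent).  The sideband
#' estimator's reference fundamental is the tracked f0 of the same
#' prototype's no-NLP stimulus when that stimulus is in the set (the voice
#' fundamental is a property of the prototype; the tracked pitch of a
#' manipulated version may instead reflect the manipulation, e.g. lock
#' onto the modulation rate itself).
#'
#' @param stimuli List of `stimulus` objects (from [resynthesize()]).
#' @param roughness_band Band for [roughness_index()].
#' @return A data.frame with one row per stimulus.
#' @export
acoustic_report <- function(stimuli, roughness_band = c(30, 150)) {
  med_f0s <- vapply(stimuli, function(s) {
    tr <- track_pitch(s$wave, s$sample_rate)
    if (any(tr$voiced)) stats::median(tr$f0[tr$voiced]) else NA_real_
  }, numeric(1))
  proto <- vapply(stimuli, `[[`, "", "prototype_id")
  cond <- vapply(stimuli, `[[`, "", "condition")
  rows <- lapply(seq_along(stimuli), function(i) {
    s <- stimuli[[i]]
    ref <- which(proto == proto[i] & cond == "none")
    ref_f0 <- if (length(ref)) med_f0s[ref[1]] else med_f0s[i]
    data.frame(
      stimulus_id = paste(s$prototype_id, s$condition, sep = "_"),
      prototype_id = s$prototype_id,
      condition = s$condition,
      tracked_f0_median = med_f0s[i],
      spectral_centroid = spectral_centroid(s$wave, s$sample_rate),
      roughness_index = roughness_index(s$wave, s$sample_rate, roughness_band),
      sideband_spacing = sideband_spacing(s$wave, s$sample_rate, ref_f0),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
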