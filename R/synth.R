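# Source-filter resynthesis with a fully controlled glottal source.
#
# The glottal source is an additive stack of harmonics of the pitch contour,
# with a fixed spectral rolloff per octave; the vocal-tract filter is applied
# by evaluating the prototype's spectral envelope at each harmonic's
# instantaneous frequency.  Each nonlinear phenomenon (NLP) is injected only
# inside the prototype's annotated segments, so that versions of a stimulus
# differ in nothing but the manipulated phenomenon.

# Quadratic (Schroeder-style) per-harmonic phase offsets keep the crest
# factor of the harmonic stack low so that RMS-normalized stimuli stay far
# from clipping.  Deterministic and independent of the number of harmonics
# actually synthesized, so adding inaudible harmonics (or lowering f0
# inside a jittered segment) never changes the phases of the others.
.harmonic_phase_offsets <- function(n_harm) {
  k <- seq_len(n_harm)
  pi * k * (k - 1) / 40
}

# Upsample a frame-level contour to the sample grid.
.contour_at_samples <- function(contour, sample_rate) {
  n <- max(1L, round(contour_duration(contour) * sample_rate))
  t_frame <- (seq_along(contour$f0) - 1) * contour$step
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- stats::approx(t_frame, contour$f0, xout = t, rule = 2)$y
  voiced <- stats::approx(t_frame, as.numeric(contour$voiced), xout = t,
                          method = "constant", rule = 2)$y > 0.5
  list(t = t, f0 = f0, voiced = voiced, n = n)
}

# Core additive synthesis given sample-level f0 and a precomputed phase
# track (radians) for the fundamental.  Harmonic k uses phase k * phase.
.additive_synth <- function(f0_samp, phase, voiced_samp, envelope,
                            sample_rate, rolloff = -6) {
  nyq <- sample_rate / 2
  fmin <- min(f0_samp[voiced_samp])
  n_harm <- max(1L, floor(nyq / fmin))
  # envelope gain lookup table, 2 Hz resolution
  grid <- seq(0, nyq, by = 2)
  gain_tab <- envelope_gain(envelope, grid)
  phi <- .harmonic_phase_offsets(n_harm)
  wave <- numeric(length(f0_samp))
  for (k in seq_len(n_harm)) {
    fk <- k * f0_samp
    live <- fk <= nyq
    if (!any(live & voiced_samp)) next
    amp <- db_to_amp(rolloff * log2(k)) *
      stats::approx(grid, gain_tab, xout = pmin(fk, nyq), rule = 2)$y
    wave <- wave + (amp * live) * sin(k * phase + phi[k])
  }
  wave * as.numeric(voiced_samp)
}

#' Synthesize the voiced (harmonic) component of a vocalization
#'
#' Additive harmonic synthesis: harmonics `k * f0(t)` up to Nyquist, each
#' with phase obtained by integrating the instantaneous frequency and
#' amplitude given by the source rolloff at `k * f0` times the spectral
#' envelope gain at `k * f0`.  Unvoiced frames are silent.
#'
#' @param contour A [pitch_contour()].
#' @param envelope A `spectral_envelope`.
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param rolloff Source spectral rolloff in dB/octave (default -6).
#' @return Numeric waveform (un-normalized).
#' @export
synthesize_voiced <- function(contour, envelope, sample_rate = 16000,
                              rolloff = -6) {
  stopifnot(inherits(contour, "pitch_contour"))
  if (length(contour$f0) == 0) stop("empty pitch contour")
  if (any(contour$f0[contour$voiced] > sample_rate / 4)) {
    stop("f0 exceeds Nyquist/2; raise the sample rate")
  }
  cs <- .contour_at_samples(contour, sample_rate)
  if (!any(cs$voiced)) return(numeric(cs$n))
  phase <- 2 * pi * cumsum(cs$f0) / sample_rate
  .additive_synth(cs$f0, phase, cs$voiced, envelope, sample_rate, rolloff)
}

#' Synthesize the subharmonic component of a stimulus
#'
#' Adds a new, harmonically related voiced component with fundamental
#' `f0 / g` (g0), filtered through the same spectral envelope and with the
#' same source rolloff as the main component, amplitude-ramped inside the
#' annotated segments and exactly zero outside them.  The returned waveform
#' is already scaled by `depth` and is meant to be mixed with the main
#' component.
#'
#' @param contour Main [pitch_contour()].
#' @param params [subharmonic_params()].
#' @param segments List of [nlp_segment()]s delimiting where the
#'   subharmonic regime is active.
#' @param envelope The prototype's `spectral_envelope`.
#' @param sample_rate Sampling rate in Hz.
#' @param rolloff Source rolloff in dB/octave.
#' @param ramp Edge ramp inside segments, seconds.
#' @return Numeric waveform component (zero outside segments).
#' @export
apply_subharmonics <- function(contour, params, segments, envelope,
                               sample_rate = 16000, rolloff = -6,
                               ramp = 0.005) {
  if (!inherits(params, "subharmonic_params")) {
    params <- do.call(subharmonic_params, params) # validates g in {2,3,4}
  }
  sub_contour <- pitch_contour(contour$f0 / params$g, contour$voiced,
                               contour$step)
  comp <- synthesize_voiced(sub_contour, envelope, sample_rate, rolloff)
  w <- segment_weight(segments, length(comp), sample_rate, ramp)
  params$depth * w * comp
}

#' Apply amplitude modulation inside annotated segments
#'
#' Multiplies the signal by a periodic low-frequency envelope with the given
#' modulation frequency and peak-to-trough relative depth.  The envelope is
#' scaled so that segment RMS is preserved (for a sinusoidal envelope the
#' scale is `1 / sqrt(a^2 + b^2/2)` with `a = 1 - depth/2`, `b = depth/2`).
#' Outside the segments the waveform is returned unchanged, sample for
#' sample.
#'
#' @param waveform Input waveform.
#' @param params [am_params()].
#' @param segments List of [nlp_segment()]s.
#' @param sample_rate Sampling rate in Hz.
#' @param shape Envelope shape, `"sine"` (raised sinusoid, default) or
#'   `"triangle"`.
#' @param ramp Edge ramp inside segments, seconds.
#' @return Modulated waveform.
#' @export
apply_am <- function(waveform, params, segments, sample_rate = 16000,
                     shape = c("sine", "triangle"), ramp = 0.005) {
  if (!inherits(params, "am_params")) params <- do.call(am_params, params)
  shape <- match.arg(shape)
  d <- params$mod_depth
  if (d == 0) return(waveform)
  n <- length(waveform)
  t <- (seq_len(n) - 1) / sample_rate
  a <- 1 - d / 2
  b <- d / 2
  out <- waveform
  for (seg in segments) {
    inside <- t >= seg$start & t < seg$end
    if (!any(inside)) next
    ph <- 2 * pi * params$mod_freq * (t[inside] - seg$start)
    carrier <- switch(shape,
                      sine = cos(ph),
                      triangle = 2 / pi * asin(cos(ph)))
    env <- a + b * carrier
    scale <- 1 / sqrt(mean(env^2)) # RMS-preserving mean level
    w <- segment_weight(list(seg), n, sample_rate, ramp)[inside]
    out[inside] <- waveform[inside] * (1 + w * (scale * env - 1))
  }
  out
}

#' Emulate deterministic chaos as strong jitter on the pitch contour
#'
#' Inside the annotated segments, f0 is multiplied frame-wise by
#' `2^(d / 12)` where `d` is a random deviation drawn uniformly in
#' `[-jitter_depth, jitter_depth]` semitones and redrawn every
#' `jitter_period` seconds.  Outside the segments the contour is unchanged.
#' Reproducible under a fixed seed.
#'
#' @param contour A [pitch_contour()].
#' @param params [chaos_params()].
#' @param segments List of [nlp_segment()]s.
#' @param seed Integer seed for the jitter draws, or `NULL`.
#' @return A jittered [pitch_contour()].
#' @export
apply_chaos <- function(contour, params, segments, seed = NULL) {
  if (!inherits(params, "chaos_params")) params <- do.call(chaos_params, params)
  with_seed(seed, {
    f0 <- contour$f0
    t <- (seq_along(f0) - 1) * contour$step
    block <- max(1L, round(params$jitter_period / contour$step))
    for (seg in segments) {
      idx <- which(t >= seg$start & t < seg$end)
      if (!length(idx)) next
      n_blocks <- ceiling(length(idx) / block)
      d <- stats::runif(n_blocks, -params$jitter_depth, params$jitter_depth)
      dev <- rep(d, each = block)[seq_along(idx)]
      f0[idx] <- f0[idx] * 2^(dev / 12)
    }
    pitch_contour(f0, contour$voiced, contour$step)
  })
}

# Synthesis of the chaos condition: jitter changes the source only inside
# the segments.  The phase track equals the no-NLP track outside segments
# (accumulated frequency deviations are reset at each segment end), so the
# waveform is sample-identical to the no-NLP version outside the annotated
# NLP windows.
.synth_chaos <- function(prototype, sample_rate, rolloff, seed) {
  jit <- apply_chaos(prototype$contour, prototype$nlp_params$chaos,
                     prototype$segments, seed = seed)
  base <- .contour_at_samples(prototype$contour, sample_rate)
  chaos <- .contour_at_samples(jit, sample_rate)
  # jitter is strictly segment-local: keep the base f0 at every sample
  # outside the segments (frame interpolation would otherwise bleed a few
  # ms across the boundaries)
  f0_c <- base$f0
  phase_base <- 2 * pi * cumsum(base$f0) / sample_rate
  adj <- numeric(base$n)
  for (seg in prototype$segments) {
    idx <- which(base$t >= seg$start & base$t < seg$end)
    if (!length(idx)) next
    f0_c[idx] <- chaos$f0[idx]
    adj[idx] <- 2 * pi * cumsum(f0_c[idx] - base$f0[idx]) / sample_rate
  }
  .additive_synth(f0_c, phase_base + adj, chaos$voiced,
                  prototype$envelope, sample_rate, rolloff)
}

#' Resynthesize a prototype in one condition
#'
#' Produces the stimulus for `prototype x condition`: the pitch contour and
#' spectral envelope are identical across conditions, and exactly one NLP
#' type (or none) is injected inside the prototype's annotated segments.
#' The output is RMS-normalized to a common level so that loudness is
#' constant across conditions.
#'
#' @param prototype A [prototype()].
#' @param condition One of `"none"`, `"am"`, `"subharmonics"`, `"chaos"`.
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param rolloff Source rolloff in dB/octave (default -6).
#' @param target_rms_db Normalization target in dBFS (default -20).
#' @param normalize If `FALSE`, skip RMS normalization (used when checking
#'   sample-identity of conditions outside NLP segments).
#' @param seed Seed for the chaos jitter draws; by default derived
#'   deterministically from the prototype id so repeated calls agree.
#' @return An object of class `stimulus`: list with `prototype_id`,
#'   `condition`, `wave`, `sample_rate`.
#' @export
resynthesize <- function(prototype, condition, sample_rate = 16000,
                         rolloff = -6, target_rms_db = -20,
                         normalize = TRUE, seed = NULL) {
  stopifnot(inherits(prototype, "prototype"))
  if (!(length(condition) == 1 && condition %in% CONDITIONS)) {
    stop("unknown condition: ", paste(condition, collapse = ", "))
  }
  if (is.null(seed)) seed <- sum(utf8ToInt(prototype$id)) %% 100000L + 17L
  wave <- switch(
    condition,
    none = synthesize_voiced(prototype$contour, prototype$envelope,
                             sample_rate, rolloff),
    am = apply_am(synthesize_voiced(prototype$contour, prototype$envelope,
                                    sample_rate, rolloff),
                  prototype$nlp_params$am, prototype$segments, sample_rate),
    subharmonics = {
      main <- synthesize_voiced(prototype$contour, prototype$envelope,
                                sample_rate, rolloff)
      main + apply_subharmonics(prototype$contour,
                                prototype$nlp_params$subharmonics,
                                prototype$segments, prototype$envelope,
                                sample_rate, rolloff)
    },
    chaos = .synth_chaos(prototype, sample_rate, rolloff, seed)
  )
  if (normalize) {
    r <- rms(wave)
    if (r > 0) wave <- wave * db_to_amp(target_rms_db) / r
    peak <- max(abs(wave))
    if (peak > 0.999) wave <- wave * 0.999 / peak
  }
  structure(list(prototype_id = prototype$id, condition = condition,
                 wave = wave, sample_rate = sample_rate),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus %s/%s: %.2f s @ %d Hz, RMS %.3f>\n",
              x$prototype_id, x$condition,
              length(x$wave) / x$sample_rate, x$sample_rate, rms(x$wave)))
  invisible(x)
}
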