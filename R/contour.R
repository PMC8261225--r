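# Domain containers for the synthesis stage: pitch contours, spectral
# envelopes, nonlinear-phenomenon (NLP) segment annotations, prototypes and
# synthesized stimuli.  Plain lists with S3 classes and validators, in the
# style of field packages for parametric voice synthesis.

#' Nonlinear vocal phenomenon types and synthesis conditions
#'
#' `NLP_TYPES` are the three manipulated phenomena; `CONDITIONS` adds the
#' no-NLP reference, giving the four synthesis conditions of every
#' prototype.
#'
#' @format Character vectors.
#' @export
NLP_TYPES <- c("am", "subharmonics", "chaos")

#' @rdname NLP_TYPES
#' @export
CONDITIONS <- c("none", NLP_TYPES)

#' Construct a pitch contour
#'
#' A fundamental-frequency (f0) trajectory sampled at a fixed step
#' (default 10 ms), with a per-frame voicing flag.  This is the carrier of
#' all source manipulations: subharmonics and jitter are defined relative
#' to it.
#'
#' @param f0 Numeric vector of f0 values in Hz, one per frame.
#' @param voiced Logical vector, one per frame; defaults to `f0 > 0`.
#' @param step Frame step in seconds (default 0.010).
#' @return An object of class `pitch_contour`.
#' @export
pitch_contour <- function(f0, voiced = f0 > 0, step = 0.010) {
  stopifnot(is.numeric(f0), length(f0) >= 1, length(voiced) == length(f0),
            is.numeric(step), step > 0)
  if (any(voiced & (!is.finite(f0) | f0 <= 0))) {
    stop("f0 must be positive and finite on voiced frames")
  }
  structure(list(f0 = as.numeric(f0), voiced = as.logical(voiced),
                 step = step),
            class = "pitch_contour")
}

#' @export
print.pitch_contour <- function(x, ...) {
  cat(sprintf("<pitch_contour: %d frames, step %.0f ms, duration %.2f s, median f0 %.0f Hz>\n",
              length(x$f0), x$step * 1000, contour_duration(x),
              stats::median(x$f0[x$voiced])))
  invisible(x)
}

#' Duration of a pitch contour in seconds
#' @param contour A `pitch_contour`.
#' @return Duration in seconds (`n_frames * step`).
#' @export
contour_duration <- function(contour) length(contour$f0) * contour$step

#' Construct a spectral envelope from a formant list
#'
#' The vocal-tract filter is represented as a sum of resonance (formant)
#' peaks over a dB gain curve; each formant has a centre frequency,
#' bandwidth and peak amplitude.  Alternatively a smoothed gain curve can
#' be supplied directly via [envelope_curve()].
#'
#' @param freq Formant centre frequencies in Hz.
#' @param bw Formant bandwidths in Hz.
#' @param amp_db Formant peak amplitudes in dB (relative).
#' @return An object of class `spectral_envelope`.
#' @export
formant_envelope <- function(freq, bw, amp_db = rep(0, length(freq))) {
  stopifnot(length(freq) == length(bw), length(freq) == length(amp_db),
            all(freq > 0), all(bw > 0), all(is.finite(amp_db)))
  structure(list(type = "formants",
                 formants = data.frame(freq = freq, bw = bw, amp_db = amp_db)),
            class = "spectral_envelope")
}

#' Construct a spectral envelope from a smoothed gain curve
#'
#' @param freq Monotonic frequency grid in Hz starting at 0.
#' @param gain_db Gain in dB at each grid frequency; finite.
#' @return An object of class `spectral_envelope`.
#' @export
envelope_curve <- function(freq, gain_db) {
  stopifnot(length(freq) == length(gain_db), all(diff(freq) > 0),
            freq[1] >= 0, all(is.finite(gain_db)))
  structure(list(type = "curve", freq = freq, gain_db = gain_db),
            class = "spectral_envelope")
}

#' Evaluate a spectral envelope as linear amplitude gain
#'
#' @param envelope A `spectral_envelope`.
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @return Linear amplitude gains (max-normalized to 1).
#' @export
envelope_gain <- function(envelope, freq_hz) {
  stopifnot(inherits(envelope, "spectral_envelope"))
  if (envelope$type == "curve") {
    g_db <- stats::approx(envelope$freq, envelope$gain_db, xout = freq_hz,
                          rule = 2)$y
    return(db_to_amp(g_db - max(envelope$gain_db)))
  }
  fo <- envelope$formants
  # sum of Lorentzian resonance power profiles plus a -40 dB floor
  pow <- rep(1e-4, length(freq_hz))
  for (i in seq_len(nrow(fo))) {
    hw <- fo$bw[i] / 2
    pow <- pow + 10^(fo$amp_db[i] / 10) * hw^2 / ((freq_hz - fo$freq[i])^2 + hw^2)
  }
  sqrt(pow / max(1, max(pow)))
}

#' Amplitude-modulation parameters
#' @param mod_freq Modulation frequency in Hz (> 0).
#' @param mod_depth Peak-to-trough relative modulation depth in `[0, 1]`.
#' @return An `am_params` object.
#' @export
am_params <- function(mod_freq, mod_depth = 0.5) {
  stopifnot(is.numeric(mod_freq), mod_freq > 0,
            mod_depth >= 0, mod_depth <= 1)
  structure(list(mod_freq = mod_freq, mod_depth = mod_depth),
            class = "am_params")
}

#' Subharmonic parameters
#'
#' A subharmonic regime adds a new voiced component whose fundamental g0 is
#' an integer fraction of f0 (f0/2, f0/3 or f0/4), filling the spectrum
#' between the harmonics of f0.
#'
#' @param g Integer divisor, one of 2, 3, 4.
#' @param depth Amplitude of the subharmonic component relative to the main
#'   component, in `[0, 1]`.
#' @return A `subharmonic_params` object.
#' @export
subharmonic_params <- function(g, depth = 0.5) {
  if (!(length(g) == 1 && g %in% c(2, 3, 4))) {
    stop("subharmonic divisor g must be 2, 3 or 4")
  }
  stopifnot(depth >= 0, depth <= 1)
  structure(list(g = as.integer(g), depth = depth),
            class = "subharmonic_params")
}

#' Chaos (jitter) parameters
#'
#' Deterministic chaos is emulated as strong jitter: rapid random pitch
#' deviations, redrawn every `jitter_period` seconds, bounded by
#' `jitter_depth` semitones.
#'
#' @param jitter_depth Peak pitch deviation in semitones (> 0).
#' @param jitter_period Time scale of random pitch changes in seconds.
#' @return A `chaos_params` object.
#' @export
chaos_params <- function(jitter_depth = 6, jitter_period = 0.010) {
  stopifnot(jitter_depth > 0, jitter_period > 0)
  structure(list(jitter_depth = jitter_depth, jitter_period = jitter_period),
            class = "chaos_params")
}

#' Annotated NLP segment
#'
#' @param nlp_type One of `"am"`, `"subharmonics"`, `"chaos"` — the type
#'   annotated in the prototype recording.
#' @param start,end Segment boundaries in seconds, `0 <= start < end`.
#' @return An `nlp_segment` object.
#' @export
nlp_segment <- function(nlp_type, start, end) {
  nlp_type <- match.arg(nlp_type, NLP_TYPES)
  stopifnot(start >= 0, end > start)
  structure(list(nlp_type = nlp_type, start = start, end = end),
            class = "nlp_segment")
}

#' Construct a prototype vocalization
#'
#' One "original" vocalization: a pitch contour, a spectral envelope,
#' annotated NLP segments (timing windows into which each manipulation is
#' injected), and per-type NLP parameters drawn for this prototype.
#'
#' @param id Character id.
#' @param sex `"M"` or `"F"`.
#' @param contour A `pitch_contour`.
#' @param envelope A `spectral_envelope`.
#' @param segments List of `nlp_segment`s; at least one, all within the
#'   contour duration.
#' @param nlp_params Named list with elements `am` ([am_params()]),
#'   `subharmonics` ([subharmonic_params()]) and `chaos` ([chaos_params()]).
#' @return An object of class `prototype`.
#' @export
prototype <- function(id, sex, contour, envelope, segments, nlp_params) {
  sex <- match.arg(sex, c("M", "F"))
  stopifnot(inherits(contour, "pitch_contour"),
            inherits(envelope, "spectral_envelope"),
            length(segments) >= 1)
  dur <- contour_duration(contour)
  for (seg in segments) {
    stopifnot(inherits(seg, "nlp_segment"))
    if (seg$end > dur + 1e-9) stop("NLP segment extends beyond prototype duration")
  }
  stopifnot(inherits(nlp_params$am, "am_params"),
            inherits(nlp_params$subharmonics, "subharmonic_params"),
            inherits(nlp_params$chaos, "chaos_params"))
  structure(list(id = as.character(id), sex = sex, duration = dur,
                 contour = contour, envelope = envelope,
                 segments = segments, nlp_params = nlp_params),
            class = "prototype")
}

#' @export
print.prototype <- function(x, ...) {
  cat(sprintf("<prototype %s (%s): %.2f s, %d NLP segment(s), median f0 %.0f Hz>\n",
              x$id, x$sex, x$duration, length(x$segments),
              stats::median(x$contour$f0[x$contour$voiced])))
  invisible(x)
}

# Sample-level boolean mask of the union of segments (TRUE inside)
segment_mask <- function(segments, n, sample_rate) {
  mask <- logical(n)
  t <- (seq_len(n) - 1) / sample_rate
  for (seg in segments) mask <- mask | (t >= seg$start & t < seg$end)
  mask
}

# Raised-cosine ramped weight inside the segment mask: exactly 0 outside
# every segment, ramping 0 -> 1 over `ramp` seconds just inside each edge.
segment_weight <- function(segments, n, sample_rate, ramp = 0.005) {
  w <- numeric(n)
  t <- (seq_len(n) - 1) / sample_rate
  for (seg in segments) {
    inside <- t >= seg$start & t < seg$end
    if (!any(inside)) next
    ts <- t[inside]
    half <- (seg$end - seg$start) / 2
    r <- min(ramp, half)
    wi <- rep(1, length(ts))
    if (r > 0) {
      up <- ts < seg$start + r
      wi[up] <- 0.5 - 0.5 * cos(pi * (ts[up] - seg$start) / r)
      dn <- ts >= seg$end - r
      wi[dn] <- 0.5 - 0.5 * cos(pi * (seg$end - ts[dn]) / r)
    }
    w[inside] <- pmax(w[inside], wi)
  }
  w
}
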