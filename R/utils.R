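#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded package functions do not disturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a root seed; keeps values in
# 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

#' Root-mean-square amplitude
#' @param x Numeric waveform.
#' @return RMS of `x`.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Convert decibels (re full scale) to linear amplitude
#' @param db Level in dB.
#' @return Linear amplitude `10^(db/20)`.
#' @export
db_to_amp <- function(db) 10^(db / 20)

#' Convert a frequency ratio to semitones
#'
#' The musical interval between two frequencies: `12 * log2(f / ref)`.
#' One semitone is 1/12 of an octave.
#'
#' @param f Frequency in Hz (vectorised), must be positive.
#' @param ref Reference frequency in Hz, must be positive.
#' @return Interval in semitones (positive when `f > ref`).
#' @examples
#' hz_to_semitones(200, 100) # one octave = 12 semitones
#' @export
hz_to_semitones <- function(f, ref) {
  if (any(!is.finite(f)) || any(f <= 0) || !is.finite(ref) || ref <= 0) {
    stop("hz_to_semitones() requires positive finite frequencies")
  }
  12 * log2(f / ref)
}

#' Convert semitones above a reference to Hz
#' @param st Interval in semitones.
#' @param ref Reference frequency in Hz.
#' @return Frequency in Hz.
#' @export
semitones_to_hz <- function(st, ref) ref * 2^(st / 12)
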