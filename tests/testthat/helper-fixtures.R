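# Shared fixtures, built in code.

flat_envelope <- function() envelope_curve(c(0, 8000), c(0, 0))

# A minimal fully voiced prototype with a flat pitch contour and one NLP
# segment spanning a known window; handy for spectral oracles.
flat_prototype <- function(f0 = 300, dur = 1, seg = c(0.2, 0.8),
                           id = "fx_flat", sex = "M",
                           am = am_params(90, 1),
                           sub = subharmonic_params(2, 1),
                           chaos = chaos_params(6)) {
  n <- round(dur / 0.01)
  prototype(
    id, sex,
    pitch_contour(rep(f0, n)),
    flat_envelope(),
    list(nlp_segment("chaos", seg[1], seg[2])),
    list(am = am, subharmonics = sub, chaos = chaos)
  )
}

# Frequencies of FFT magnitude peaks above a relative power threshold.
fft_peak_freqs <- function(wave, sample_rate, rel_power = 0.005) {
  P <- Mod(stats::fft(wave))^2
  half <- seq_len(floor(length(P) / 2))
  f <- (half - 1) * sample_rate / length(P)
  peaks <- P[half] > rel_power * max(P[half])
  # keep local maxima only
  loc <- c(FALSE, P[half][-c(1, length(half))] > P[half][-((length(half) - 1):length(half))] &
             P[half][-c(1, length(half))] >= P[half][-(1:2)], FALSE)
  f[peaks & loc]
}

# A tiny rating world: prototypes, stimuli and an allocation, sized for
# fast model fits.
small_rating_world <- function(n_proto = 12, n_part = 40, per_block = 15,
                               seed = 100) {
  protos <- generate_prototypes(n_proto, seed = seed)
  stim <- build_stimulus_set(protos)
  alloc <- allocate_rating_trials(n_part, stim, seed = seed + 1,
                                  stimuli_per_block = per_block)
  list(protos = protos, stim = stim, alloc = alloc)
}
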