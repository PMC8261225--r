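test_that("harmonic synthesis produces the constructed periodicity and spectrum", {
  ct <- pitch_contour(rep(200, 100))
  w <- synthesize_voiced(ct, flat_envelope())
  expect_length(w, 16000)
  # autocorrelation peak at one period (5 ms = 80 samples)
  ac <- stats::acf(w, lag.max = 120, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[40:120]) + 39, 80, tolerance = 0)
  # FFT oracle: magnitude peaks only within one bin of multiples of 200 Hz
  pk <- fft_peak_freqs(w, 16000)
  expect_gt(length(pk), 5)
  expect_true(all(abs(pk - 200 * round(pk / 200)) <= 1))
})

test_that("unvoiced frames are silent and invalid inputs error", {
  ct <- pitch_contour(rep(200, 50), voiced = rep(FALSE, 50))
  expect_equal(synthesize_voiced(ct, flat_envelope()), rep(0, 8000))
  expect_error(synthesize_voiced(pitch_contour(rep(5000, 10)), flat_envelope()),
               "Nyquist")
  expect_error(pitch_contour(numeric(0)), "length")
})

test_that("subharmonic component adds exactly the g0 harmonic series", {
  seg <- list(nlp_segment("subharmonics", 0, 1))
  ct <- pitch_contour(rep(300, 100))
  env <- flat_envelope()
  base <- synthesize_voiced(ct, env)
  base_pk <- fft_peak_freqs(base, 16000)
  for (g in c(2, 3)) {
    comp <- apply_subharmonics(ct, subharmonic_params(g, 1), seg, env,
                               ramp = 0)
    pk <- fft_peak_freqs(base + comp, 16000)
    g0 <- 300 / g
    # all peaks are multiples of g0 = f0/g ...
    expect_true(all(abs(pk - g0 * round(pk / g0)) <= 2))
    # ... and the non-f0 multiples are new relative to the no-NLP version
    new_pk <- pk[abs(pk - 300 * round(pk / 300)) > 2]
    expect_gt(length(new_pk), 3)
    expect_true(all(vapply(new_pk, function(p) min(abs(base_pk - p)) > 10,
                           logical(1))))
  }
  expect_error(subharmonic_params(5, 1), "2, 3 or 4")
})

test_that("zero-depth manipulations are bit-identical to the no-NLP synthesis", {
  seg <- list(nlp_segment("am", 0.1, 0.9))
  ct <- pitch_contour(rep(250, 100))
  env <- flat_envelope()
  base <- synthesize_voiced(ct, env)
  expect_identical(apply_am(base, am_params(90, 0), seg), base)
  comp <- apply_subharmonics(ct, subharmonic_params(2, 0), seg, env)
  expect_identical(base + comp, base)
})

test_that("amplitude modulation creates sidebands at +/- mod_freq with half amplitude", {
  # pure tone: synthesize a single 1000 Hz partial via a contour with one
  # harmonic under Nyquist at rolloff 0
  n <- 16000
  t <- (0:(n - 1)) / 16000
  tone <- sin(2 * pi * 1000 * t)
  seg <- list(nlp_segment("am", 0, 1))
  wam <- apply_am(tone, am_params(90, 1), seg, ramp = 0)
  A <- Mod(stats::fft(wam))[1:8000]
  f <- 0:7999
  amp_at <- function(freq) max(A[abs(f - freq) <= 1])
  # AM identity: (a + b cos(2 pi M t)) sin(2 pi f t) has sidebands of
  # amplitude b/2 relative to carrier amplitude a
  expect_equal(amp_at(910) / amp_at(1000), 0.5, tolerance = 0.02)
  expect_equal(amp_at(1090) / amp_at(1000), 0.5, tolerance = 0.02)
  # harmonic stimulus: sidebands flank every harmonic
  ct <- pitch_contour(rep(400, 100))
  ws <- apply_am(synthesize_voiced(ct, flat_envelope()), am_params(90, 1),
                 seg, ramp = 0)
  A2 <- Mod(stats::fft(ws))[1:8000]
  for (h in c(400, 800, 1200)) {
    side <- max(A2[abs(f - (h + 90)) <= 1])
    floor_amp <- stats::median(A2)
    expect_gt(side, 50 * floor_amp)
  }
})

test_that("amplitude modulation preserves segment RMS", {
  ct <- pitch_contour(rep(250, 100))
  base <- synthesize_voiced(ct, flat_envelope())
  seg <- list(nlp_segment("am", 0.1, 0.9))
  for (d in c(0.3, 0.7, 1)) {
    wam <- apply_am(base, am_params(90, d), seg, ramp = 0)
    idx <- 1600:14400
    expect_equal(rms(wam[idx]), rms(base[idx]), tolerance = 0.01)
  }
})

test_that("chaos jitter is bounded, segment-local and seed-reproducible", {
  ct <- pitch_contour(rep(300, 100))
  seg <- list(nlp_segment("chaos", 0.3, 0.7))
  j1 <- apply_chaos(ct, chaos_params(6), seg, seed = 42)
  j2 <- apply_chaos(ct, chaos_params(6), seg, seed = 42)
  j3 <- apply_chaos(ct, chaos_params(6), seg, seed = 43)
  expect_identical(j1$f0, j2$f0)
  expect_false(identical(j1$f0, j3$f0))
  t <- (seq_along(ct$f0) - 1) * ct$step
  inside <- t >= 0.3 & t < 0.7
  expect_identical(j1$f0[!inside], ct$f0[!inside])
  dev_st <- abs(12 * log2(j1$f0[inside] / 300))
  expect_true(all(dev_st <= 6 + 1e-9))
  expect_gt(max(dev_st), 1) # strong jitter actually applied
  # depth -> 0 limit
  j0 <- apply_chaos(ct, chaos_params(1e-9), seg, seed = 1)
  expect_equal(j0$f0, ct$f0, tolerance = 1e-9)
})

test_that("resynthesis is condition-pure outside annotated segments", {
  p <- flat_prototype(f0 = 280, seg = c(0.3, 0.6))
  waves <- lapply(CONDITIONS, function(cc) {
    resynthesize(p, cc, normalize = FALSE)$wave
  })
  names(waves) <- CONDITIONS
  t <- (seq_along(waves$none) - 1) / 16000
  outside <- t < 0.3 | t >= 0.6
  for (cc in NLP_TYPES) {
    expect_identical(waves[[cc]][outside], waves$none[outside])
    expect_false(identical(waves[[cc]][!outside], waves$none[!outside]))
  }
})

test_that("resynthesis normalizes RMS equally across the four conditions", {
  p <- flat_prototype(f0 = 350, seg = c(0.2, 0.8))
  stims <- lapply(CONDITIONS, function(cc) resynthesize(p, cc))
  rmss <- vapply(stims, function(s) rms(s$wave), numeric(1))
  expect_true(all(abs(rmss / db_to_amp(-20) - 1) < 0.01))
  durs <- vapply(stims, function(s) length(s$wave), numeric(1))
  expect_true(all(durs == durs[1]))
  expect_true(all(vapply(stims, function(s) max(abs(s$wave)) <= 1, logical(1))))
  # determinism: same prototype, same condition, identical waveforms
  expect_identical(resynthesize(p, "chaos")$wave, resynthesize(p, "chaos")$wave)
  expect_error(resynthesize(p, "tremolo"), "unknown condition")
})

test_that("WAV round trip preserves the waveform to 16-bit precision", {
  p <- flat_prototype(f0 = 220, dur = 0.3, seg = c(0.05, 0.25))
  s <- resynthesize(p, "am")
  path <- tempfile(fileext = ".wav")
  write_wav(s$wave, s$sample_rate, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 16000)
  expect_lt(max(abs(back$wave - s$wave)), 1.1 / 32767)
  unlink(path)
})
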