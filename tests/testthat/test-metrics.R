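test_that("pitch tracker recovers flat synthesized contours within 1%", {
  env <- flat_envelope()
  for (f0 in c(120, 200, 440)) {
    w <- synthesize_voiced(pitch_contour(rep(f0, 80)), env)
    tr <- track_pitch(w, 16000)
    expect_gt(mean(tr$voiced), 0.8)
    expect_lt(abs(stats::median(tr$f0[tr$voiced]) - f0) / f0, 0.01)
  }
})

test_that("full-depth g=2 subharmonics halve the tracked pitch", {
  ct <- pitch_contour(rep(300, 100))
  env <- flat_envelope()
  seg <- list(nlp_segment("subharmonics", 0, 1))
  w <- synthesize_voiced(ct, env) +
    apply_subharmonics(ct, subharmonic_params(2, 1), seg, env, ramp = 0)
  tr <- track_pitch(w, 16000)
  expect_lt(abs(stats::median(tr$f0[tr$voiced]) - 150), 2)
})

test_that("white noise is classified as unvoiced", {
  set.seed(7)
  noise <- stats::rnorm(16000) * 0.1
  tr <- track_pitch(noise, 16000)
  expect_gte(mean(!tr$voiced), 0.9)
  # silent input: all-unvoiced contour
  tr0 <- track_pitch(rep(0, 8000), 16000)
  expect_true(all(!tr0$voiced))
})

test_that("roughness index is near zero without modulation and monotone in AM depth", {
  ct <- pitch_contour(rep(300, 100))
  base <- synthesize_voiced(ct, flat_envelope())
  expect_lt(roughness_index(base, 16000), 0.05)
  seg <- list(nlp_segment("am", 0, 1))
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  ri <- vapply(depths, function(d) {
    roughness_index(apply_am(base, am_params(90, d), seg, ramp = 0), 16000)
  }, numeric(1))
  expect_true(all(diff(ri) > 0))
  expect_gt(ri[length(ri)], ri[1])
  expect_error(roughness_index(base[1:100], 16000), "short")
})

test_that("roughness increases with jitter depth on matched stimuli", {
  p0 <- flat_prototype(f0 = 300, seg = c(0, 1), chaos = chaos_params(0.5))
  p1 <- flat_prototype(f0 = 300, seg = c(0, 1), chaos = chaos_params(8))
  r0 <- roughness_index(resynthesize(p0, "chaos", seed = 5)$wave, 16000)
  r1 <- roughness_index(resynthesize(p1, "chaos", seed = 5)$wave, 16000)
  expect_gt(r1, r0)
})

test_that("semitone conversion follows the 12*log2 contract", {
  expect_equal(hz_to_semitones(200, 100), 12)
  expect_equal(hz_to_semitones(100, 100), 0)
  # the pitch slider spans six octaves: 62 Hz to 4300 Hz ~ 73.4 semitones
  expect_equal(hz_to_semitones(4300, 62), 73.39, tolerance = 0.01)
  expect_error(hz_to_semitones(-1, 100), "positive")
  expect_error(hz_to_semitones(100, 0), "positive")
})

test_that("sideband spacing recovers the modulation rate and is absent without AM", {
  ct <- pitch_contour(rep(300, 100))
  base <- synthesize_voiced(ct, flat_envelope())
  seg <- list(nlp_segment("am", 0, 1))
  for (m in c(70, 90, 110)) {
    w <- apply_am(base, am_params(m, 1), seg, ramp = 0)
    expect_lt(abs(sideband_spacing(w, 16000, 300) - m), 2)
  }
  expect_true(is.na(sideband_spacing(base, 16000, 300)))
})

test_that("chaos shifts the spectral centroid relative to the no-NLP version", {
  p <- flat_prototype(f0 = 300, seg = c(0.1, 0.9))
  c_none <- spectral_centroid(resynthesize(p, "none")$wave, 16000)
  c_chaos <- spectral_centroid(resynthesize(p, "chaos")$wave, 16000)
  expect_gt(abs(c_chaos - c_none) / c_none, 0.005)
})

test_that("acoustic report emits one complete row per stimulus", {
  p <- flat_prototype(f0 = 300, dur = 0.6, seg = c(0.1, 0.5))
  stims <- lapply(c("none", "am"), function(cc) resynthesize(p, cc))
  rep <- acoustic_report(stims)
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$roughness_index >= 0 & rep$roughness_index <= 1))
  expect_true(all(rep$tracked_f0_median > 0))
  expect_true(is.na(rep$sideband_spacing[rep$condition == "none"]))
  expect_lt(abs(rep$sideband_spacing[rep$condition == "am"] - 90), 2)
})
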