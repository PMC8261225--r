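test_that("prototype generator matches the corpus conditions", {
  protos <- generate_prototypes(82, seed = 1)
  expect_length(protos, 82)
  durs <- vapply(protos, function(p) p$duration, numeric(1))
  # mean duration within 2 s.e. of 1.0 s (population sd 0.5 s)
  expect_lt(abs(mean(durs) - 1.0), 2 * 0.5 / sqrt(82))
  expect_true(all(durs >= 0.3))
  # same seed reproduces the set; a single prototype passes all invariants
  protos2 <- generate_prototypes(82, seed = 1)
  expect_identical(protos, protos2)
  p1 <- generate_prototypes(1, seed = 9)[[1]]
  expect_s3_class(p1, "prototype")
  expect_error(generate_prototypes(0), ">= 1")
})

test_that("prototype NLP segments and parameters respect the configured ranges", {
  protos <- generate_prototypes(60, seed = 2)
  for (p in protos) {
    cover <- sum(vapply(p$segments, function(s) s$end - s$start, numeric(1)))
    expect_gte(cover / p$duration, 0.3)
    for (s in p$segments) {
      expect_gte(s$start, 0)
      expect_lte(s$end, p$duration + 1e-9)
    }
    expect_true(p$nlp_params$subharmonics$g %in% 2:4)
    expect_true(p$nlp_params$am$mod_freq >= 30 && p$nlp_params$am$mod_freq <= 150)
    f0 <- p$contour$f0[p$contour$voiced]
    expect_true(all(f0 > 40 & f0 < 1200))
  }
  # the sampled AM rates follow the configured 90 +/- 20 Hz population
  am <- vapply(generate_prototypes(400, seed = 3),
               function(p) p$nlp_params$am$mod_freq, numeric(1))
  expect_lt(abs(mean(am) - 90), 2 * 20 / sqrt(400))
  expect_lt(abs(stats::sd(am) - 20), 5)
})

test_that("rating simulator reduces to the scale baselines when all variation is off", {
  w <- small_rating_world()
  eff0 <- default_effect_table()
  eff0$ratings$effect <- 0
  par0 <- default_cohort_params()
  par0$scales[, c("sd_participant", "sd_prototype",
                  "sd_proto_condition", "sd_resid")] <- 0
  tr <- simulate_ratings(w$alloc, eff0, par0, seed = 5)
  base <- stats::setNames(par0$scales$baseline, par0$scales$scale)
  for (s in unique(tr$scale)) {
    y <- tr$response[tr$scale == s]
    if (s == "pitch") y <- hz_to_semitones(y, 62)
    expect_equal(unique(y), unname(base[s]), tolerance = 1e-9)
  }
})

test_that("rating simulator reproduces configured condition effects at large n", {
  protos <- generate_prototypes(40, seed = 6)
  stim <- build_stimulus_set(protos)
  alloc <- allocate_rating_trials(600, stim, seed = 7, stimuli_per_block = 40)
  tr <- simulate_ratings(alloc, seed = 8)
  d <- tr[tr$scale == "pitch", ]
  st <- hz_to_semitones(d$response, 62)
  diff <- mean(st[d$condition == "chaos"]) - mean(st[d$condition == "none"])
  expect_equal(diff, -4.2, tolerance = 0.6)
  # responses respect the slider bounds on every scale
  sc <- default_cohort_params()$scales
  for (s in sc$scale) {
    y <- tr$response[tr$scale == s]
    if (s == "pitch") {
      expect_true(all(y >= 62 - 1e-6 & y <= 4300 + 1e-6))
    } else {
      expect_true(all(y >= sc$lo[sc$scale == s] & y <= sc$hi[sc$scale == s]))
    }
  }
  # different seeds: different values, identical schema
  tr2 <- simulate_ratings(alloc, seed = 9)
  expect_identical(names(tr2), names(tr))
  expect_false(identical(tr2$response, tr$response))
})

test_that("forced-choice simulator is symmetric for identical pairs and honours the tie limit", {
  protos <- generate_prototypes(20, seed = 10)
  pairs <- enumerate_pairs(protos)
  alloc <- allocate_2afc_trials(150, pairs, seed = 11)
  afc <- simulate_2afc(alloc, seed = 12)
  catch <- afc[afc$is_catch, ]
  p_first <- mean(catch$response == "first")
  p_second <- mean(catch$response == "second")
  expect_lt(abs(p_first - p_second), 3 * sqrt(0.5 / nrow(catch)))
  # chaos chosen as larger far more often than none
  cn <- afc[!afc$is_catch &
              ((afc$cond_first == "chaos" & afc$cond_second == "none") |
                 (afc$cond_first == "none" & afc$cond_second == "chaos")), ]
  chose_chaos <- ifelse(cn$cond_first == "chaos",
                        cn$response == "first", cn$response == "second")
  chose_none <- ifelse(cn$cond_first == "none",
                       cn$response == "first", cn$response == "second")
  expect_gt(mean(chose_chaos) - mean(chose_none), 0.2)
  # tie threshold -> infinity: every response is "similar"
  par_inf <- default_cohort_params()
  par_inf$afc$tie_threshold <- 1e9
  shifts <- calibrate_afc_shifts()
  afc_inf <- simulate_2afc(alloc, params = par_inf, seed = 13,
                           shifts = shifts)
  expect_true(all(afc_inf$response == "similar"))
})

test_that("forced-choice calibration hits the configured probability differences", {
  # closed-form marginal check of the calibrated latent sizes
  eff <- default_effect_table()
  par <- default_cohort_params()
  s <- calibrate_afc_shifts(eff, par)
  a <- par$afc
  d1 <- nlpvoice:::.afc_marginal_delta(
    s[["chaos"]], a$tie_threshold,
    sqrt(a$sigma_resid^2 + a$sd_proto_condition^2))
  expect_equal(100 * d1, eff$afc_delta[["chaos_none"]], tolerance = 1e-5)
  d2 <- nlpvoice:::.afc_marginal_delta(
    s[["chaos"]] - s[["am"]], a$tie_threshold,
    sqrt(a$sigma_resid^2 + 2 * a$sd_proto_condition^2))
  expect_equal(100 * d2, eff$afc_delta[["chaos_am"]], tolerance = 1e-5)
})

test_that("implicit-association simulator matches its generative contract", {
  eff0 <- default_effect_table()
  eff0$iat$error_logodds <- 0
  eff0$iat$rt_shift_ms <- 0
  iat0 <- simulate_iat(effects = eff0, seed = 14)
  err <- tapply(!iat0$correct, iat0$congruency, mean)
  expect_lt(abs(log(err[["incongruent"]] / (1 - err[["incongruent"]])) -
                  log(err[["congruent"]] / (1 - err[["congruent"]]))), 0.3)
  rtd <- tapply(iat0$rt_ms, iat0$congruency, mean)
  expect_lt(abs(rtd[["incongruent"]] - rtd[["congruent"]]), 15)
  # positive congruency effects: more errors and longer RTs when incongruent
  iat1 <- simulate_iat(seed = 15)
  err1 <- tapply(!iat1$correct, iat1$congruency, mean)
  expect_gt(err1[["incongruent"]], err1[["congruent"]])
  rt1 <- tapply(iat1$rt_ms, iat1$congruency, mean)
  expect_gt(rt1[["incongruent"]] - rt1[["congruent"]], 50)
  # reproducible under a fixed seed
  expect_identical(simulate_iat(seed = 15), iat1)
  expect_true(all(iat1$rt_ms > 0))
})
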