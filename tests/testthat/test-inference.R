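test_that("rating model recovers the null when no effects are injected", {
  w <- small_rating_world(seed = 200)
  eff0 <- default_effect_table()
  eff0$ratings$effect <- 0
  tr <- simulate_ratings(w$alloc, eff0, seed = 201)
  for (s in c("pitch", "roughness")) {
    est <- fit_rating_model(tr, s, seed = 202)$estimates
    expect_true(all(est$lo <= 0 & est$hi >= 0))
  }
})

test_that("rating model reports contrasts in the stated units with per-prototype spread", {
  w <- small_rating_world(n_part = 60, seed = 210)
  tr <- simulate_ratings(w$alloc, seed = 211)
  f <- fit_rating_model(tr, "pitch", seed = 212)
  expect_equal(f$estimates$units, rep("semitones", 3))
  expect_true(all(f$estimates$lo <= f$estimates$point &
                    f$estimates$point <= f$estimates$hi))
  expect_equal(nrow(f$prototype_effects), 12 * 3)
  fh <- fit_rating_model(tr, "height", seed = 212)
  expect_equal(unique(fh$estimates$units), "cm")
  # a condition missing from the data is an error
  expect_error(fit_rating_model(tr[tr$condition != "chaos", ], "pitch"),
               "conditions")
})

test_that("estimation backends agree on point estimates", {
  skip_if_not_installed("rjags")
  w <- small_rating_world(n_proto = 15, n_part = 50, seed = 220)
  tr <- simulate_ratings(w$alloc, seed = 221)
  fw <- fit_rating_model(tr, "pitch", backend = "wald", seed = 222)
  fb <- fit_rating_model(tr, "pitch", backend = "bootstrap", B = 100,
                         seed = 222)
  fm <- fit_rating_model(tr, "pitch", backend = "mcmc", seed = 222)
  for (i in 1:3) {
    mag <- abs(fw$estimates$point[i])
    expect_lt(abs(fb$estimates$point[i] - fw$estimates$point[i]), 0.1 * mag)
    expect_lt(abs(fm$estimates$point[i] - fw$estimates$point[i]), 0.1 * mag)
  }
})

test_that("ordinal forced-choice model is antisymmetric and null on catch pairs", {
  protos <- generate_prototypes(20, seed = 230)
  pairs <- enumerate_pairs(protos)
  alloc <- allocate_2afc_trials(120, pairs, seed = 231)
  afc <- simulate_2afc(alloc, seed = 232)
  fit <- fit_2afc_model(afc, B = 60, seed = 233)
  est <- fit$estimates
  # swapping presentation labels (responses unchanged) flips the sign
  swapped <- afc
  swapped$cond_first <- afc$cond_second
  swapped$cond_second <- afc$cond_first
  fit_sw <- fit_2afc_model(swapped, B = 0)
  i <- which(est$first == "chaos" & est$second == "none")
  j <- which(fit_sw$estimates$first == "chaos" &
               fit_sw$estimates$second == "none")
  expect_equal(fit_sw$estimates$delta[j], -est$delta[i], tolerance = 0.1)
  # ROPE from catch pairs straddles zero
  expect_lt(fit$rope[1], 0)
  expect_gt(fit$rope[2], 0.0 + 1e-9 - 5) # lower bound negative, upper near/above 0
  expect_true(fit$rope[2] > fit$rope[1])
  # chaos contrast clears the catch-pair noise region
  expect_true(est$cleared_rope[i])
  # without catch trials the ROPE is unavailable
  expect_warning(f2 <- fit_2afc_model(afc[!afc$is_catch, ], B = 0),
                 "catch")
  expect_true(all(is.na(f2$rope)))
})

test_that("implicit-association model recovers null and positive congruency effects", {
  eff0 <- default_effect_table()
  eff0$iat$error_logodds <- 0
  eff0$iat$rt_shift_ms <- 0
  par <- default_cohort_params()
  alloc <- allocate_iat_blocks(60, seed = 240)
  iat0 <- simulate_iat(alloc, eff0, par, seed = 241)
  f0 <- fit_iat_model(iat0, seed = 242)
  pop <- f0[f0$level == "population", ]
  # intervals cover the nulls up to a small sampling slack
  expect_true(pop$or_lo <= 1.05 && pop$or_hi >= 0.95)
  expect_true(pop$rt_lo <= 5 && pop$rt_hi >= -5)
  expect_lt(abs(pop$rt), 15)
  iat1 <- simulate_iat(alloc, seed = 243)
  f1 <- fit_iat_model(iat1, seed = 244)
  pop1 <- f1[f1$level == "population", ]
  expect_gt(pop1$or, 1.5)
  expect_gt(pop1$rt, 50)
  expect_true(pop1$or_excludes_null && pop1$rt_excludes_null)
  # single-block data is rejected
  expect_error(fit_iat_model(iat1[iat1$congruency == "congruent", ]),
               "block")
})

test_that("inter-rater agreement has the correct fixed points", {
  # identical raters: mean r = 1 and ICC ~ 1
  stim_ids <- sprintf("s%02d", 1:20)
  truth <- stats::rnorm(20, 50, 10)
  d <- do.call(rbind, lapply(1:30, function(p) {
    data.frame(participant_id = sprintf("P%02d", p),
               stimulus_id = stim_ids, prototype_id = "x",
               condition = "none", scale = "roughness",
               response = truth, stringsAsFactors = FALSE)
  }))
  ag <- interrater_agreement(d)
  expect_equal(ag$mean_r, 1, tolerance = 1e-6)
  expect_gt(ag$icc, 0.99)
  # independent random responses: mean r near zero (the leave-self-in
  # aggregate inflates it by about 1/sqrt(n_raters))
  set.seed(1)
  d$response <- stats::rnorm(nrow(d), 50, 10)
  ag2 <- interrater_agreement(d)
  expect_lt(abs(ag2$mean_r), 0.3)
  expect_lt(abs(ag2$icc), 0.15)
})

test_that("agreement is higher for low-noise than for high-noise scales", {
  w <- small_rating_world(n_part = 80, seed = 250)
  tr <- simulate_ratings(w$alloc, seed = 251)
  ag <- interrater_agreement(tr)
  mean_psy <- mean(ag$mean_r[ag$scale %in% PSYCHOACOUSTIC_SCALES])
  mean_eco <- mean(ag$mean_r[ag$scale %in% ECOLOGICAL_SCALES])
  expect_gt(mean_psy, mean_eco)
  icc_psy <- mean(ag$icc[ag$scale %in% PSYCHOACOUSTIC_SCALES])
  icc_eco <- mean(ag$icc[ag$scale %in% ECOLOGICAL_SCALES])
  expect_gt(icc_psy, icc_eco)
})

test_that("scale correlations behave under identity and permutation", {
  w <- small_rating_world(n_part = 80, seed = 260)
  tr <- simulate_ratings(w$alloc, seed = 261)
  cm <- scale_correlations(tr)
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_true(all(abs(cm) <= 1 + 1e-9))
  # shared prototype latent: pitch and timbre strongly positively related
  expect_gt(cm["pitch", "timbre"], 0.5)
  # permuting the stimulus ids of one scale destroys its correlations
  tr_perm <- tr
  idx <- tr_perm$scale == "pitch"
  set.seed(262)
  perm <- sample(unique(tr_perm$stimulus_id))
  names(perm) <- unique(tr_perm$stimulus_id)
  tr_perm$stimulus_id[idx] <- perm[tr_perm$stimulus_id[idx]]
  cm_perm <- scale_correlations(tr_perm)
  expect_lt(abs(cm_perm["pitch", "timbre"]), 0.35)
})

test_that("estimates become more precise as the cohort grows", {
  protos <- generate_prototypes(15, seed = 270)
  stim <- build_stimulus_set(protos)
  widths <- vapply(c(30, 120), function(n) {
    alloc <- allocate_rating_trials(n, stim, seed = 271,
                                    stimuli_per_block = 20)
    tr <- simulate_ratings(alloc, seed = 272)
    est <- fit_rating_model(tr, "roughness", seed = 273)$estimates
    mean(est$hi - est$lo)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})
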