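# Synthetic stand-ins for the stimulus corpus and the listener cohorts.
#
# The generator produces prototype vocalizations matching the corpus
# conditions (short intense vocalizations, duration ~ 1 +/- 0.5 s, male and
# female f0 ranges, 1-2 annotated NLP segments, AM rate ~ 90 +/- 20 Hz,
# subharmonic divisors 2/3/4, strong jitter) and simulates listener
# responses for the three experiments around configurable population
# effects, with participant- and prototype-level heterogeneity.

#' Rating scales of the listener experiment
#'
#' Three psychoacoustic scales (pitch, timbre, roughness) and three
#' ecological scales (height, formidability, aggression); each participant
#' rates one block of each kind.
#'
#' @format Character vectors.
#' @export
RATING_SCALES <- c("pitch", "timbre", "roughness",
                   "height", "formidability", "aggression")

#' @rdname RATING_SCALES
#' @export
PSYCHOACOUSTIC_SCALES <- RATING_SCALES[1:3]

#' @rdname RATING_SCALES
#' @export
ECOLOGICAL_SCALES <- RATING_SCALES[4:6]

# Project a symmetric matrix onto the nearest correlation matrix by
# eigenvalue clipping (used to make the partially specified default
# between-scale correlation matrix positive definite).
.make_correlation <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 1e-6)
  m2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(m2))
  out <- m2 / tcrossprod(d)
  dimnames(out) <- dimnames(m)
  out
}

#' Default population effect table
#'
#' The population-level effects of each NLP type relative to the no-NLP
#' condition, used as the generative truth of the listener simulators.
#' Rating effects are in model units: semitones for pitch (negative =
#' perceived lower), cm for height, percentage points for the 0-100 scales
#' (timbre is coded as brightness, so darkening is negative).  The
#' two-alternative forced-choice block holds target probability differences
#' Delta = P(first larger) - P(first smaller) in percent for the chaos
#' contrasts; the implicit-association block holds the congruency shift on
#' the error log-odds and the response-time shift in ms.
#'
#' @return A list with elements `ratings` (data.frame scale/condition/effect),
#'   `afc_delta` (named vector, percent), `iat` (list), and `proto_cor`
#'   (6x6 between-scale correlation of prototype intercepts).
#' @export
default_effect_table <- function() {
  ratings <- data.frame(
    scale = rep(RATING_SCALES, each = 3),
    condition = rep(c("am", "subharmonics", "chaos"), times = 6),
    effect = c(
      -2.2, -2.8, -4.2,     # pitch, semitones
      -5.3, -6.1, -11.2,    # timbre brightness, pp (negative = darker)
      13.8, 10.5, 23.6,     # roughness, pp
      2.5, 2.2, 1.8,        # height, cm
      4.2, 4.3, 13.0,       # formidability, pp
      8.0, 4.7, 19.4        # aggression, pp
    ),
    stringsAsFactors = FALSE
  )
  # Between-scale correlation of prototype intercepts.  Values off the
  # pitch/timbre/roughness/height grid are plausible fillers (ecological
  # scales track roughness positively and pitch/brightness negatively);
  # the matrix is projected to the nearest correlation matrix.
  m <- diag(6)
  dimnames(m) <- list(RATING_SCALES, RATING_SCALES)
  set_pair <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set_pair("pitch", "timbre", 0.94)
  set_pair("pitch", "roughness", -0.69)
  set_pair("timbre", "roughness", -0.78)
  set_pair("aggression", "formidability", 0.70)
  set_pair("height", "formidability", 0.47)
  set_pair("height", "pitch", 0.31)
  set_pair("height", "timbre", 0.28)
  set_pair("height", "roughness", -0.10)
  set_pair("formidability", "pitch", -0.35)
  set_pair("formidability", "timbre", -0.40)
  set_pair("formidability", "roughness", 0.50)
  set_pair("aggression", "pitch", -0.45)
  set_pair("aggression", "timbre", -0.50)
  set_pair("aggression", "roughness", 0.65)
  list(
    ratings = ratings,
    afc_delta = c(chaos_none = 38.0, chaos_am = 29.3,
                  chaos_subharmonics = 24.9),
    iat = list(error_logodds = 0.8, rt_shift_ms = 100),
    proto_cor = .make_correlation(m)
  )
}

#' Default cohort and heterogeneity parameters
#'
#' Sample sizes of the three experiments (301 raters, 192 forced-choice
#' listeners after exclusions, 184 implicit-association participants),
#' per-scale baselines and variance components of the rating model,
#' forced-choice latent-noise and tie-threshold settings, response-time
#' distribution parameters, and the distributions from which prototype
#' acoustics are drawn.  Pitch is parameterized in semitones above the
#' low end of the response slider (62 Hz); its bounds correspond to the
#' 62-4300 Hz slider span.  All values are configuration defaults exposed
#' to the user.
#'
#' @return A nested list of parameters.
#' @export
default_cohort_params <- function() {
  list(
    n_rating = 301L,
    n_2afc = 192L,
    n_iat = 184L,
    pitch_ref_hz = 62,
    # Variance components per scale, chosen so that simulated inter-rater
    # agreement reproduces the study's pattern: psychoacoustic scales
    # (low-level, consistently perceived) have small residual noise and
    # high stimulus-level variance, ecological scales (speaker inferences)
    # have large rater and residual variance.
    scales = data.frame(
      scale = RATING_SCALES,
      baseline = c(38, 50, 35, 166, 40, 35),
      sd_participant = c(3.5, 6, 8, 6, 11, 11),
      sd_prototype = c(6, 8, 8, 4.5, 6, 5),
      sd_proto_condition = c(1.5, 4, 4, 1.5, 4, 4),
      sd_resid = c(4, 8, 9, 8, 14, 15),
      lo = c(0, 0, 0, 128, 0, 0),
      hi = c(12 * log2(4300 / 62), 100, 100, 202, 100, 100),
      stringsAsFactors = FALSE
    ),
    afc = list(sigma_resid = 1, sd_proto_condition = 0.3,
               tie_threshold = 0.27),
    iat = list(trials_per_block = 40L, baseline_error = 0.06,
               sd_participant_error = 0.5, rt_median_ms = 600,
               rt_sdlog = 0.25, sd_participant_rt = 0.12),
    prototypes = list(
      # symmetric truncation keeps the mean duration at exactly 1 s
      duration_mean = 1, duration_sd = 0.5, duration_min = 0.3,
      duration_max = 1.7,
      f0_range_m = c(150, 350), f0_range_f = c(250, 550),
      contour_sd_semitones = 2,
      am_freq_mean = 90, am_freq_sd = 20, am_freq_range = c(30, 150),
      am_depth_range = c(0.3, 0.9),
      sub_divisor_prob = c(`2` = 0.5, `3` = 0.3, `4` = 0.2),
      sub_depth_range = c(0.3, 0.9),
      jitter_depth_range = c(4, 8), jitter_period = 0.010,
      segment_coverage = c(0.4, 0.8)
    )
  )
}

# Truncated-normal draw by rejection (small n; bounds well within 3 sd).
.rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate synthetic prototype vocalizations
#'
#' Stands in for the corpus of 82 short intense vocalizations: durations
#' are drawn from a normal distribution (mean 1 s, sd 0.5 s) truncated at
#' 0.3 s; f0 contours have sex-dependent ranges and smooth random shapes;
#' each prototype carries 1-2 annotated NLP segments jointly covering at
#' least 30% of its duration, plus per-prototype NLP parameters (AM rate
#' ~ 90 +/- 20 Hz, subharmonic divisor 2/3/4, strong jitter).
#'
#' @param n Number of prototypes (default 82).
#' @param seed Integer seed.
#' @param params Prototype block of [default_cohort_params()].
#' @return A list of [prototype()] objects.
#' @export
generate_prototypes <- function(n = 82, seed = NULL,
                                params = default_cohort_params()$prototypes) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sex <- sample(c("M", "F"), 1)
      dur <- .rnorm_trunc(1, params$duration_mean, params$duration_sd,
                          lo = params$duration_min,
                          hi = if (is.null(params$duration_max)) Inf else params$duration_max)
      n_frames <- max(3L, round(dur / 0.010))
      dur <- n_frames * 0.010 # snap to the contour frame grid
      f0r <- if (sex == "M") params$f0_range_m else params$f0_range_f
      f0_base <- exp(stats::runif(1, log(f0r[1]), log(f0r[2])))
      # smooth random contour shape: spline through a few random knots
      k <- 4
      knots <- stats::rnorm(k, 0, params$contour_sd_semitones)
      shape <- stats::spline(seq(0, 1, length.out = k), knots,
                             xout = seq(0, 1, length.out = n_frames))$y
      contour <- pitch_contour(f0_base * 2^(shape / 12),
                               voiced = rep(TRUE, n_frames))
      scale_vt <- if (sex == "M") 1 else 1.15
      ff <- c(500, 1500, 2500, 3500) * scale_vt * exp(stats::rnorm(4, 0, 0.06))
      envelope <- formant_envelope(ff, bw = 80 + 0.06 * ff,
                                   amp_db = c(0, -3, -6, -9))
      # 1-2 segments covering a configured fraction of the duration
      n_seg <- sample(1:2, 1)
      cov <- stats::runif(1, params$segment_coverage[1],
                          params$segment_coverage[2]) * dur
      ann_type <- sample(NLP_TYPES, 1)
      segments <- if (n_seg == 1) {
        start <- stats::runif(1, 0, dur - cov)
        list(nlp_segment(ann_type, start, start + cov))
      } else {
        half <- cov / 2
        s1 <- stats::runif(1, 0, dur / 2 - half)
        s2 <- stats::runif(1, dur / 2, dur - half)
        list(nlp_segment(ann_type, s1, s1 + half),
             nlp_segment(ann_type, s2, s2 + half))
      }
      nlp_params <- list(
        am = am_params(
          .rnorm_trunc(1, params$am_freq_mean, params$am_freq_sd,
                       params$am_freq_range[1], params$am_freq_range[2]),
          stats::runif(1, params$am_depth_range[1], params$am_depth_range[2])
        ),
        subharmonics = subharmonic_params(
          as.integer(sample(names(params$sub_divisor_prob), 1,
                            prob = params$sub_divisor_prob)),
          stats::runif(1, params$sub_depth_range[1], params$sub_depth_range[2])
        ),
        chaos = chaos_params(
          stats::runif(1, params$jitter_depth_range[1],
                       params$jitter_depth_range[2]),
          params$jitter_period
        )
      )
      prototype(sprintf("proto_%03d", i), sex, contour, envelope,
                segments, nlp_params)
    })
  })
}

# Effect lookup matrix (scales x conditions, none = 0).
.effect_matrix <- function(effects) {
  m <- matrix(0, nrow = length(RATING_SCALES), ncol = length(CONDITIONS),
              dimnames = list(RATING_SCALES, CONDITIONS))
  r <- effects$ratings
  m[cbind(r$scale, r$condition)] <- r$effect
  m
}

#' Simulate the rating experiment
#'
#' For every allocated trial the latent response is
#' `baseline(scale) + prototype intercept + condition effect +
#' per-prototype condition deviation + participant intercept + residual`,
#' clipped into the scale bounds (visual-analogue sliders truncate).
#' Prototype intercepts are correlated across scales according to
#' `effects$proto_cor`.  Pitch is simulated in semitones and stored as the
#' slider value in Hz (62-4300, log scale).
#'
#' @param allocation Trial allocation from [allocate_rating_trials()].
#' @param effects Effect table, see [default_effect_table()].
#' @param params Cohort parameters, see [default_cohort_params()].
#' @param seed Integer seed.
#' @return Long-format data.frame of rating trials: `participant_id`,
#'   `stimulus_id`, `prototype_id`, `condition`, `scale`, `response`.
#' @export
simulate_ratings <- function(allocation, effects = default_effect_table(),
                             params = default_cohort_params(), seed = NULL) {
  stopifnot(all(c("participant_id", "stimulus_id", "prototype_id",
                  "condition", "scale") %in% names(allocation)))
  if (!all(allocation$scale %in% RATING_SCALES)) {
    stop("unknown rating scale in allocation")
  }
  with_seed(seed, {
    sc <- params$scales
    rownames(sc) <- sc$scale
    eff <- .effect_matrix(effects)
    protos <- sort(unique(allocation$prototype_id))
    np <- length(protos)
    # correlated prototype intercepts (np x 6), unit variance then scaled
    L <- chol(effects$proto_cor[RATING_SCALES, RATING_SCALES])
    z <- matrix(stats::rnorm(np * 6), np, 6) %*% L
    proto_int <- sweep(z, 2, sc[RATING_SCALES, "sd_prototype"], `*`)
    dimnames(proto_int) <- list(protos, RATING_SCALES)
    # per-prototype condition deviations (none = 0), independent per scale
    dev <- array(stats::rnorm(np * 3 * 6), dim = c(np, 3, 6),
                 dimnames = list(protos, NLP_TYPES, RATING_SCALES))
    for (s in RATING_SCALES) dev[, , s] <- dev[, , s] * sc[s, "sd_proto_condition"]
    # participant intercepts per (participant, scale) actually rated
    ps <- unique(allocation[, c("participant_id", "scale")])
    ps$intercept <- stats::rnorm(nrow(ps)) *
      sc[ps$scale, "sd_participant"]
    key <- function(p, s) paste(p, s, sep = "\r")
    part_int <- stats::setNames(ps$intercept, key(ps$participant_id, ps$scale))

    i_proto <- match(allocation$prototype_id, protos)
    i_scale <- match(allocation$scale, RATING_SCALES)
    cond_eff <- eff[cbind(allocation$scale, allocation$condition)]
    dev_trial <- ifelse(
      allocation$condition == "none", 0,
      dev[cbind(i_proto, match(allocation$condition, NLP_TYPES), i_scale)]
    )
    latent <- sc[allocation$scale, "baseline"] +
      proto_int[cbind(i_proto, i_scale)] +
      cond_eff + dev_trial +
      part_int[key(allocation$participant_id, allocation$scale)] +
      stats::rnorm(nrow(allocation)) * sc[allocation$scale, "sd_resid"]
    latent <- pmax(sc[allocation$scale, "lo"],
                   pmin(sc[allocation$scale, "hi"], latent))
    response <- ifelse(allocation$scale == "pitch",
                       semitones_to_hz(latent, params$pitch_ref_hz),
                       latent)
    data.frame(
      participant_id = allocation$participant_id,
      stimulus_id = allocation$stimulus_id,
      prototype_id = allocation$prototype_id,
      condition = allocation$condition,
      scale = allocation$scale,
      response = as.numeric(response),
      stringsAsFactors = FALSE
    )
  })
}

# Marginal Delta = P(first larger) - P(first smaller) for a latent size
# difference delta, tie threshold tau and total latent sd sigma.
.afc_marginal_delta <- function(delta, tau, sigma) {
  stats::pnorm((delta - tau) / sigma) - stats::pnorm(-(delta + tau) / sigma)
}

#' Calibrate latent condition sizes for the forced-choice simulator
#'
#' Inverts the configured target probability differences (percent) for the
#' three chaos contrasts into latent condition sizes on the comparison
#' scale, accounting for the tie threshold and for prototype-level
#' heterogeneity.  The no-NLP condition is the zero reference; AM and
#' subharmonic sizes follow from the chaos-vs-AM and chaos-vs-subharmonics
#' targets.
#'
#' @param effects Effect table with `afc_delta` in percent.
#' @param params Cohort parameters (uses the `afc` block).
#' @return Named numeric vector of latent sizes for all four conditions.
#' @export
calibrate_afc_shifts <- function(effects = default_effect_table(),
                                 params = default_cohort_params()) {
  a <- params$afc
  solve_delta <- function(target_pct, n_nlp_in_pair) {
    sigma <- sqrt(a$sigma_resid^2 + n_nlp_in_pair * a$sd_proto_condition^2)
    stats::uniroot(function(d) {
      .afc_marginal_delta(d, a$tie_threshold, sigma) - target_pct / 100
    }, c(0, 50), tol = 1e-10)$root
  }
  s_chaos <- solve_delta(effects$afc_delta[["chaos_none"]], 1)
  s_am <- s_chaos - solve_delta(effects$afc_delta[["chaos_am"]], 2)
  s_sub <- s_chaos - solve_delta(effects$afc_delta[["chaos_subharmonics"]], 2)
  c(none = 0, am = s_am, subharmonics = s_sub, chaos = s_chaos)
}

#' Simulate the two-alternative forced-choice experiment
#'
#' Each trial compares two versions of the same prototype.  The latent size
#' difference is `size(first) - size(second)` plus per-prototype condition
#' deviations and Gaussian noise; responses within the tie threshold are
#' "similar".  Catch pairs (identical stimuli) have exactly zero latent
#' difference.
#'
#' @param allocation Allocation from [allocate_2afc_trials()].
#' @param effects Effect table (uses `afc_delta`).
#' @param params Cohort parameters (uses the `afc` block).
#' @param seed Integer seed.
#' @param shifts Optional named vector of latent condition sizes (as from
#'   [calibrate_afc_shifts()]); by default calibrated from `effects`.
#' @return The allocation with a `response` column in
#'   `{"first", "similar", "second"}`.
#' @export
simulate_2afc <- function(allocation, effects = default_effect_table(),
                          params = default_cohort_params(), seed = NULL,
                          shifts = NULL) {
  stopifnot(all(c("participant_id", "prototype_id", "cond_first",
                  "cond_second", "is_catch") %in% names(allocation)))
  with_seed(seed, {
    a <- params$afc
    s <- if (is.null(shifts)) calibrate_afc_shifts(effects, params) else shifts
    protos <- sort(unique(allocation$prototype_id))
    w <- matrix(0, length(protos), length(CONDITIONS),
                dimnames = list(protos, CONDITIONS))
    w[, NLP_TYPES] <- stats::rnorm(length(protos) * 3) * a$sd_proto_condition
    i_proto <- match(allocation$prototype_id, protos)
    latent <- (s[allocation$cond_first] + w[cbind(i_proto, match(allocation$cond_first, CONDITIONS))]) -
      (s[allocation$cond_second] + w[cbind(i_proto, match(allocation$cond_second, CONDITIONS))]) +
      stats::rnorm(nrow(allocation)) * a$sigma_resid
    allocation$response <- ifelse(latent > a$tie_threshold, "first",
                                  ifelse(latent < -a$tie_threshold,
                                         "second", "similar"))
    allocation
  })
}

#' Simulate the implicit-association experiment
#'
#' Six sound pairs (two per NLP type), each judged by its own group of
#' participants in one congruent and one incongruent block.  Errors follow
#' a logistic model with a participant intercept and a congruency shift on
#' the log-odds; response times are lognormal with a participant intercept
#' on the log-median and an additive congruency shift (ms) in the
#' incongruent block.
#'
#' @param allocation Participant-to-pair allocation from
#'   [allocate_iat_blocks()]; defaults to the study-size allocation.
#' @param effects Effect table (uses the `iat` block).
#' @param params Cohort parameters (uses the `iat` block).
#' @param seed Integer seed.
#' @return Long-format data.frame of trials: `participant_id`,
#'   `sound_pair`, `nlp_type`, `block`, `congruency`, `trial`, `correct`,
#'   `rt_ms`.
#' @export
simulate_iat <- function(allocation = NULL,
                         effects = default_effect_table(),
                         params = default_cohort_params(), seed = NULL) {
  with_seed(seed, {
    if (is.null(allocation)) {
      allocation <- allocate_iat_blocks(params$n_iat)
    }
    it <- params$iat
    nt <- it$trials_per_block
    rows <- lapply(seq_len(nrow(allocation)), function(i) {
      p <- allocation[i, ]
      u_err <- stats::rnorm(1, 0, it$sd_participant_error)
      u_rt <- stats::rnorm(1, 0, it$sd_participant_rt)
      blocks <- if (p$first_block == "congruent") {
        c("congruent", "incongruent")
      } else {
        c("incongruent", "congruent")
      }
      cong <- rep(blocks, each = nt)
      incong <- as.numeric(cong == "incongruent")
      p_err <- stats::plogis(stats::qlogis(it$baseline_error) + u_err +
                               effects$iat$error_logodds * incong)
      err <- stats::rbinom(2 * nt, 1, p_err)
      rt <- stats::rlnorm(2 * nt, log(it$rt_median_ms) + u_rt, it$rt_sdlog) +
        effects$iat$rt_shift_ms * incong
      data.frame(
        participant_id = p$participant_id,
        sound_pair = p$sound_pair,
        nlp_type = p$nlp_type,
        block = rep(1:2, each = nt),
        congruency = cong,
        trial = seq_len(2 * nt),
        correct = err == 0,
        rt_ms = rt,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
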