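# Estimation of NLP effects from trial tables.
#
# The rating model is a Gaussian multilevel model with fixed condition
# effects and random intercepts for participants, prototypes and
# prototype-by-condition cells; pitch responses are modelled in semitones
# (log-Hz).  Uncertainty is summarized as median + 95% interval from one of
# three backends with a common contract: "wald" (draws from the asymptotic
# Gaussian distribution of the fixed effects; default), "bootstrap"
# (parametric bootstrap with model refits) and "mcmc" (Gibbs sampling via
# JAGS with weakly informative priors).

NLP_CONTRASTS <- c("am", "subharmonics", "chaos")

.scale_units <- function(scale) {
  switch(scale, pitch = "semitones", height = "cm", "percentage points")
}

# Response on the modelling scale: semitones above the slider's low end for
# pitch, raw slider units otherwise.
.model_response <- function(trials, scale, pitch_ref_hz = 62) {
  if (scale == "pitch") {
    hz_to_semitones(trials$response, pitch_ref_hz)
  } else {
    trials$response
  }
}

.jags_rating_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(b0 + beta[cond[i]] + u[part[i]] + v[proto[i]] + w[pc[i]],
                 tau_e)
  }
  beta[1] <- 0
  for (c in 2:4) { beta[c] ~ dnorm(0, 1.0E-4) }
  b0 ~ dnorm(0, 1.0E-6)
  for (j in 1:Npart) { u[j] ~ dnorm(0, tau_u) }
  for (j in 1:Nproto) { v[j] ~ dnorm(0, tau_v) }
  for (j in 1:Npc) { w[j] ~ dnorm(0, tau_w) }
  sd_u ~ dunif(0, 100); tau_u <- pow(sd_u, -2)
  sd_v ~ dunif(0, 100); tau_v <- pow(sd_v, -2)
  sd_w ~ dunif(0, 100); tau_w <- pow(sd_w, -2)
  sd_e ~ dunif(0, 100); tau_e <- pow(sd_e, -2)
}"

.mcmc_rating_draws <- function(data, n_iter = 2000, n_burn = 500,
                               seed = NULL) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("the 'mcmc' backend requires the rjags package")
  }
  jd <- list(
    y = data$y, N = nrow(data),
    cond = as.integer(factor(data$condition, levels = CONDITIONS)),
    part = as.integer(factor(data$participant_id)),
    proto = as.integer(factor(data$prototype_id)),
    pc = as.integer(factor(data$pc)),
    Npart = length(unique(data$participant_id)),
    Nproto = length(unique(data$prototype_id)),
    Npc = length(unique(data$pc))
  )
  inits <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = if (is.null(seed)) 1L else as.integer(seed))
  m <- rjags::jags.model(textConnection(.jags_rating_model), data = jd,
                         inits = inits, n.chains = 1, n.adapt = n_burn,
                         quiet = TRUE)
  update(m, n_burn, progress.bar = "none")
  s <- rjags::coda.samples(m, "beta", n.iter = n_iter,
                           progress.bar = "none")[[1]]
  draws <- as.matrix(s)[, c("beta[2]", "beta[3]", "beta[4]")]
  colnames(draws) <- NLP_CONTRASTS
  draws
}

#' Fit the multilevel rating model for one scale
#'
#' Estimates the effect of each NLP type relative to the no-NLP condition
#' from trial-level rating data, with participant intercepts, prototype
#' intercepts and prototype-by-condition deviations as random effects.
#' Pitch contrasts are reported in semitones (responses are log-transformed
#' before modelling), height in cm, the 0-100 scales in percentage points.
#' Also returns the per-prototype fitted contrasts (the spread of the
#' effect over individual prototype vocalizations).
#'
#' @param trials Long-format rating trial table (see [simulate_ratings()]).
#' @param scale One of the six rating scales.
#' @param backend `"wald"` (default), `"bootstrap"` or `"mcmc"`.
#' @param ndraws Number of draws for the wald backend (default 1000).
#' @param B Number of refits for the bootstrap backend (default 200).
#' @param seed Seed for the draw stage.
#' @param pitch_ref_hz Low end of the pitch slider in Hz (default 62).
#' @return A list with `estimates` (data.frame: scale, contrast, point,
#'   lo, hi, units, backend), `prototype_effects` (per-prototype fitted
#'   contrasts) and `model` (the lme4 fit).
#' @export
fit_rating_model <- function(trials, scale,
                             backend = c("wald", "bootstrap", "mcmc"),
                             ndraws = 1000, B = 200, seed = NULL,
                             pitch_ref_hz = 62) {
  backend <- match.arg(backend)
  scale <- match.arg(scale, RATING_SCALES)
  d <- trials[trials$scale == scale, , drop = FALSE]
  if (!all(CONDITIONS %in% d$condition)) {
    stop("all four conditions must be present in the data for scale ", scale)
  }
  d$y <- .model_response(d, scale, pitch_ref_hz)
  d$condition <- factor(d$condition, levels = CONDITIONS)
  d$pc <- paste(d$prototype_id, d$condition, sep = "|")
  fit <- lme4::lmer(
    y ~ condition + (1 | participant_id) + (1 | prototype_id) + (1 | pc),
    data = d, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  )
  keep <- paste0("condition", NLP_CONTRASTS)
  draws <- with_seed(seed, switch(
    backend,
    wald = {
      beta <- lme4::fixef(fit)[keep]
      V <- as.matrix(stats::vcov(fit))[keep, keep]
      dr <- MASS::mvrnorm(ndraws, beta, V)
      colnames(dr) <- NLP_CONTRASTS
      dr
    },
    bootstrap = {
      sims <- stats::simulate(fit, nsim = B)
      dr <- t(vapply(seq_len(B), function(b) {
        # refits of simulated responses may hit variance boundaries;
        # that is expected across bootstrap replicates
        lme4::fixef(suppressMessages(lme4::refit(fit, sims[[b]])))[keep]
      }, numeric(length(keep))))
      colnames(dr) <- NLP_CONTRASTS
      dr
    },
    mcmc = .mcmc_rating_draws(d, seed = seed)
  ))
  est <- data.frame(
    scale = scale,
    contrast = NLP_CONTRASTS,
    point = apply(draws, 2, stats::median),
    lo = apply(draws, 2, stats::quantile, 0.025),
    hi = apply(draws, 2, stats::quantile, 0.975),
    units = .scale_units(scale),
    backend = backend,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  # per-prototype fitted contrasts: fixed effect + (pc deviation - none
  # deviation) for each prototype
  re <- lme4::ranef(fit)$pc
  pc_dev <- stats::setNames(re[[1]], rownames(re))
  protos <- sort(unique(d$prototype_id))
  proto_eff <- do.call(rbind, lapply(NLP_CONTRASTS, function(cc) {
    dev_c <- pc_dev[paste(protos, cc, sep = "|")]
    dev_0 <- pc_dev[paste(protos, "none", sep = "|")]
    dev_c[is.na(dev_c)] <- 0
    dev_0[is.na(dev_0)] <- 0
    data.frame(scale = scale, prototype_id = protos, contrast = cc,
               effect = lme4::fixef(fit)[paste0("condition", cc)] +
                 dev_c - dev_0,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(scale = scale, estimates = est, prototype_effects = proto_eff,
       model = fit)
}

#' Fit all six rating scales
#'
#' @param trials Rating trial table covering all scales.
#' @param ... Passed to [fit_rating_model()].
#' @return data.frame of effect estimates, 6 scales x 3 contrasts.
#' @export
fit_all_rating_models <- function(trials, ...) {
  do.call(rbind, lapply(intersect(RATING_SCALES, unique(trials$scale)),
                        function(s) fit_rating_model(trials, s, ...)$estimates))
}

# Delta = P(first larger) - P(first smaller) for a three-category ordinal
# probit model with thresholds z1 < z2 and linear predictor eta.
.ordinal_delta <- function(eta, z1, z2) {
  (1 - stats::pnorm(z2 - eta)) - stats::pnorm(z1 - eta)
}

.afc_design <- function(trials) {
  d <- data.frame(
    response = factor(trials$response,
                      levels = c("second", "similar", "first"),
                      ordered = TRUE),
    participant_id = trials$participant_id,
    stringsAsFactors = FALSE
  )
  for (cc in NLP_CONTRASTS) {
    d[[paste0("x_", cc)]] <- as.numeric(trials$cond_first == cc) -
      as.numeric(trials$cond_second == cc)
  }
  d
}

.afc_fit_once <- function(d) {
  fit <- MASS::polr(response ~ x_am + x_subharmonics + x_chaos, data = d,
                    method = "probit", Hess = FALSE)
  s <- c(none = 0, fit$coefficients)
  names(s) <- c("none", NLP_CONTRASTS)
  list(s = s, zeta = fit$zeta)
}

#' Fit the three-category ordinal model to forced-choice data
#'
#' Models the response (first taller / similar / second taller) as an
#' ordinal probit regression on signed condition indicators, so that one
#' latent size parameter per condition (no-NLP = 0) drives all contrasts.
#' Reports, for each ordered contrast, the fitted probability of perceiving
#' the first vocalization as larger minus the probability of perceiving it
#' as smaller (ignoring ties), in percent.  Intervals come from a cluster
#' bootstrap over participants, which also propagates listener
#' heterogeneity.  The region of practical equivalence (ROPE) is the
#' central 95% interval of the same quantity evaluated for catch pairs of
#' identical stimuli; contrasts whose interval fails to clear the ROPE are
#' flagged as not distinguishable from the catch-pair noise level.
#'
#' @param trials Forced-choice trial table incl. catch trials (see
#'   [simulate_2afc()]).
#' @param B Cluster-bootstrap replicates (default 200); `B = 0` skips
#'   interval estimation (point estimates only).
#' @param seed Seed for the bootstrap.
#' @return A list with `estimates` (data.frame: first, second, delta, lo,
#'   hi in percent, cleared_rope) and `rope` (interval in percent).
#' @export
fit_2afc_model <- function(trials, B = 200, seed = NULL) {
  d <- .afc_design(trials)
  fit0 <- .afc_fit_once(d)
  contrasts <- data.frame(
    first = c("chaos", "chaos", "chaos", "subharmonics", "am", "subharmonics"),
    second = c("none", "am", "subharmonics", "none", "none", "am"),
    stringsAsFactors = FALSE
  )
  delta_of <- function(par) {
    vapply(seq_len(nrow(contrasts)), function(i) {
      eta <- par$s[contrasts$first[i]] - par$s[contrasts$second[i]]
      100 * .ordinal_delta(eta, par$zeta[1], par$zeta[2])
    }, numeric(1))
  }
  point <- delta_of(fit0)
  has_catch <- any(trials$is_catch)
  if (!has_catch) {
    warning("no catch trials: ROPE unavailable")
  }
  lo <- hi <- rep(NA_real_, nrow(contrasts))
  rope <- c(NA_real_, NA_real_)
  cleared <- rep(NA, nrow(contrasts))
  if (B > 0) {
    parts <- unique(d$participant_id)
    split_idx <- split(seq_len(nrow(d)), d$participant_id)
    boot <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        take <- sample(parts, length(parts), replace = TRUE)
        db <- d[unlist(split_idx[take], use.names = FALSE), , drop = FALSE]
        par <- .afc_fit_once(db)
        c(delta_of(par),
          100 * .ordinal_delta(0, par$zeta[1], par$zeta[2]))
      }, numeric(nrow(contrasts) + 1))
    })
    lo <- apply(boot[seq_len(nrow(contrasts)), , drop = FALSE], 1,
                stats::quantile, 0.025)
    hi <- apply(boot[seq_len(nrow(contrasts)), , drop = FALSE], 1,
                stats::quantile, 0.975)
    if (has_catch) {
      rope <- stats::quantile(boot[nrow(contrasts) + 1, ], c(0.025, 0.975))
      cleared <- lo > rope[2] | hi < rope[1]
    }
  }
  list(
    estimates = data.frame(contrasts, delta = point, lo = lo, hi = hi,
                           cleared_rope = cleared, stringsAsFactors = FALSE,
                           row.names = NULL),
    rope = unname(rope)
  )
}

.wald_interval_draws <- function(beta, V, ndraws) {
  MASS::mvrnorm(ndraws, beta, V)
}

#' Fit the implicit-association congruency models
#'
#' Errors: logistic multilevel model (participant intercepts) with a
#' congruency term; reported as the odds ratio of an error in incongruent
#' versus congruent blocks.  Response times: Gaussian multilevel location
#' model on RT in ms with a congruency shift.  Both are fit per sound pair
#' and at population level (adding a sound-pair intercept), and each
#' interval is flagged if it fails to exclude the null (odds ratio 1, RT
#' shift 0).
#'
#' @param trials Trial table from [simulate_iat()].
#' @param ndraws Draws for interval construction (default 1000).
#' @param seed Seed for the draw stage.
#' @return data.frame with one row per sound pair plus `"population"`:
#'   odds-ratio and RT-shift medians, 95% intervals and null-exclusion
#'   flags.
#' @export
fit_iat_model <- function(trials, ndraws = 1000, seed = NULL) {
  if (length(unique(trials$congruency)) < 2) {
    stop("both congruent and incongruent blocks are required")
  }
  trials$error <- as.numeric(!trials$correct)
  trials$incong <- as.numeric(trials$congruency == "incongruent")
  fit_level <- function(d, population = FALSE) {
    err_form <- if (population) {
      error ~ incong + (1 | participant_id) + (1 | sound_pair)
    } else {
      error ~ incong + (1 | participant_id)
    }
    rt_form <- if (population) {
      rt_ms ~ incong + (1 | participant_id) + (1 | sound_pair)
    } else {
      rt_ms ~ incong + (1 | participant_id)
    }
    gm <- suppressMessages(lme4::glmer(err_form, data = d, family = stats::binomial))
    lm_rt <- lme4::lmer(rt_form, data = d,
                        control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))
    or_draws <- exp(stats::rnorm(ndraws, lme4::fixef(gm)["incong"],
                                 sqrt(stats::vcov(gm)["incong", "incong"])))
    rt_draws <- stats::rnorm(ndraws, lme4::fixef(lm_rt)["incong"],
                             sqrt(as.matrix(stats::vcov(lm_rt))["incong", "incong"]))
    c(or = stats::median(or_draws),
      or_lo = unname(stats::quantile(or_draws, 0.025)),
      or_hi = unname(stats::quantile(or_draws, 0.975)),
      rt = stats::median(rt_draws),
      rt_lo = unname(stats::quantile(rt_draws, 0.025)),
      rt_hi = unname(stats::quantile(rt_draws, 0.975)))
  }
  with_seed(seed, {
    pairs <- sort(unique(trials$sound_pair))
    rows <- lapply(pairs, function(sp) {
      fit_level(trials[trials$sound_pair == sp, , drop = FALSE])
    })
    rows <- c(rows, list(fit_level(trials, population = TRUE)))
    out <- as.data.frame(do.call(rbind, rows))
    out$level <- c(pairs, "population")
    out$or_excludes_null <- out$or_lo > 1 | out$or_hi < 1
    out$rt_excludes_null <- out$rt_lo > 0 | out$rt_hi < 0
    out[, c("level", "or", "or_lo", "or_hi", "or_excludes_null",
            "rt", "rt_lo", "rt_hi", "rt_excludes_null")]
  })
}

#' Inter-rater agreement of the rating experiment
#'
#' For each scale: the mean Pearson correlation between each participant's
#' responses and the per-stimulus aggregated (mean) ratings, and the
#' intraclass correlation coefficient for absolute agreement under a
#' two-way random-effects decomposition (stimulus + rater + error variance
#' components, estimated by a crossed mixed model, which accommodates the
#' incomplete rating design).  Raters with fewer than `min_shared` trials
#' on a scale or zero response variance are excluded (with a message).
#'
#' @param trials Rating trial table.
#' @param min_shared Minimum trials per rater to enter the mean-r (default 3).
#' @param pitch_ref_hz Pitch slider low end in Hz.
#' @return data.frame with `scale`, `mean_r`, `icc`, `n_raters`,
#'   `n_excluded`.
#' @export
interrater_agreement <- function(trials, min_shared = 3, pitch_ref_hz = 62) {
  out <- lapply(intersect(RATING_SCALES, unique(trials$scale)), function(s) {
    d <- trials[trials$scale == s, , drop = FALSE]
    d$y <- .model_response(d, s, pitch_ref_hz)
    agg <- tapply(d$y, d$stimulus_id, mean)
    rs <- vapply(split(d, d$participant_id), function(dp) {
      if (nrow(dp) < min_shared) return(NA_real_)
      if (stats::sd(dp$y) < 1e-12) return(NA_real_)
      a <- agg[dp$stimulus_id]
      if (stats::sd(a) < 1e-12) return(NA_real_)
      stats::cor(dp$y, a)
    }, numeric(1))
    n_excl <- sum(is.na(rs))
    if (n_excl > 0) {
      message(n_excl, " rater(s) excluded from mean-r on scale ", s,
              " (too few trials or zero variance)")
    }
    icc <- tryCatch({
      # degenerate inputs (e.g. zero residual variance) are legitimate
      # fixed points here; optimizer roundoff warnings are expected there
      m <- suppressWarnings(
        lme4::lmer(y ~ 1 + (1 | stimulus_id) + (1 | participant_id),
                      data = d,
                      control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))))
      vc <- as.data.frame(lme4::VarCorr(m))
      v <- stats::setNames(vc$vcov, vc$grp)
      unname(v["stimulus_id"] /
               (v["stimulus_id"] + v["participant_id"] + v["Residual"]))
    }, error = function(e) NA_real_)
    data.frame(scale = s, mean_r = mean(rs, na.rm = TRUE), icc = icc,
               n_raters = sum(!is.na(rs)), n_excluded = n_excl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlations between scales over per-stimulus mean ratings
#'
#' Pearson correlations of the per-stimulus average ratings between
#' scales (pitch averaged in semitones).  A scale with (near-)constant
#' stimulus means yields `NA` entries and a warning.
#'
#' @param trials Rating trial table.
#' @param pitch_ref_hz Pitch slider low end in Hz.
#' @return Correlation matrix over the scales present.
#' @export
scale_correlations <- function(trials, pitch_ref_hz = 62) {
  scales <- intersect(RATING_SCALES, unique(trials$scale))
  stim <- sort(unique(trials$stimulus_id))
  m <- sapply(scales, function(s) {
    d <- trials[trials$scale == s, , drop = FALSE]
    d$y <- .model_response(d, s, pitch_ref_hz)
    agg <- tapply(d$y, d$stimulus_id, mean)
    agg[stim]
  })
  const <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) < 1e-12)
  if (any(const)) {
    warning("constant per-stimulus means on scale(s): ",
            paste(scales[const], collapse = ", "))
  }
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}
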