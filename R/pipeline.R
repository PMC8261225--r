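# End-to-end orchestration: synth -> design -> simulate -> fit -> report,
# with a persisted configuration, a single root seed and an artefact
# manifest with checksums.

#' Build a run configuration
#'
#' All experiment counts default to the study-scale design (82 prototypes,
#' 301 / 192 / 184 participants); a reduced run scales everything down for
#' smoke testing.  The root seed drives every stochastic stage through
#' derived per-stage seeds.
#'
#' @param seed Root seed (default 1).
#' @param out_dir Output directory.
#' @param run_scale `"full"` or `"reduced"`.
#' @param n_prototypes,n_rating,n_2afc,n_iat Design sizes; defaults depend
#'   on `run_scale`.
#' @param synthesize_audio If `TRUE`, write WAV stimuli and an acoustic
#'   report (slow at full scale; default `TRUE` only for reduced runs).
#' @param backend Inference backend for the rating models.
#' @param effects,params Effect table and cohort parameters.
#' @return A `run_config` object (list).
#' @export
run_config <- function(seed = 1, out_dir = tempfile("nlpvoice_run_"),
                       run_scale = c("full", "reduced"),
                       n_prototypes = NULL, n_rating = NULL,
                       n_2afc = NULL, n_iat = NULL,
                       synthesize_audio = NULL,
                       backend = "wald",
                       effects = default_effect_table(),
                       params = default_cohort_params()) {
  run_scale <- match.arg(run_scale)
  reduced <- run_scale == "reduced"
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    run_scale = run_scale,
    n_prototypes = if (is.null(n_prototypes)) (if (reduced) 10L else 82L) else as.integer(n_prototypes),
    n_rating = if (is.null(n_rating)) (if (reduced) 30L else params$n_rating) else as.integer(n_rating),
    n_2afc = if (is.null(n_2afc)) (if (reduced) 30L else params$n_2afc) else as.integer(n_2afc),
    n_iat = if (is.null(n_iat)) (if (reduced) 36L else params$n_iat) else as.integer(n_iat),
    synthesize_audio = if (is.null(synthesize_audio)) reduced else synthesize_audio,
    backend = backend,
    effects = effects,
    params = params
  )
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Persists the scalar configuration and the effect table; together with
#' the package version this reproduces a run bit-for-bit for the
#' deterministic stages.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$effects <- list(ratings = as.list(x$effects$ratings),
                    afc_delta = as.list(x$effects$afc_delta),
                    iat = x$effects$iat)
  x$params <- NULL # defaults; only overrides are scalar fields above
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  eff <- default_effect_table()
  if (!is.null(x$effects)) {
    eff$ratings <- as.data.frame(x$effects$ratings,
                                 stringsAsFactors = FALSE)
    eff$afc_delta <- unlist(x$effects$afc_delta)
    eff$iat <- x$effects$iat
  }
  run_config(seed = x$seed, out_dir = x$out_dir, run_scale = x$run_scale,
             n_prototypes = x$n_prototypes, n_rating = x$n_rating,
             n_2afc = x$n_2afc, n_iat = x$n_iat,
             synthesize_audio = x$synthesize_audio, backend = x$backend,
             effects = eff)
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Generates prototypes, builds the stimulus set and comparison pairs,
#' optionally synthesizes and measures the audio, simulates the three
#' listener experiments, fits all effect models and writes CSV tables plus
#' a manifest (file checksums, counts, seeds) under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all tables and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  prototypes <- .run_stage("prototypes", generate_prototypes(
    config$n_prototypes, seed = child_seed(seed, 1), config$params$prototypes))
  stimuli <- .run_stage("design", build_stimulus_set(prototypes))
  pairs <- .run_stage("design", enumerate_pairs(prototypes))

  acoustics <- NULL
  if (isTRUE(config$synthesize_audio)) {
    acoustics <- .run_stage("synthesis", {
      wav_dir <- file.path(out, "stimuli")
      dir.create(wav_dir, showWarnings = FALSE)
      stims <- lapply(seq_len(nrow(stimuli)), function(i) {
        p <- prototypes[[match(stimuli$prototype_id[i],
                               vapply(prototypes, `[[`, "", "id"))]]
        st <- resynthesize(p, stimuli$condition[i])
        write_wav(st$wave, st$sample_rate,
                  file.path(wav_dir, paste0(stimuli$stimulus_id[i], ".wav")))
        st
      })
      acoustic_report(stims)
    })
  }

  n_per_block <- min(50L, floor(nrow(stimuli) / 2))
  rating_alloc <- .run_stage("design", allocate_rating_trials(
    config$n_rating, stimuli, seed = child_seed(seed, 2),
    stimuli_per_block = n_per_block))
  afc_alloc <- .run_stage("design", allocate_2afc_trials(
    config$n_2afc, pairs, seed = child_seed(seed, 3),
    n_experimental = min(47L, nrow(pairs))))
  iat_alloc <- .run_stage("design", allocate_iat_blocks(
    config$n_iat, seed = child_seed(seed, 4)))

  ratings <- .run_stage("simulate", simulate_ratings(
    rating_alloc, config$effects, config$params, seed = child_seed(seed, 5)))
  afc <- .run_stage("simulate", simulate_2afc(
    afc_alloc, config$effects, config$params, seed = child_seed(seed, 6)))
  iat <- .run_stage("simulate", simulate_iat(
    iat_alloc, config$effects, config$params, seed = child_seed(seed, 7)))

  effects_rating <- .run_stage("fit", fit_all_rating_models(
    ratings, backend = config$backend, seed = child_seed(seed, 8)))
  afc_fit <- .run_stage("fit", fit_2afc_model(
    afc, seed = child_seed(seed, 9)))
  effects_iat <- .run_stage("fit", fit_iat_model(
    iat, seed = child_seed(seed, 10)))
  agreement <- .run_stage("fit", interrater_agreement(ratings))
  corr <- .run_stage("fit", scale_correlations(ratings))

  .write <- function(df, name) {
    path <- file.path(out, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(
    .write(stimuli, "stimuli.csv"),
    .write(pairs, "pairs.csv"),
    .write(ratings, "trials_rating.csv"),
    .write(afc, "trials_2afc.csv"),
    .write(iat, "trials_iat.csv"),
    .write(effects_rating, "effects_rating.csv"),
    .write(afc_fit$estimates, "effects_2afc.csv"),
    .write(effects_iat, "effects_iat.csv"),
    .write(agreement, "agreement.csv"),
    .write(as.data.frame(corr), "scale_correlations.csv")
  )
  if (!is.null(acoustics)) files <- c(files, .write(acoustics, "acoustics.csv"))
  if (isTRUE(config$synthesize_audio)) {
    files <- c(files, list.files(file.path(out, "stimuli"),
                                 full.names = TRUE))
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out, "run_config.yaml"))
  yaml::write_yaml(list(
    seed = seed,
    n_prototypes = length(prototypes),
    n_stimuli = nrow(stimuli),
    n_pairs = nrow(pairs),
    n_rating_participants = config$n_rating,
    n_2afc_participants = config$n_2afc,
    n_iat_participants = config$n_iat
  ), file.path(out, "run_summary.yaml"))

  invisible(list(
    prototypes = prototypes, stimuli = stimuli, pairs = pairs,
    ratings = ratings, afc = afc, iat = iat,
    effects_rating = effects_rating, effects_2afc = afc_fit,
    effects_iat = effects_iat, agreement = agreement,
    scale_correlations = corr, acoustics = acoustics,
    manifest = manifest, out_dir = out
  ))
}
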