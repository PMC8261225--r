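# Deterministic (seeded) construction of the stimulus sets and trial
# allocations of the three listener experiments.

#' Build the full stimulus set
#'
#' The Cartesian product of prototypes and the four synthesis conditions:
#' 82 prototypes yield 4 x 82 = 328 stimulus descriptors.
#'
#' @param prototypes List of [prototype()] objects, or a character vector
#'   of prototype ids.
#' @return data.frame with `stimulus_id`, `prototype_id`, `condition`.
#' @export
build_stimulus_set <- function(prototypes) {
  ids <- if (is.character(prototypes)) {
    prototypes
  } else {
    vapply(prototypes, function(p) p$id, character(1))
  }
  if (anyDuplicated(ids)) stop("duplicate prototype ids")
  out <- expand.grid(prototype_id = ids, condition = CONDITIONS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$prototype_id, ids)), ]
  out$stimulus_id <- paste(out$prototype_id, out$condition, sep = "_")
  rownames(out) <- NULL
  out[, c("stimulus_id", "prototype_id", "condition")]
}

#' Enumerate within-prototype condition pairs
#'
#' All C(4,2) = 6 unordered condition pairs for each prototype: 82
#' prototypes yield 492 non-catch comparison pairs.  Catch pairs (the same
#' stimulus twice) are generated separately by [allocate_2afc_trials()].
#'
#' @param prototypes List of [prototype()] objects or character ids.
#' @return data.frame with `pair_id`, `prototype_id`, `cond_a`, `cond_b`.
#' @export
enumerate_pairs <- function(prototypes) {
  ids <- if (is.character(prototypes)) {
    prototypes
  } else {
    vapply(prototypes, function(p) p$id, character(1))
  }
  if (anyDuplicated(ids)) stop("duplicate prototype ids")
  cmb <- utils::combn(CONDITIONS, 2)
  out <- do.call(rbind, lapply(ids, function(pid) {
    data.frame(prototype_id = pid, cond_a = cmb[1, ], cond_b = cmb[2, ],
               stringsAsFactors = FALSE)
  }))
  out$pair_id <- sprintf("%s|%s|%s", out$prototype_id, out$cond_a, out$cond_b)
  rownames(out) <- NULL
  out[, c("pair_id", "prototype_id", "cond_a", "cond_b")]
}

#' Allocate rating trials
#'
#' Each participant rates `stimuli_per_block` stimuli in each of two
#' blocks: one with a randomly selected psychoacoustic scale (pitch,
#' timbre or roughness) and one with a randomly selected ecological scale
#' (height, formidability or aggression), in randomized block and trial
#' order, under the constraint that the same stimulus never occurs twice
#' for a participant.  With the study-scale defaults (301 participants, 50
#' stimuli per block, 328 stimuli) every stimulus is rated about 15 times
#' per scale.
#'
#' @param n_participants Number of participants (default 301).
#' @param stimuli Stimulus set from [build_stimulus_set()].
#' @param seed Integer seed.
#' @param stimuli_per_block Stimuli per block (default 50).
#' @return data.frame with one row per trial: `participant_id`, `block`,
#'   `trial`, `scale`, `stimulus_id`, `prototype_id`, `condition`.
#' @export
allocate_rating_trials <- function(n_participants = 301, stimuli,
                                   seed = NULL, stimuli_per_block = 50) {
  n_needed <- 2 * stimuli_per_block
  if (nrow(stimuli) < n_needed) {
    stop("need at least ", n_needed, " distinct stimuli, have ",
         nrow(stimuli))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_participants), function(p) {
      scales <- c(sample(PSYCHOACOUSTIC_SCALES, 1),
                  sample(ECOLOGICAL_SCALES, 1))
      scales <- sample(scales) # randomize block order
      idx <- sample.int(nrow(stimuli), n_needed)
      data.frame(
        participant_id = sprintf("P%04d", p),
        block = rep(1:2, each = stimuli_per_block),
        trial = seq_len(n_needed),
        scale = rep(scales, each = stimuli_per_block),
        stimulus_id = stimuli$stimulus_id[idx],
        prototype_id = stimuli$prototype_id[idx],
        condition = stimuli$condition[idx],
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Allocate forced-choice trials
#'
#' Each participant receives `n_experimental` comparison pairs sampled
#' without replacement from the enumerated pairs, with the presentation
#' order within each pair randomized, plus `n_catch` catch trials pairing
#' a randomly chosen stimulus with itself; experimental and catch trials
#' are randomly interleaved.
#'
#' @param n_participants Number of participants (default 192).
#' @param pairs Pair list from [enumerate_pairs()].
#' @param seed Integer seed.
#' @param n_experimental Experimental trials per participant (default 47).
#' @param n_catch Catch trials per participant (default 3).
#' @return data.frame with one row per trial: `participant_id`, `trial`,
#'   `prototype_id`, `cond_first`, `cond_second`, `is_catch`.
#' @export
allocate_2afc_trials <- function(n_participants = 192, pairs, seed = NULL,
                                 n_experimental = 47, n_catch = 3) {
  if (nrow(pairs) < n_experimental) {
    stop("need at least ", n_experimental, " pairs, have ", nrow(pairs))
  }
  protos <- unique(pairs$prototype_id)
  with_seed(seed, {
    rows <- lapply(seq_len(n_participants), function(p) {
      idx <- sample.int(nrow(pairs), n_experimental)
      swap <- stats::runif(n_experimental) < 0.5
      exp_df <- data.frame(
        prototype_id = pairs$prototype_id[idx],
        cond_first = ifelse(swap, pairs$cond_b[idx], pairs$cond_a[idx]),
        cond_second = ifelse(swap, pairs$cond_a[idx], pairs$cond_b[idx]),
        is_catch = FALSE,
        stringsAsFactors = FALSE
      )
      catch_cond <- sample(CONDITIONS, n_catch, replace = TRUE)
      catch_df <- data.frame(
        prototype_id = sample(protos, n_catch, replace = TRUE),
        cond_first = catch_cond,
        cond_second = catch_cond,
        is_catch = TRUE,
        stringsAsFactors = FALSE
      )
      out <- rbind(exp_df, catch_df)
      out <- out[sample.int(nrow(out)), ]
      out$participant_id <- sprintf("P%04d", p)
      out$trial <- seq_len(nrow(out))
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("participant_id", "trial", "prototype_id", "cond_first",
            "cond_second", "is_catch")]
  })
}

#' Allocate participants to implicit-association sound pairs
#'
#' Six sound pairs (two per NLP type) are tested between subjects:
#' participants are spread as evenly as possible over the six pairs
#' (about 30 each at the default 184), and the order of the congruent and
#' incongruent blocks is randomized per participant.
#'
#' @param n_participants Number of participants (default 184).
#' @param seed Integer seed.
#' @return data.frame with `participant_id`, `sound_pair`, `nlp_type`,
#'   `first_block`.
#' @export
allocate_iat_blocks <- function(n_participants = 184, seed = NULL) {
  pair_names <- paste(rep(NLP_TYPES, each = 2), 1:2, sep = "_")
  with_seed(seed, {
    sp <- rep_len(pair_names, n_participants)
    data.frame(
      participant_id = sprintf("P%04d", seq_len(n_participants)),
      sound_pair = sp,
      nlp_type = sub("_[12]$", "", sp),
      first_block = sample(c("congruent", "incongruent"),
                           n_participants, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}
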