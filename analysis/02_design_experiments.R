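#!/usr/bin/env Rscript

# Stage 2: construct the trial allocations of the three experiments.
#
# Rating task: 301 participants x 2 blocks x 50 stimuli (one psychoacoustic
# and one ecological scale each, no stimulus repeated within participant).
# Forced choice: 192 participants x (47 experimental + 3 catch) trials over
# the 492 within-prototype condition pairs.  Implicit associations: 184
# participants over 6 sound pairs (two per NLP type).

suppressMessages(library(nlpvoice))

seed <- 20260928L
out <- "results"
dir.create(out, showWarnings = FALSE)

stimuli <- read.csv(file.path(out, "stimuli.csv"))
pairs <- enumerate_pairs(unique(stimuli$prototype_id))
write.csv(pairs, file.path(out, "pairs.csv"), row.names = FALSE)

rating_alloc <- allocate_rating_trials(301, stimuli, seed = seed + 1)
afc_alloc <- allocate_2afc_trials(192, pairs, seed = seed + 2)
iat_alloc <- allocate_iat_blocks(184, seed = seed + 3)

write.csv(rating_alloc, file.path(out, "alloc_rating.csv"), row.names = FALSE)
write.csv(afc_alloc, file.path(out, "alloc_2afc.csv"), row.names = FALSE)
write.csv(iat_alloc, file.path(out, "alloc_iat.csv"), row.names = FALSE)

cat("Comparison pairs:", nrow(pairs), "(82 prototypes x 6 contrasts)\n")
cat("Rating trials:", nrow(rating_alloc),
    sprintf("-> %.1f ratings per stimulus per scale\n",
            nrow(rating_alloc) / (nrow(stimuli) * 6)))
cat("Forced-choice trials:", nrow(afc_alloc),
    sprintf("-> %.1f presentations per pair\n",
            sum(!afc_alloc$is_catch) / nrow(pairs)))
cat("Implicit-association groups:\n")
print(table(iat_alloc$sound_pair))
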