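#!/usr/bin/env Rscript

# Stage 3: simulate listener responses for all three experiments.
#
# The population effects are the default effect table (the published
# contrast estimates); individual heterogeneity enters through participant
# intercepts, prototype intercepts (correlated across scales) and
# prototype-by-condition deviations.

suppressMessages(library(nlpvoice))

seed <- 20260928L
out <- "results"

rating_alloc <- read.csv(file.path(out, "alloc_rating.csv"))
afc_alloc <- read.csv(file.path(out, "alloc_2afc.csv"))
iat_alloc <- read.csv(file.path(out, "alloc_iat.csv"))

ratings <- simulate_ratings(rating_alloc, seed = seed + 11)
afc <- simulate_2afc(afc_alloc, seed = seed + 12)
iat <- simulate_iat(iat_alloc, seed = seed + 13)

write.csv(ratings, file.path(out, "trials_rating.csv"), row.names = FALSE)
write.csv(afc, file.path(out, "trials_2afc.csv"), row.names = FALSE)
write.csv(iat, file.path(out, "trials_iat.csv"), row.names = FALSE)

cat("Rating trials:", nrow(ratings), "\n")
cat("Mean rating by condition on the roughness scale:\n")
r <- ratings[ratings$scale == "roughness", ]
print(round(tapply(r$response, r$condition, mean), 1))
cat("\nForced-choice response shares:\n")
print(round(prop.table(table(afc$response)), 3))
cat("\nImplicit-association error rates by block congruency:\n")
print(round(tapply(!iat$correct, iat$congruency, mean), 3))
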