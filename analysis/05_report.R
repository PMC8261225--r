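#!/usr/bin/env Rscript

# Stage 5: compare the recovered effects with the configured population
# truth and draw the summary figures.

suppressMessages(library(nlpvoice))

out <- "results"
effects_rating <- read.csv(file.path(out, "effects_rating.csv"))
afc <- read.csv(file.path(out, "effects_2afc.csv"))

truth <- default_effect_table()$ratings
cmp <- merge(effects_rating,
             setNames(truth, c("scale", "contrast", "injected")),
             by = c("scale", "contrast"))
cmp$recovered <- cmp$point
cmp$abs_error <- abs(cmp$recovered - cmp$injected)
cmp <- cmp[order(cmp$scale, cmp$contrast),
           c("scale", "contrast", "injected", "recovered", "lo", "hi",
             "abs_error", "units")]
write.csv(cmp, file.path(out, "recovery_summary.csv"), row.names = FALSE)
cat("Parameter recovery (injected vs recovered, all scales):\n")
print(cbind(cmp[, c("scale", "contrast")],
            round(cmp[, c("injected", "recovered", "abs_error")], 2)),
      row.names = FALSE)
cat(sprintf("\nMax |recovered - injected| relative to interval half-width: %.2f\n",
            max(cmp$abs_error / ((cmp$hi - cmp$lo) / 2))))

pdf(file.path(out, "fig_effects.pdf"), width = 9, height = 6)
op <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
for (s in unique(effects_rating$scale)) {
  e <- effects_rating[effects_rating$scale == s, ]
  x <- seq_len(nrow(e))
  plot(x, e$point, ylim = range(c(e$lo, e$hi, 0)), xaxt = "n", pch = 16,
       xlab = "", ylab = e$units[1], main = s, xlim = c(0.5, 3.5))
  axis(1, at = x, labels = e$contrast, las = 2, cex.axis = 0.8)
  arrows(x, e$lo, x, e$hi, angle = 90, code = 3, length = 0.04)
  abline(h = 0, lty = 3)
}
par(op)
dev.off()

pdf(file.path(out, "fig_2afc.pdf"), width = 6, height = 4)
x <- seq_len(nrow(afc))
lab <- paste(afc$first, "vs", afc$second)
plot(afc$delta, rev(x), xlim = range(c(afc$lo, afc$hi, 0)), yaxt = "n",
     pch = ifelse(afc$cleared_rope, 16, 1),
     xlab = "P(first larger) - P(first smaller), %", ylab = "")
axis(2, at = rev(x), labels = lab, las = 1, cex.axis = 0.7)
arrows(afc$lo, rev(x), afc$hi, rev(x), angle = 90, code = 3, length = 0.04)
abline(v = 0, lty = 3)
dev.off()

cat("Figures written to", file.path(out, "fig_effects.pdf"), "and",
    file.path(out, "fig_2afc.pdf"), "\n")
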