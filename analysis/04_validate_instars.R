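#!/usr/bin/env Rscript
# Step 4 — instar validation battery.
#
# Validates the OPTICS instar partition with the Brooks-Dyar rule (constant
# growth ratio), the Crosby rule (|relative change of ratios| < 10%),
# size-frequency overlap analysis, the log-linear growth regression per
# feature, and the PCA projection.

suppressPackageStartupMessages(library(instarcluster))

tab <- read_measurements("results/synthetic_measurements.csv")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
rp <- run_pipeline(tab, "optics", seed = 1L)
part <- rp$partition

sm <- summarize_instars(tab, part)
write.table(sm, "results/instar_summary.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("per-instar summary (means in cm):\n")
print(cbind(sm[, c("feature", "instar", "n")],
            round(sm[, c("mean", "sd", "cv", "dyar", "crosby")], 3)))

cat("\nBrooks-Dyar growth regressions, ln(size in mm) on instar number:\n")
for (f in feature_columns()) print(rp$regressions[[f]])
jsonlite::write_json(lapply(rp$regressions, unclass),
                     "results/regressions.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

fa <- frequency_analysis(tab, part)
cat("\nsize-frequency range overlap between adjacent instars:\n")
for (f in feature_columns()) {
  cat(sprintf("  %-24s overlaps (cm): %s\n", f,
              paste(sprintf("%.3f", fa[[f]]$overlap), collapse = ", ")))
}
cat("any overlap:", fa$any_overlap,
    " | Crosby rule pass (|C| < 0.10):", rp$crosby_pass, "\n")

pdf("results/figures/size_frequency.pdf", width = 8, height = 6)
op <- par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
for (f in feature_columns()) {
  z <- fa[[f]]
  mids <- (z$breaks[-1] + z$breaks[-length(z$breaks)]) / 2
  barplot(z$counts, beside = FALSE, col = 2:5, names.arg = round(mids, 3),
          las = 2, cex.names = 0.6, main = f, ylab = "count")
}
par(op)
dev.off()

pc <- pca_projection(tab)
pdf("results/figures/pca_projection.pdf", width = 5.5, height = 5)
plot(pc$scores, col = partition_labels(part) + 1, pch = 19, cex = 0.7,
     xlab = sprintf("PC1 (%.1f%%)", 100 * pc$variance_explained[1]),
     ylab = sprintf("PC2 (%.1f%%)", 100 * pc$variance_explained[2]),
     main = "PCA projection of the instar clusters")
dev.off()
cat("PCA variance explained:",
    paste(sprintf("%.1f%%", 100 * pc$variance_explained), collapse = ", "),
    "\n")
cat("wrote results/instar_summary.tsv, results/regressions.json, figures\n")
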