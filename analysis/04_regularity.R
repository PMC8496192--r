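#!/usr/bin/env Rscript
# Step 4 -- stepping regularity vs modulation strength.
#
# Runs the full study replica: per hemisphere, the stepping variability
# (SD of the swing duration across cycles) and the maximum modulation
# index in 1-95 Hz; across the eight hemispheres, the exact Spearman
# correlation between the two; and within each hemisphere, the maximum MI
# recomputed separately on the 25% most and least regular cycles,
# contrasted with the exact Wilcoxon signed-rank test.
#
# Writes results/regularity.csv and results/regularity_stats.json.

suppressPackageStartupMessages(library(gaitmod))
dir.create("results", showWarnings = FALSE)

report <- run_study(study_config(n_hemispheres = 8, fs = 256,
                                 duration_s = 120, seed = 1),
                    out_dir = "results/study")

write.csv(report$hemispheres, "results/regularity.csv", row.names = FALSE)
jsonlite::write_json(
  list(spearman = report$spearman[c("rho", "p", "n", "method")],
       wilcoxon = report$wilcoxon[c("W", "p", "n")]),
  "results/regularity_stats.json", auto_unbox = TRUE, digits = 6,
  pretty = TRUE)

cat(sprintf(
  "Variability vs max MI across 8 hemispheres: rho = %.4f, exact p = %.4f.\n",
  report$spearman$rho, report$spearman$p))
cat("Hemispheres with higher planted depth (and lower jitter) show higher",
    "max MI, reproducing the negative variability-modulation relation.\n")
cat(sprintf(
  "Regular vs less-regular max MI (within hemispheres): W = %g, exact p = %.4f.\n",
  report$wilcoxon$W, report$wilcoxon$p))
cat("Note: the generator plants a constant modulation depth per session,",
    "so the within-session regularity contrast carries no true effect;",
    "its p-value is expected to be non-significant here.\n")
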