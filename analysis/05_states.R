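#!/usr/bin/env Rscript
# Step 5 -- unsupervised LFP states and their gait-phase occupancy.
#
# A session whose LFP dynamics switch between two AR regimes gated by the
# gait phase (regime A near lift/strike, regime B near mid-swing and
# mid-stance) is segmented blindly -- no phase information enters the
# model -- by the AR-observation hidden Markov model. Each decoded state's
# gait-phase occupancy histogram (100 bins) is tested against uniformity
# (KS) and the histograms are clustered with K-medoids (k = 3).
#
# Writes results/state_occupancy.csv and results/state_clusters.json.

suppressPackageStartupMessages(library(gaitmod))
dir.create("results", showWarnings = FALSE)

fs <- 256
n <- 120 * fs
phase <- wrap_angle(2 * pi * seq_len(n) / fs / 2)
gate <- abs(phase) > 3 * pi / 4 | abs(phase) < pi / 4
ar_a <- c(1.6, -0.81)      # slow resonance: anchor phases (lift/strike)
ar_b <- c(-0.5, -0.4)      # fast alternation: mid-swing / mid-stance
x <- gaitmod:::with_seed(31, {
  v <- numeric(n)
  for (t in 3:n) {
    cf <- if (gate[t]) ar_a else ar_b
    v[t] <- cf[1] * v[t - 1] + cf[2] * v[t - 2] + rnorm(1)
  }
  v
})

message("fitting the AR-HMM (4 states max, order 2)...")
model <- suppressWarnings(
  fit_state_model(matrix(x, 1), fs = fs, n_states_max = 4, ar_order = 2,
                  seed = 32))
print(model)

occ <- occupancy_histograms(model, phase_series(phase, fs = fs))
ks <- lapply(seq_len(model$n_states), function(k) ks_uniformity(occ, k))
cl <- cluster_histograms(occ, k = min(3, model$n_states))

write.csv(cbind(data.frame(bin_center = occ$bin_centers),
                as.data.frame(`colnames<-`(t(occ$prob),
                                           paste0("state_", seq_len(model$n_states))))),
          "results/state_occupancy.csv", row.names = FALSE)
jsonlite::write_json(
  list(n_states = model$n_states,
       fractional_occupancy = model$fractional_occupancy,
       ks_p = vapply(ks, `[[`, numeric(1), "p"),
       cluster_labels = cl$labels, medoids = cl$medoids),
  "results/state_clusters.json", auto_unbox = TRUE, digits = 6,
  pretty = TRUE)

anchor_bins <- abs(occ$bin_centers) > 3 * pi / 4 |
  abs(occ$bin_centers) < pi / 4
anchor_mass <- as.numeric(occ$prob %*% anchor_bins)
cat(sprintf("State %d prefers the lift/strike phases (%.0f%% of its mass);",
            which.max(anchor_mass), 100 * max(anchor_mass)))
cat(sprintf(" state %d prefers mid-swing/mid-stance (%.0f%%).\n",
            which.min(anchor_mass), 100 * (1 - min(anchor_mass))))
cat("KS uniformity p-values per state:",
    paste(sprintf("%.2g", vapply(ks, `[[`, numeric(1), "p")),
          collapse = ", "), "\n")
cat("The gait phase never enters the model: phase preference emerges from",
    "the LFP dynamics alone.\n")
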