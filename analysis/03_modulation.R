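#!/usr/bin/env Rscript
# Step 3 -- gait-phase modulograms, modulation index, and the within-cycle
# phase-shuffle cluster permutation test.
#
# For the cohort of step 1: reconstruct the gait phase from the
# contralateral force plate, decompose the bipolar LFPs (Morlet, 1-95 Hz),
# bin power into 18 gait-phase bins, and compute the per-frequency KL
# modulation index. The strongest channel of the most regular hemisphere is
# tested with the cluster-based permutation procedure (1000 within-cycle
# phase shuffles).
#
# Writes results/group_modulogram.csv, results/mi_spectra.csv and
# results/modulogram_clusters.json.

suppressPackageStartupMessages(library(gaitmod))
dir.create("results", showWarnings = FALSE)

cfg <- study_config(n_hemispheres = 8, fs = 256, duration_s = 120, seed = 1)
freqs <- 1:95

message("per-hemisphere modulograms...")
hemi_maps <- list()
hemi_mi <- list()
best <- NULL
for (i in seq_along(cfg$hemispheres)) {
  sess <- generate_session(cfg$hemispheres[[i]])
  pre <- preprocess_recording(sess$recording)
  bip <- make_bipolar(pre, pre$labels[pre$kinds == "lfp"])
  ph <- phase_from_force(gaitmod:::channel_signal(pre, "force_left"),
                         pre$fs)
  tfr <- morlet_tfr(bip, freqs = freqs)
  mods <- lapply(seq_along(bip$labels), function(ci)
    modulogram(tfr, ph$phase, channel = ci))
  mis <- lapply(mods, modulation_index)
  hemi_maps[[i]] <- Reduce(`+`, lapply(mods, `[[`, "mean_norm")) /
    length(mods)
  hemi_mi[[i]] <- Reduce(`+`, lapply(mis, `[[`, "mi")) / length(mis)
  if (i == 1) {
    ch <- which.max(vapply(mis, function(m) max_mi(m)$value, numeric(1)))
    best <- list(tfr = tfr, phase = ph, channel = ch,
                 label = bip$labels[ch])
  }
}

group_map <- Reduce(`+`, hemi_maps) / length(hemi_maps)
group_mi <- Reduce(`+`, hemi_mi) / length(hemi_mi)
bin_centers <- seq(-pi + pi / 18, pi - pi / 18, length.out = 18)

write.csv(cbind(data.frame(freq_hz = freqs, group_mi = group_mi),
                as.data.frame(`colnames<-`(group_map,
                                           sprintf("bin_%02d", 1:18)))),
          "results/group_modulogram.csv", row.names = FALSE)
write.csv(data.frame(freq_hz = freqs,
                     do.call(cbind, setNames(hemi_mi,
                                             paste0("hemi_", 1:8)))),
          "results/mi_spectra.csv", row.names = FALSE)

message("cluster permutation on the strongest channel (1000 shuffles)...")
perm <- cluster_perm_modulogram(best$tfr, best$phase$phase,
                                best$phase$cycles, n_perm = 1000,
                                seed = 21, channel = best$channel)
sig <- Filter(function(cl) cl$p_value < 0.05, perm$clusters)
cluster_json <- lapply(perm$clusters, function(cl) {
  fr <- ((cl$cells - 1) %% length(freqs)) + 1
  list(freq_lo = min(freqs[fr]), freq_hi = max(freqs[fr]),
       n_cells = length(cl$cells), mass = cl$mass, p = cl$p_value)
})
jsonlite::write_json(list(channel = best$label, n_perm = perm$n_perm,
                          mode = perm$mode, clusters = cluster_json),
                     "results/modulogram_clusters.json",
                     auto_unbox = TRUE, digits = 6, pretty = TRUE)

peak <- which(group_mi == max(group_mi))
cat(sprintf("Group MI peaks at %d Hz (MI = %.3f); planted band is 20-25 Hz.\n",
            freqs[peak], max(group_mi)))
cat(sprintf("Peak phase bin of the group modulogram at %d Hz: center %.2f rad (planted preferred phase 0).\n",
            freqs[peak], bin_centers[which.max(group_map[peak, ])]))
cat(sprintf("Significant clusters on %s: %d (smallest p = %.4f).\n",
            best$label, length(sig), min_cluster_p(perm)))
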