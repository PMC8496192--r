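---
title: "Gait-phase-locked modulation of deep-brain LFP oscillations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-phase-locked modulation of deep-brain LFP oscillations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmod)
```

## The question and the measurement model

During walking or stepping in place, activity in deep-brain structures
involved in locomotor control is not merely elevated on average — it can be
*rhythmically modulated within each gait cycle*. `gaitmod` implements an
analysis chain that makes this modulation measurable from multichannel
local field potentials (LFPs) recorded from deep-brain-stimulation
electrode contacts, together with synchronized gait sensors (per-foot force
plates or a trunk accelerometer):

1. **Preprocessing** — bipolar re-referencing of adjacent contacts (to
   suppress volume-conducted common-mode activity), zero-phase Butterworth
   filtering, and resampling.
2. **Time–frequency decomposition** — complex Morlet wavelets on a linear
   1–95 Hz grid with 4–8 cycles (linearly increasing with frequency).
3. **Gait phase** — each cycle is mapped onto $[-\pi, \pi)$: foot lift at
   $\pm\pi$, heel strike at $0$, linear interpolation in between, anchored
   on zero-crossings of the band-passed force (or accelerometer minima).
4. **Modulogram and modulation index** — wavelet power is averaged within
   18 phase bins per frequency. With $P$ the sum-normalized binned power at
   one frequency and $U$ the uniform distribution over $N = 18$ bins,
   $$\mathrm{MI} = \frac{D_{\mathrm{KL}}(P, U)}{\log N}, \qquad
     D_{\mathrm{KL}}(P, U) = \sum_{j=1}^{N} P(j)\,
     \log\!\frac{P(j)}{U(j)},$$
   so MI is 0 iff power is flat over phase and 1 when it concentrates in a
   single bin.
5. **Statistics** — a cluster-based permutation test whose null is built by
   *within-cycle phase shuffling* (each cycle's phase vector is cut at a
   random point and the segments swapped, preserving the per-cycle phase
   multiset while destroying phase–power alignment); a sign-flip cluster
   permutation test for paired condition contrasts; and exact
   small-sample Wilcoxon signed-rank and Spearman tests by full
   enumeration.
6. **Unsupervised states** — an HMM whose states are multivariate AR
   processes segments the raw LFP into recurring dynamical states;
   per-state gait-phase occupancy histograms (100 bins, uniform reference
   1%) are tested against uniformity and clustered with K-medoids.

Imaginary coherence between LFP and EEG derivations,
$\mathrm{IC}(f) = |\mathrm{Im}\,G_{xy}(f)| / \sqrt{G_{xx}(f)\,G_{yy}(f)}$,
quantifies cortical coupling while being blind to zero-lag
(volume-conducted or artifactual) components; the spectral densities are
averaged products of the Morlet coefficients.

## The synthetic-session generator

No patient recordings accompany this package, so all validation runs on
`generate_session()`, which emulates a paced stepping-in-place session with
known ground truth:

* **Cycles.** Nominal period 2 s (one left plus one right step); per-cycle
  durations are $2 + \mathcal N(0, \sigma_j^2)$ s, truncated below at half
  the period. $\sigma_j$ (`cycle_jitter_sd_s`) is the stepping-variability
  dial.
* **LFP.** Each monopolar contact carries, per configured band, an
  independent unit-RMS band-limited Gaussian carrier whose instantaneous
  amplitude is $1 + d\cos(\varphi - \varphi_0)$ with depth $d \in [0, 1]$
  and preferred phase $\varphi_0$; plus $1/f$ background noise (unit RMS by
  default) and a common-mode $1/f$ component shared across contacts (unit
  RMS by default), which the bipolar montage removes exactly. Physical
  signal-to-noise is not identifiable from published summaries, so the
  carrier/background/common-mode amplitudes are free parameters with the
  defaults above, documented rather than tuned.
* **EEG.** Background noise plus an attenuated copy of the contact-0
  oscillation delayed by 10 ms; the delay makes the planted LFP–EEG
  coupling visible to *imaginary* coherence.
* **Force plates.** Modeled as sinusoidal load transfer between the feet:
  each plate sees $\tfrac{1}{2}(1 + \sin\varphi)$ body weights (the other
  foot the complement, i.e. half a cycle offset). A half-rectified stance
  profile was considered and rejected: removing its DC with the 0.5–5 Hz
  band-pass shifts the zero-crossings ~0.4 rad away from the true
  lift/strike instants, which would corrupt every phase-locked quantity
  downstream. With load transfer the band-passed trace is a single
  sinusoid per cycle and its crossings sit exactly on the anchors, while
  the raw trace remains positive while loaded, maximal mid-stance and
  minimal in swing, and the "foot lifted" period coincides with the
  filtered force being negative.
* **Accelerometer.** $x = \cos\varphi$ (one minimum per cycle at
  $\pm\pi$), $y = -\sin\varphi$ (increasing at the minimum), $z$ noise —
  exactly the anchor rule the accelerometer phase detector uses.
* **Edges.** The first anchor sits 1 s into the trace and cycles are kept
  while their closing anchor stays 0.25 s clear of the end. The phase
  detectors discard events within 0.3 s of the trace ends (`guard_s`),
  where the 0.5 Hz filter corner has not settled; the two constants are
  aligned so the first uncounted generator anchor can never surface as a
  spurious extra cycle.

## Numerical and design choices

* **Filters.** "Order 8" denotes the final band-filter order
  (`signal::butter(4, ...)` for a band design), applied forward–backward,
  so the effective magnitude response is order 16 — the common convention
  of the MATLAB-style toolchains this mirrors. Before filtering, signals
  are odd-reflection padded by three periods of the low corner frequency;
  `signal::filtfilt` alone does no padding, and the 0.5 Hz corner would
  otherwise ring far into short gait blocks. Filtering is exactly linear;
  the time-reversal (zero-phase) identity holds away from the padded
  edges.
* **Wavelets.** Kernels are analytic Gaussians in the frequency domain
  with *peak gain 1* at the centre frequency, so a unit-amplitude tone
  yields power 1 at every frequency (unit-energy normalization would make
  tone power scale with the wavelet length instead). Coefficients within
  three temporal SDs of either edge are flagged per frequency and excluded
  from every average.
* **Resampling** is Fourier-domain truncation: an ideal anti-alias filter
  and exact in-band amplitude preservation in one step.
* **Bins.** 18 half-open bins $[-\pi + k \cdot 2\pi/18, \cdot)$, the last
  closed at $\pi$. Phase 0 (heel strike) is therefore a *bin edge*: a
  modulation peaked exactly at 0 straddles the two adjacent bins, and
  recovery checks accordingly accept a peak in either bin touching 0
  (preferred phase recovered within the ±20° bin discretization).
* **KL convention.** $0 \log 0 \equiv 0$; MI is invariant to overall power
  gain by construction.
* **Cluster tests.** Cells are z-scored against the permutation mean and
  SD. With ≥ 500 permutations, cell thresholds come from each cell's own
  permuted $|z|$ quantile ("empirical" mode); below that the Gaussian
  two-sided threshold is used ("gaussian" mode); both are exposed.
  Same-sign suprathreshold cells are joined by 4-connectivity with the
  phase-bin dimension circular (bin 18 borders bin 1 — phase is an angle);
  cluster mass is $\sum |z|$ and cluster $p = (1 + \#\{\text{null} \ge
  \text{mass}\})/(n_{\mathrm{perm}} + 1)$. The permutation engine exploits
  that a within-cycle shuffle is a circular rotation of the cycle's bin
  labels: per-cycle cumulative power sums turn each permuted modulogram
  into $O(\text{bins})$ range sums, which is what makes 200 replicates
  × 200 permutations of the false-positive simulation affordable.
* **Exact tests.** The signed-rank null is evaluated by the
  generating-function convolution over all $2^n$ sign assignments (ties in
  $|d|$ get midranks, zeros are dropped); the reported $W$ is the larger
  rank sum. The Spearman null enumerates all $n!$ rank permutations for
  $3 \le n \le 9$; outside that range the function falls back to the
  asymptotic test *with a warning and a flag*, never silently.
* **Gait events.** Zero-crossings are localized between the straddling
  samples by linear interpolation; anchors closer than 0.25 s
  (`debounce_s`) to the previous kept event, or repeating the same
  direction, are treated as sensor chatter. Lift anchors carry $-\pi$ when
  opening and $\pi$ when closing a cycle, making phase continuous and
  strictly increasing within a cycle. Partial cycles at block edges keep
  an interpolated phase but are excluded (`valid = FALSE`) from
  modulograms. Accelerometer-derived phase has no strike anchor; the
  series carries `strike_observable = FALSE` and no alignment to
  force-derived phase 0 is attempted.
* **Regularity split.** Cycles are ranked by $|{\rm duration} - \overline{\rm
  duration}|$; the lowest quarter (floor rounding) is `regular`, the
  highest `less_regular`, ties broken by earlier cycle so labels are
  invariant to row order.
* **States.** The AR-HMM is maximum-likelihood EM with k-means
  initialization on short-window variance/autocorrelation features plus
  randomized restarts, hard Viterbi assignment, and occupancy-based
  pruning — a deliberate simplification of variational Bayes toolboxes
  with automatic state selection; validation therefore rests on synthetic
  recovery (decoded-state accuracy after label matching, planted-partition
  ARI), not on matching any external implementation. Channels are
  standardized to unit variance before fitting (pooled-channel inputs
  would otherwise let one contact dominate the likelihood). AR order
  defaults to 3 at 256 Hz, exposed in the interface. K-medoids uses PAM
  (BUILD + SWAP, Euclidean), which is deterministic, so no seed is
  consumed; medoids are always members.

## Problem sizes

Examples, tests and the reproduction script use sessions of 30–205 s at
256 Hz with 14–100 cycles, 1 Hz frequency resolution over 1–95 Hz, 200–1000
permutations, 20 seeds for recovery rates and 200 replicates for the
false-positive simulation — sizes at which every quantity of interest is
stable while a full run stays in the minutes range on one core. The
generator's 2048 Hz default matches the acquisition rate the package
targets; the analyses themselves are rate-agnostic above twice the highest
analysis frequency.

## What the synthetic validation does and does not show

Passing on `generate_session()` data demonstrates that the chain is
*self-consistent*: planted modulation is recovered at the right frequency
and phase, destroyed by within-cycle shuffling, invisible when depth is 0
(with calibrated family-wise error), and the exact tests reproduce their
closed-form values. It does **not** demonstrate robustness to what the
generator omits: movement artifacts (only an amplitude-threshold flagger
stands in for visual screening), non-stationary stepping (freezing
episodes, speed drifts), biomechanically realistic force profiles, EMG
contamination, or electrode localization. Two further caveats: the
generator plants a *constant* depth per session, so the within-session
regular/less-regular MI contrast carries no true effect (its exact
Wilcoxon p is expected non-significant on synthetic cohorts — the
between-session variability–MI correlation is where the planted effect
lives); and accelerometer-derived phase is only anchor-accurate at
mid-cycle interpolation, inheriting the caveat that its 0/π need not match
force-derived strike/lift.

## A worked example

```{r example, eval = FALSE}
sess <- generate_session(session_config(
  duration_s = 60, fs = 256, cycle_jitter_sd_s = 0.05,
  modulation_bands = list(c(20, 25, 0.8, 0)), seed = 1))

pre <- preprocess_recording(sess$recording)
bip <- make_bipolar(pre, c("0", "1", "2", "3"))
ph  <- phase_from_force(pre$signals["force_left", ], pre$fs)

tfr <- morlet_tfr(bip, freqs = 1:95)
m   <- modulogram(tfr, ph$phase)
mi  <- modulation_index(m)
max_mi(mi)                               # argmax frequency in 20-25 Hz

perm <- cluster_perm_modulogram(tfr, ph$phase, ph$cycles,
                                n_perm = 1000, seed = 2)
min_cluster_p(perm)
```

The cohort-level drivers under `analysis/` run this chain over eight
hemispheres and write their tables to `results/`; see the README for the
sequence and for `scripts/acceptance.R`, which recomputes the package's
headline numbers from scratch.
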