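---
title: "Methods: population dynamics and the developmental inhibition switch"
author: "pupdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population dynamics and the developmental inhibition switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pupdyn` implements the population-level analysis chain used to
characterise how hippocampal CA1 dynamics in neonatal mice disengage from
self-generated movement at the end of the first postnatal week, together
with the two-population network models that explain the disengagement as a
consequence of rising somatic (perisomatic) inhibition. The package covers
five layers:

1. **Rasters and sessions** — binary activity matrices built from calcium
   transient (onset, peak) intervals, movement epochs, optional DF/F
   traces, and a plain-CSV session-bundle format.
2. **Event statistics** — synchronous calcium event (SCE) detection
   against circular-shift surrogates; transient frequency; the fraction of
   transients inside SCEs.
3. **Movement coupling** — peri-movement time histograms (PMTHs) with
   permutation chance bands, post-movement activity ratios, the
   "inhibiting movement" classification, movement/immobility-associated
   cells, and developmental trend fits (linear, sigmoid, quartic).
4. **Models** — a two-population excitatory/inhibitory rate model with
   analytic noise-correlation predictions, and a sparse
   leaky-integrate-and-fire (LIF) network; both compared to data through
   the same fluorescence forward model and correlogram estimator.
5. **Supporting modalities** — EMG vigilance scoring with twitch
   detection, early-sharp-wave (eSW) detection in layered LFP,
   synaptotagmin-2 bouton coverage, and skeleton-based axon segmentation
   with activity clustering.

Seeded generators (`generate_session()`, `generate_emg()`,
`generate_lfp()`, `generate_axon_movie()`, `generate_syt2_image()`)
produce inputs with the statistical structure each analysis assumes, so
the full chain is testable without any external recording.

# Conventions

Frames are 1-based, following R's indexing; a neuron is active over the
closed interval from transient onset to transient peak. The frame rate is
carried as data (default 10 Hz, so five frames span 500 ms) rather than
hard-coded, since acquisition rates vary slightly around that value.
Cells labelled `noise` are removed when a raster is constructed and never
enter any statistic.

# Surrogate-based statistics

**SCE detection.** Co-activity is the per-frame count of active cells.
Chance co-activity is estimated from 300 surrogate rasters in which every
cell's row is rotated by an independent uniform integer in
`[1, n_frames - 1]` (zero excluded, so a surrogate row never coincides
with the original; totals and transient durations are conserved exactly).
The detection threshold is the 99th percentile of the per-frame counts
pooled across all surrogates — pooling is the stationary reading of the
procedure and keeps the threshold well-defined even for short sessions.
SCE frames are strict local maxima of the observed count above the
threshold; plateaus resolve to their first frame, and peaks closer than
five frames are merged keeping the larger count (earlier frame on ties).
This merge rule is a declared convention, not inferred from data.

**PMTHs.** A 20-s window centred on each movement onset is binned at
frame resolution. Per-bin 25th/50th/75th percentiles across movements are
divided by the cell count (x100 for the active-cell percentage). The
chance band stacks the median PMTHs of 500 circular-shift surrogates and
takes their per-bin 5th/50th/95th percentiles; bins whose observed median
exceeds the 95th (falls below the 5th) surrogate percentile are flagged
as significant activation (suppression). Group-level curves stack session
medians (and pool all session surrogate medians) with the same percentile
semantics. Movements whose window does not fit inside the session are
dropped rather than padded. All movement categories are pooled by
default; a `categories` filter is available.

**Post-movement activity and inhibiting movements.** For each movement a
4-s window centred on the onset is split into a 2-s pre and a 2-s post
half, with the onset frame assigned to the post half (a declared
convention). The ratio is the number of cells active at least once in the
post half over the number active anywhere in the window; movements with
no active cell are skipped. A movement is *inhibiting* when the ratio is
strictly below 0.40 ("less than 40%"); the per-animal summary is the
proportion of inhibiting movements.

**Epoch-associated cells.** Per cell, the count of transient onsets
inside the epoch set is compared with the 99th percentile of the same
count under 100 circular shifts of the onsets (onset-only shifts — the
procedure rolls the onset times, not the whole raster). Cells are flagged
only on strict exceedance; transient-free cells are never flagged. On
independent null cells the flagged fraction sits at or slightly below 1%
— the discreteness of small counts makes the strict-exceedance rule
conservative, which the calibration tests account for with a binomial
band.

**Trend fits.** `fit_trend()` offers least-squares linear, fourth-order
polynomial and four-parameter logistic fits,
`y = bottom + (top - bottom) / (1 + exp(-k (x - v50)))`, with a
multi-start Levenberg-Marquardt search over `k` and `v50` to avoid local
minima. For constant responses `r^2` is 0 by convention and the fit is
flat.

# Synthetic sessions as study conditions

The session generator encodes the study conditions the analyses are
tested under. Defaults were chosen once, to echo the magnitudes the
analyses report on real data, and are all exposed in `session_design()`:

* 400 pyramidal cells and 25 interneurons per session (a few hundred
  cells per field of view, with interneurons a small minority), 10
  minutes at 10 Hz;
* baseline transient rates of 0.7/min (pyramidal) and 2/min
  (interneuron) with log-normal onset-to-peak durations around 0.4 s,
  which put the baseline active fraction near 0.5% per frame for
  pyramidal cells and a few percent for interneurons;
* movements at 6/min with log-normal durations (mu = log 0.4 s, sigma =
  0.8 for the twitch component; a >= 2 s component for complex
  movements); realised durations label epochs as twitch (< 1 s), complex
  (>= 2 s) or unclassified;
* SCE bursts at 1/min recruiting 15% of cells;
* movement coupling as a multiplicative hazard on transient onsets in the
  2 s after each onset. Pre-switch gains (pyramidal x4, interneuron
  x3.8) reproduce peri-movement peak/baseline ratios of roughly four;
  post-switch the pyramidal gain falls to 0.05 (suppression) while
  interneurons stay activated (x2.5).

The pyramidal gain blends from its pre- to its post-switch value along a
logistic in age centred on `switch_age_days` with a half-day scale, so
the designed switch age is the midpoint of a graded transition rather
than a hard step — matching the observation that the transition completes
over about two days, and making the switch age recoverable by a sigmoid
fit. Because the inhibiting-movement proportion is a *thresholded*
readout of the coupling, its fitted midpoint sits slightly above the
coupling midpoint (recovered V50 ~ 9.2-9.4 for a designed switch at 9);
the recovery tolerance of half a day covers this known, stable offset.

DF/F traces are the binary raster convolved with a unit-peak exponential
kernel of characteristic time 2 s (the indicator decay) plus independent
Gaussian noise per frame — the simplest forward model consistent with the
slow sensor.

What the generator does **not** emulate: spatial cell geometry, movement
artefacts, correlated noise, cell-type misclassification, and any direct
recurrent coupling between cells outside movement windows. Passing tests
therefore demonstrate the correctness and calibration of the statistics,
not robustness to every nuisance of real imaging data.

# Correlograms

Population signals are per-frame active fractions of one cell type.
Cross-correlograms are lagged Pearson correlations on the frame grid,
restricted to immobility: masked frames split the series into contiguous
segments and only same-segment pairs contribute, so no pair straddles a
movement gap. Positive lag means the second signal follows the first;
lags with fewer than 10 valid pairs are reported missing. The estimator
(signal type, normalisation, binning) is a declared choice; the essential
point is that data and model pass through the *same* estimator, making
the comparison internally valid.

# The two-population model

Both models have one excitatory (E) and one inhibitory (I) population;
`J_ab` is the effect of population b on a, with `J_EI` and `J_II`
entering negatively. Development of perisomatic innervation is modelled
as an increase of `J_EI` alone — the interaction weight in the rate
model, the I-to-E in-degree `C_EI` in the LIF network.

**Rate model.** Threshold-linear rate equations with white noise,
integrated by Euler-Maruyama with rates clipped at zero. The transfer
function is not specified by the source description; threshold-linear is
the simplest choice and makes the linearised analysis exact in the
fluctuation regime. Defaults (`J_EE = 0.8`, `J_IE = 2`, `J_II = 0.5`,
`tau = 3 s`, presets `J_EI = 0.2` weak / `2` strong) were chosen, once,
to satisfy four structural constraints: (i) both regimes have stable,
strictly positive fixed points; (ii) the weak regime has real eigenvalues
(monotone pulse relaxation) while the strong regime is oscillatory
(post-pulse undershoot); (iii) the oscillation is slow enough
(~10 s period) to survive smoothing by the 2-s indicator kernel, which
suppresses any frequency much above 0.5 rad/s — this is what motivates
population time constants of seconds, standing in for the slow synaptic
kinetics of the neonatal circuit; and (iv) the feedforward movement pulse
drives I about twice as strongly as E, reflecting the much larger
movement response of interneurons, so that strong inhibition flips the
net E response from activation to suppression.

**Analytic correlations.** Around the interior fixed point the linearised
system is a two-dimensional Ornstein-Uhlenbeck process: the stationary
covariance solves the continuous Lyapunov equation `A C0 + C0 A' + D = 0`
(solved exactly via Kronecker vectorisation) and lagged covariances are
`exp(A tau) C0`. Predictions are convolved with the symmetric
autocorrelation of the indicator kernel and normalised, so they predict
exactly what the empirical correlogram estimator measures on
kernel-convolved simulated rates. The implementation is verified two
ways: against the OU closed form in the decoupled case, and against an
independent spectral-integration oracle for coupled parameters. Agreement
with *simulated* correlograms is checked at T = 2000 s; at that run
length the pointwise sampling SD of a correlation estimate is about 0.02,
so the automated check bounds the mean absolute deviation across the
+/-10 s lag grid by 0.05 (a pointwise-maximum bound at this T would be
dominated by sampling noise rather than by the analytics).

**LIF network.** 400 E and 100 I neurons with fixed in-degree random
connectivity, exponentially decaying synaptic currents (tau = 1 s, the
slow-synapse assumption again), membrane time constant 50 ms,
threshold/reset spiking with a 5-ms refractory period, and a normally
distributed noisy drive standing in for fast dynamics the calcium sensor
cannot follow. Weights and drives were tuned, once, so that the
100-ms-bin fraction of active E cells sits in the experimentally observed
few-percent range in the weak regime (`C_EI = 10`) and near 1% in the
strong regime (`C_EI = 40`). The simulator core is C++ (Rcpp); a single
noiseless neuron reproduces the closed-form LIF rate to 0.1% at
dt = 0.1 ms. Model "PMTHs" are pulse-triggered averages of the
kernel-convolved binned activity, on the same contract as the imaging
PMTH.

# EMG and LFP

**Vigilance scoring.** EMG is decimated to 1 kHz, high-pass filtered at
300 Hz (zero-phase Butterworth), and rectified. Five 1-s representative
windows per tone give the thresholds: wake at or above the midpoint of
the two mean rectified levels, active sleep below the quarter point,
transition between. Twitches are active-sleep samples above the low-tone
mean + 5 SD; super-threshold samples closer than 50 ms are one event
(rectified signals oscillate at the carrier scale, so sample-level
contiguity alone over-segments). The final visual-inspection step of the
manual protocol is replaced by a machine check that flags bins within 5%
of a threshold for review.

**eSW detection.** Layer traces are band-passed 2-45 Hz with a zero-phase
Butterworth filter — used here as the practical equivalent of a
forward-inverse wavelet reconstruction over the band, and validated by
frequency response (gain > 0.7 at 50 Hz, < 0.1 at 200 Hz in the 2-100 Hz
preprocessing stage). Candidate events are extrema of the
radiatum-minus-oriens difference trace above 4 SD of the whole trace; the
pyramidale reversal is operationalised as opposite-sign oriens/radiatum
deflections with the pyramidale amplitude below half the smaller flank.
Events closer than 100 ms merge keeping the larger peak. Co-occurrence
histograms bin contralateral-minus-ipsilateral time differences at 10 ms;
ties for the peak resolve to the lag nearest zero.

# Images

**Bouton coverage.** Max projection of the top 6 um, morphological
top-hat background removal (disc radius 15 px), subtraction of the mean
of a background ROI (clipped at zero), Kapur max-entropy binarisation,
connected components, and retention of particles between 0.4 and
4 um^2; coverage is retained area over image area. All steps are
histogram- or morphology-based, so coverage is invariant to global
intensity scaling. On noise-free phantoms coverage is within 10% of the
drawn ground truth; the residual error is boundary discretisation.

**Axon segmentation.** The movie is summarised (Gaussian smoothing then
temporal averaging), equalised, smoothed again, adaptively thresholded
(local mean, window 12 px, offset 0.2 in equalised units), and thinned to
a 1-px skeleton (Zhang-Suen 2-D thinning — the published 3-D thinning
method applied to a 2-D summary image reduces to this). Because
histogram equalisation is rank-based, a structure-free movie would be
stretched into spurious texture; a contrast gate (maximum at least 10
robust SDs above the median of the summary image) short-circuits to an
empty result in that case. Spur twigs up to 4 px are pruned, junctions
are detected by the crossing number (three or more neighbourhood
transitions — robust to the staircase pixels of thinned diagonals), and
the remaining segments of at least 10 px are the branches. Branch
validation computes the sample skewness of the branch's pixel intensities
at the frame of its largest smoothed-trace excursion and keeps branches
with |skewness| <= 1 (zero-variance distributions count as skewness 0);
note that a branch lit on exactly half its length is *not* skewed — the
rejection criterion targets minority-lit branches, which is the common
failure mode of merged segments. Branch traces are clustered on one minus
their Spearman correlation via a 2-D classical-MDS embedding followed by
density clustering (DBSCAN with a data-driven radius of a quarter of the
median embedded distance); groups smaller than `min_cluster_size` are
singletons, and constant traces are singletons by definition.

# Numerical choices and degenerate inputs

* Quantiles everywhere use R's default (type 7) estimator.
* Surrogate shift ranges exclude zero; percentile comparisons are strict,
  making all surrogate tests conservative under ties.
* All generators and stochastic analyses take a `seed` and restore the
  caller's RNG state; identical inputs give bit-identical outputs.
* Degenerate inputs are first-class: all-zero rasters yield zero
  thresholds and no SCEs; transient-free cells are excluded from ratio
  means (an all-silent raster is an error, not a silent zero); movements
  whose windows leave the session are dropped; flat EMG errors on
  threshold construction; flat LFP yields zero events; blank images yield
  zero coverage; structure-free movies yield no branches.

# Problem sizes in the automated checks

The test suite and the acceptance script run everything at desk scale,
chosen to keep each stage's sampling error well inside its tolerance: 50
null rasters of 100 x 5000 frames for surrogate calibration, 24 synthetic
sessions (ages 5-12, three animals per age) for the switch recovery,
three sessions per group for PMTHs, T = 2000 s for the
analytic-vs-simulated correlation comparison, 300-400 s network runs
with 8-14 pulses for the pulse-response contracts, and 10-20 seeded
phantoms for the image pipelines.

# Known limitations

* The generator couples cells only through movement and SCE events; it
  contains no recurrent connectivity, so data-level correlogram
  asymmetries are weaker than in real post-switch recordings (the model,
  which has true feedback inhibition, is the right place to study the
  undershoot).
* Exact model parameter values from the original study's supplementary
  table are not redistributed here; the defaults satisfy the qualitative
  contracts and are fully exposed, and users may substitute the published
  values.
* The NWB reading interface is not implemented; sessions enter through
  the CSV bundle dialect or the generators.
* The sigmoid V50 of a thresholded readout is a biased estimator of the
  underlying coupling midpoint (see above); analyses that need the exact
  midpoint should fit the coupling directly.
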