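# pupdyn

Population dynamics of the developing hippocampus: surrogate-based
synchrony detection, movement-coupling statistics, and two-population
network models of the perisomatic-inhibition switch.

## The scientific problem

During the first postnatal week, activity in mouse CA1 is discontinuous —
recurring population bursts (synchronous calcium events, SCEs) — and is
*driven* by spontaneous movements: twitches and complex movements are
followed by a surge in the fraction of active pyramidal cells. Around
postnatal day 9 this relationship inverts within about two days: movements
start to *suppress* pyramidal activity while local GABAergic interneurons
remain movement-activated, and neuronal firing redistributes toward
immobility. The anatomical correlate is an abrupt rise of perisomatic
(putative parvalbumin basket cell) innervation of the pyramidal layer.

`pupdyn` is an R package for the analyses that establish this switch and
the models that explain it:

- **SCE detection** against circular-shift surrogates: the threshold is
  the 99th percentile of co-active cell counts pooled over 300 shuffled
  rasters; synchrony peaks above it, at least 5 frames (500 ms) apart, are
  SCE frames.
- **Peri-movement time histograms (PMTHs)**: percentage of active cells in
  a 20-s window around movement onsets, with a 5th/95th-percentile chance
  band from 500 surrogate rasters per session.
- **Post-movement activity** (active cells in the 2 s after onset over
  active cells in the surrounding 4-s window) and the **inhibiting
  movement** rule (ratio < 40%); the per-animal proportion of inhibiting
  movements follows a sigmoid in age,
  `y = bottom + (top-bottom) / (1 + exp(-k (age - V50)))`,
  whose midpoint V50 dates the switch.
- **Movement/immobility-associated cells** (onset counts vs the 99th
  percentile of 100 circular shifts) and **immobility-restricted
  cross-correlograms** between interneuron and pyramidal population
  activity.
- A **two-population E/I model** — rate equations `tau_a dr_a/dt = -r_a +
  phi(sum_b ±J_ab r_b + I_ext + pulse)` with analytic noise-correlation
  predictions from the Lyapunov equation, and a sparse LIF network —
  showing that strengthening the inhibitory-to-excitatory coupling `J_EI`
  (the number of I-to-E connections) alone flips the pulse response from
  activation to suppression and carves an undershoot into the
  positive-lag cross-correlogram, both seen through a 2-s exponential
  GCaMP6s kernel.
- **EMG vigilance scoring** (1-s bins; wake / active sleep / transition by
  midpoint and quarter-point thresholds; twitches above mean + 5 SD of the
  low tone), **early sharp wave detection** in layered LFP (4 SD on the
  radiatum-minus-oriens trace with a pyramidale reversal; 10-ms-bin
  inter-hemispheric co-occurrence), **synaptotagmin-2 bouton coverage**
  (max-entropy threshold, 0.4-4 um² particles), and **skeleton-based axon
  segmentation** with skewness validation and correlation clustering.

Every input modality has a seeded synthetic generator with returned ground
truth, so the entire chain is testable offline. See the methods vignette
(`vignettes/pupdyn-methods.Rmd`) for models, parameter defaults, and
numerical conventions.

## Worked example

```r
library(pupdyn)

des <- session_design()                       # study-condition defaults
b5  <- generate_session(des, age_days = 5,  seed = 1)
b12 <- generate_session(des, age_days = 12, seed = 1)
b5
#> <session_bundle> synthetic P5 s1: <activity_raster> 425 cells x 6000 frames @ 10 Hz (400 pyr, 25 int)
#>   55 movement epochs

sce <- detect_sces(b5$raster, seed = 1)
sce$threshold                                  # co-active cells at chance
#> [1] 9
transients_in_sce_ratio(b5$raster, sce)$mean   # fraction of transients in SCEs
#> [1] 0.333
transient_frequency(b5$raster)$mean            # transients per minute per cell
#> [1] 1.3

inhibiting_movement_proportion(b5)             # movements suppressing activity
#> [1] 0.018
inhibiting_movement_proportion(b12)
#> [1] 0.473
```

At P5 almost no movement is "inhibiting" (1.8% of movements leave fewer
than 40% of window-active cells active after onset) and a third of all
transients fall inside SCEs; at P12 roughly half the movements are
inhibiting — the developmental switch. The PMTH makes the pre-switch
coupling explicit:

```r
p <- pmth_session(b5, cell_types = "pyramidal", seed = 1)
mean(p$median[p$bin_centers < -2])             # baseline % active cells
#> [1] 0.537
max(p$median[p$bin_centers > 0 & p$bin_centers <= 2])   # post-onset peak
#> [1] 2
```

Baseline ~0.5% of pyramidal cells per frame rising ~4-fold after movement
onset, significant against the surrogate band in 19 of the 20 post-onset
bins. On the model side, strong inhibition leaves its signature in the
analytic correlogram:

```r
an <- analytic_rate_correlation(rate_params_strong())
min(an$ee$values[an$ee$lags > 0.5])            # positive-lag undershoot
#> [1] -0.163
```

Fitting the age course of the inhibiting-movement proportion over
synthetic animals aged 5-12 days recovers the designed switch age:
`fit_trend(ages, proportions, "sigmoid")$coefficients[["v50"]]` gives
9.3 days for a generator switch at day 9.

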