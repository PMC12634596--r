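---
title: "Frequency-specific intermuscular coherence of synergistic muscles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-specific intermuscular coherence of synergistic muscles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Muscle synergies — fixed nonnegative weightings across muscles recruited as a
unit — describe *what* the nervous system coordinates; common synaptic input
to motoneuron pools describes *how* that coordination could be implemented.
If synergies are implemented through shared neural drives, muscles recruited
within the same synergy should show stronger intermuscular coherence than
muscles recruited by different synergies, in the frequency bands that carry
those drives. `imcoh` implements the full analysis chain needed to test this
on multi-muscle surface EMG from an isometric multi-directional force task,
together with a synthetic-EMG generator that makes every stage testable with
a known ground truth.

The pipeline has five stages, each a package module:

1. **simulate** — synthetic multi-participant EMG with known synergy
   structure and known band-limited common drives;
2. **synergies** — EMG conditioning, NMF extraction of muscle synergies, and
   three-criterion selection of the number of synergies;
3. **coherence** — Hilbert demodulation, activity gating, Welch coherence,
   Fisher normalization, and phase-randomization surrogate thresholds;
4. **layers** — NMF of concatenated coherence spectra into data-driven
   frequency layers with subject-specific band boundaries;
5. **statistics** — classification of muscle pairs as synergistic or
   non-synergistic and a linear mixed model for the pair-type effect on
   layer-averaged coherence.

# The synthetic-EMG generator

## What it emulates

The study design it mirrors: 8 participants, 17 muscles, 32 force-target
directions approximately uniform on a sphere, 5 repetitions (160 trials per
participant), EMG at 1 kHz, a rest phase followed by a 3-s hold phase.
Defaults in `sim_config()` reproduce these counts; the analyses in
`analysis/` and the acceptance tests run a scaled-down version (4
participants, 12 muscles, 16 directions x 3 repetitions) so the full chain
fits in minutes on one CPU.

Each participant receives a ground-truth weight matrix `W_true` in which
every muscle has one dominant synergy (normalized weight > 0.75, so
synergistic pairs exist under the classification rule) and small weights
elsewhere (< 0.25, so non-synergistic pairs exist). Synergy activation
follows rectified cosine tuning `max(0, baseline + gain * <d, p>)` in the
force direction `d`.

Three design choices deserve explanation because the obvious simpler
alternatives demonstrably fail:

## Why the carrier is a shot-noise process

The coherence pipeline rectifies the raw EMG and then demodulates it by
taking the cosine of the instantaneous Hilbert phase. Both operations are
*even* nonlinearities: a common drive inserted additively into a Gaussian
carrier at band (f1, f2) emerges from this chain at baseband (0, f2-f1) and
at the doubled band (2 f1, 2 f2) — not at its own band. We verified this
numerically; with an additive carrier the band-recovery oracles are
unattainable.

In real surface EMG the shared neural input does not live in an additive
waveform: it modulates the *firing density* of motor units. The generator
therefore builds each muscle's carrier as a train of biphasic MUAP-like
wavelets whose Poisson event intensity is modulated by the muscle's
synergy-weighted mix of band-limited common drives
(`shot_noise_carrier()`, event rate 100/s, intensity
`rate * max(0, 1 + kappa * d(t))`). Rectification converts firing-density
fluctuations into amplitude fluctuations whose timing survives demodulation,
and the resulting intermuscular coherence is confined to the drive band
(measured: magnitude-squared coherence 0.3-0.5 inside the band at
`drive_gain = 0.7`, chance level outside). The event rate matters: at much
higher rates the rectified signal's relative fluctuations shrink, the phase
perturbations become small, and the even `cos(phase)` nonlinearity again
suppresses the first-order (in-band) component — 100 events/s keeps the
modulation deep enough for linear transfer.

`drive_gain` (kappa) is the intensity-modulation depth and simultaneously
the mixing weight against `(1 - kappa) * noise_gain` of private white
carrier noise: at kappa = 0 all pairs are incoherent; in-band coherence
rises monotonically with kappa; at kappa = 1 coherence is high but stays
below 1 because the Poisson sampling itself is private to each muscle —
exactly as in real EMG, where perfect coherence never occurs.

## Why tuning is not purely cosine

Pure cosine tuning of all synergies spans only a 4-dimensional affine space
(intercept plus three direction components), so a dataset generated from 6
synergies with clean cosine activations has numerical rank ~4-5 and no rank
criterion can recover 6. Real directional tuning is only approximately
cosine. The generator adds a persistent per-(synergy, direction) Gaussian
residual map (`tuning_dev`, default 1.0 relative to the tuning gain). The
map is zero-mean, so least-squares preferred-direction fits remain unbiased;
preferred directions come in antipodal pairs (agonist-antagonist
organization), giving a balanced direction set.

## Why there is muscle-level motor noise

With noiseless repetitions the explained-variation curve R2(N) saturates so
close to 1 that the "smallest N with R2 > 0.9" criterion fires below the
generative rank. Real repetitions differ trial to trial, and part of that
variability is private to individual muscles — not expressible by any
synergy combination. The generator adds zero-mean Gaussian variability
(`activation_noise`, default 0.18) to each muscle's envelope per trial.
With the defaults this puts R2(5) ~= 0.88 and R2(6) ~= 0.95 on
one-participant datasets — the same qualitative regime as the study it
emulates, where the selected rank sits just above the 0.9 threshold. Under
these conditions criteria (i) and (ii) agree on the generative count across
seeds, with the uniformity tie-break (iii) rarely needed.

## What the generator does not emulate

No biophysical motoneuron-pool or muscle model, no force/cursor dynamics,
no fatigue, no electrode crosstalk, no artifacts (the study's visual
artifact rejection has no counterpart here), no nonstationarity within the
hold phase. Passing recovery tests on this generator shows the pipeline is
correct and sensitive under its assumptions; it does not show robustness to
crosstalk or nonstationarity in real recordings.

# Conditioning and synergy extraction

Per trial: full-wave rectification; 2nd-order Butterworth low-pass at 5 Hz
applied forward-backward (reflective padding suppresses `filtfilt` endpoint
transients); decimation to 100 Hz by consecutive 10-sample block means
(after the 5 Hz envelope filter the content near the new Nyquist is
attenuated by > 80 dB, and block means have exactly unit DC gain — the
`signal::resample` polyphase routine showed a 5-9 % gain ripple and was not
used); subtraction of the mean rest-phase level per muscle; division by the
MVC; averaging over the hold phase; clipping of negative values at zero
(NMF needs nonnegative input; the source analysis is silent on this case).
The hold average carries a small (< 3 %) downward bias from the filter
settling across the rest-to-hold step; it cancels in all comparisons, which
are ratios or within-dataset contrasts.

NMF uses Lee-Seung multiplicative updates for the Frobenius objective,
uniform random initialization, at most 1000 iterations, relative objective
tolerance 1e-6 checked every 10 iterations, 10 restarts, best restart by
`R2 = 1 - SSE/SST` with SST the squared residual around the per-muscle mean.
The number of synergies combines three criteria: (i) smallest N with
R2 > 0.9; (ii) first N whose least-squares line through
`(n, R2(n)), n = N..muscles` has MSE < 1e-4 (the R2 curve is made monotone
by a running maximum first); (iii) on disagreement, the candidate whose
preferred-direction set has the smaller mean resultant length
(`||sum p_i|| / N` — 0 for a balanced set). The resultant is normalized by N
so candidates of different sizes are comparable; untuned synergies
(negligible fitted gain) are excluded from it.

# Coherence estimation

Demodulation takes the four-quadrant angle of the analytic signal rather
than the two-quadrant arctangent ratio (identical where the latter is
defined, without the spurious ±pi/2 jumps), applies the cosine, and
subtracts the mean. Per trial, a muscle is *recruited* when, for a moving
window of rest-phase length stepping at 0.1 s over the hold phase, at least
75 % of windows have variance at least 1.5x the rest-phase variance. With
the default rest = hold = 3 s there is exactly one window; the 0.3-s rest
option gives 28. Coherence is computed only for pairs of recruited muscles;
other pairs are carried as all-zero spectra.

Welch parameters: 0.2-s Hamming windows, 50 % overlap, FFT length 256 at
1 kHz. This is the only parameter set that yields the printed 15 frequency
bins with centers inside 1-60 Hz (bin width 3.90625 Hz) and gives Ns = 29
segments for a 3-s hold. Fisher normalization is implemented exactly as
printed, `Z = 2 Ns atanh(C)` applied to the magnitude-squared coherence,
with C capped at 1 - 1e-12; the conventional `sqrt(2 Ns) atanh(sqrt(C))` is
available behind a flag for sensitivity checks.

Significance: 100 phase-randomized surrogates per recruited muscle
(independent uniform phases on the positive-frequency components, Hermitian
symmetry preserved, DC and Nyquist left real — the surrogate's periodogram
equals the original's exactly); per pair, the i-th surrogate of one muscle
is paired with the i-th surrogate of the other; the per-bin threshold is the
95th percentile of the 100 surrogate coherences, and bins at or below it are
zeroed. Under independence ~5 % of bins survive, which the test suite
verifies. The threshold is per trial, per pair, per bin; pooling across bins
is a defensible alternative the source leaves open, not taken here.

# Frequency layers

Per participant, the thresholded Z spectra are concatenated into a
15 x (trials x pairs) matrix (zero columns retained) and decomposed by the
same NMF for k = 1..15. `W_c` columns are rescaled to unit maximum (the
NMF scale ambiguity otherwise dominates any across-participant comparison)
and ordered by spectral center of mass, which is also the across-participant
alignment for the selection criterion. The layer count is the deepest interior
local minimum of the mean across-participant SD of the aligned patterns;
without an interior minimum the global minimum is used, ties resolved toward
the smallest k with near-exact reconstruction. Two alternatives were
rejected on measured curves: the *global* minimum lands on k = number of
bins, where one-hot patterns are trivially identical across participants
(SD -> 0) — over-discretization, not consistency (the boundary is not an
interior point, and near-boundary SD values are not strict local minima);
and the *first* interior local minimum latches onto shallow sampling dips
at small k (observed: a dip of 0.15 at k = 3 selected over a true minimum
of 0.02 at the generative k = 6). The deepest-interior-minimum rule selects
the generative layer count stably at the study's scaled-down size.

Bounds: each bin goes to the layer with maximal `W_c` (ties to the
lower-frequency layer); a layer split into several runs keeps its longest
run and donates the others to adjacent layers, so layers are contiguous;
bounds are the half-bin edges around each layer's bin run, clipped to
1 and 60 Hz, so the layers tile the analyzed range. `I_Z` over a layer is
the mean of the bin values whose centers fall in the interval — the
discretization of the printed integral mean.

# Pair classification and the mixed model

Muscle weights are row-normalized to unit squared sum. A pair is
*synergistic* if both weights exceed 0.75 in one common synergy,
*non-synergistic* if in some synergy one exceeds 0.75 and the other is
below 0.25, otherwise *excluded*. The normalization makes these labels
well-defined: no muscle can exceed 0.75 twice (0.75^2 + 0.75^2 > 1), so a
pair can never satisfy both rules in different synergies.

Observations are one row per (participant, trial, pair, layer) with the
layer-averaged `I_Z`; a (pair, trial) spectrum enters only when it has at
least one significant bin (silent spectra would mask the effects — the
inclusion rule is applied per trial; applying it per pair across all trials
is the main alternative reading). The mixed model per layer (and per bin,
on thresholded Z) is

```
iz ~ direction dummies + repetition + pair_type + (1 | participant)
```

fitted by REML with `lme4`, first direction as reference, repetition
numeric, random intercept only, Wald test on the pair-type coefficient,
alpha = 0.05, no multiplicity correction for the per-bin models (the source
reports raw per-bin stars). Type-I calibration of this exact model at
~alpha is part of the test suite.

# Numerical choices and degenerate inputs

- All randomness flows through R's RNG; every analysis entry point is
  seeded. Identical seeds give identical datasets and results.
- All-zero EMG demodulates to zero with a warning; zero rest-phase variance
  is floored at machine epsilon; all-zero activation or coherence matrices
  are rejected (SST undefined); layers with no assigned bin are merged into
  a neighbor with a warning; singular mixed-model fits are reported with a
  flag, not dropped.
- NMF ties and restart noise: R2 curves are monotonized by running maximum;
  reconstruction comparisons across k allow restart-level slack (1e-6).
- Problem sizes in the shipped analyses: 4 participants x 12 muscles x 48
  trials for the coherence/layer stages (about 3 minutes of coherence
  computation and 3-4 minutes of layer sweeps), 1 participant x 17 muscles
  x 160 trials for the synergy-count analysis. These sizes were chosen so
  each recovery result is stable across seeds at desk scale.

# Known limitations

- The SD-based layer-count criterion needs several participants with
  comparable spectral structure; with 2 participants it is noisy, and for
  populations with heterogeneous spectra (e.g. patients) it may have no
  clear minimum.
- Coherence is estimated on a static hold phase; dynamic tasks would need
  time-frequency methods out of scope here.
- The generator's coherence levels (C ~ 0.3-0.5 in-band) are at the upper
  end of physiological intermuscular coherence; effect sizes on synthetic
  data are correspondingly larger than in the study it emulates.
- Wald p-values from the normal approximation are anti-conservative for
  very small numbers of participants; the type-I test covers the regime
  used here (>= 4 participants, effects identified within participants).
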