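---
title: "Phase-based M1-M1 connectivity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based M1-M1 connectivity: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(imcoh)
```

## The scientific problem

Beta-band (13-30 Hz) oscillations over the sensorimotor cortices are
phase-coupled across hemispheres, and interventions such as transcranial
alternating current stimulation (tACS) are hypothesised to change that
coupling. At the sensor level, however, a single cortical source projects
instantaneously to many electrodes (volume conduction), so naive coherence
between a left-M1 and a right-M1 electrode is inflated by zero-lag leakage
that has nothing to do with inter-areal communication.

`imcoh` implements the standard remedy: **imaginary coherence** (ImCoh).
With complex analytic signals $x_i(f, t)$ and $x_j(f, t)$ for two channels,
the trial-aggregated cross-spectral density is
$S_{ij}(f,t) = \langle x_i \bar x_j \rangle$ and

$$\mathrm{ImCoh}_{ij}(f,t) \;=\;
\left| \Im \left( \frac{S_{ij}}{\sqrt{S_{ii}\,S_{jj}}} \right) \right|
\in [0, 1].$$

A zero-lag (purely real) coupling contributes nothing to the imaginary
part, so volume conduction is suppressed; a consistent non-zero phase lag
across trials yields values up to 1. Connectivity between left and right
M1 is summarised as the arithmetic mean of ImCoh over the 49 electrode
pairs formed by a 7-channel cluster centred at C3 (C3, FC3, C1, FC5, CP1,
C5, CP3) and a 7-channel cluster centred at C4 (C4, CP2, CP4, C6, C2, FC6,
FC4). The published cluster list names only six channels around C4; we
complete the "seven electrodes centred at C4" with C4 itself.

## Pipeline stages and their parameters

1. **Filtering** (`bandpass_notch()`): 0.5-95 Hz band-pass plus a 50 Hz
   notch, as a single linear-phase FIR kernel applied by centred FFT
   convolution. The kernel is symmetric, so the filter has exactly zero
   phase -- event timing is never shifted. Measured performance: >40 dB at
   50 Hz, <1 dB ripple from 1 to 90 Hz, DC removed.
2. **Resampling** (`resample_recording()`): to 500 Hz by Fourier-domain
   truncation. This gives exact passband gain and a brick-wall anti-alias
   cutoff at the new Nyquist; because onsets are stored in seconds they
   re-index exactly. The periodic boundary assumption is harmless for
   minutes-long recordings whose epochs sit away from the edges.
3. **Epoching** (`epoch_recording()`): resting data are cut into
   contiguous non-overlapping 2000 ms segments from the recording start
   (the overlap policy is unstated in the protocol; non-overlapping is the
   conservative choice); event data into -2500..4500 ms windows around
   each detected movement onset. Time windows are half-open `[start, end)`
   in samples; frequency-band edges are inclusive.
4. **Artifact handling** (`reject_and_reference()`): trials whose
   peak-to-peak amplitude on any channel exceeds 200 uV (configurable) are
   flagged, then all trials are re-referenced to the instantaneous
   cross-channel average. Visual epoch marking and ICA-based artifact
   subtraction are replaced by this deterministic rule: visual steps are
   not reproducible, and the synthetic data contain no ocular or myogenic
   components. Channel interpolation is correspondingly not implemented.
   Blocks with fewer than 20 surviving trials raise a classed
   "participant excluded" warning, mirroring the minimum-trial rule used
   for cohort exclusions.
5. **Wavelet decomposition** (`build_wavelet_bank()`,
   `tfr_transform()`): complex Morlet wavelets at 4-90 Hz in 1 Hz steps
   (87 frequencies), with cycle counts increasing geometrically over the
   frequency index from 3 to 13. "Logarithmically increasing" cycle counts
   are realized as geometric interpolation over the index; the endpoints
   pin the quoted 3 and 13 either way. Values are sampled on 20 ms grids:
   400-1600 ms within resting epochs (61 points; every point is at least
   3 sigma_t from the epoch edges at every frequency, which the transform
   asserts), and -2000..4000 ms for event epochs (covering both the
   -2000..-1000 ms baseline and the -500..4000 ms window of interest, 226
   points). Wavelets are normalized so a unit sinusoid yields magnitude 1;
   ImCoh is invariant to any per-channel positive rescaling (tested), so
   this convention cannot affect results.

## Two estimators, one formula

The protocol both shows across-trial time-frequency ImCoh maps and feeds
trial-level values into mixed models, and a coherence computed from a
single trial at a single time point is identically 1. The package
therefore provides both reductions explicitly:

- `imcoh_across_trials()` aggregates $S_{ij}$ over trials at each
  (frequency, time) cell -- the map estimator.
- `imcoh_within_trial()` aggregates $S_{ij}$ over the grid points of a
  time window within each trial -- the trial-level estimator feeding the
  long-format table (windows must contain at least 2 grid points).

Event-related maps are baselined by subtracting, per frequency, the mean
over -2000..-1000 ms (`baseline_subtract()`); trial-level event values
subtract the per-trial, per-frequency baseline-window value. Band/period
summaries (`band_period_average()`) use theta 4-7, alpha 8-12, beta 13-30
and gamma 60-90 Hz (the protocol announces "five frequency bands" but
lists these four; a fifth low-gamma band is not created by default) and
the movement periods premove -500..0, move 0..500 and postmove
1500..4000 ms.

## Peak beta and the cluster-based permutation test

`peak_beta()` returns the beta frequency with the largest absolute
baseline-corrected deviation of the connectivity profile, ties broken
toward the lower frequency; `endo_exo_diff()` subtracts the 20 Hz
stimulation frequency. The source text defines the peak via "greatest
ERD/ERS" but elsewhere names it "the ImCoh peak beta frequency"; the ImCoh
reading is implemented (a power-map reading is not). Because ImCoh here is
a property of the C3-C4 cluster *pair*, peak records carry that single
region rather than per-hemisphere values.

`permutation_test()` relates per-subject pre-stimulation frequency
differences to per-subject connectivity-change maps: Spearman's rho (with
average ranks and a t-approximation p-value on n-2 degrees of freedom) at
every cell, cells with p < 0.05 clustered under 4-neighbour
spectro-temporal adjacency with positive and negative correlations kept
separate, cluster mass = sum of |rho|, and a null distribution of maximum
cluster masses over permutations of the subject order (all n!
permutations when fewer than `n_perm` exist). Clusters whose mass exceeds
the 97.5th percentile of the null are significant; a permutation p-value
`(1 + #{null >= mass}) / (1 + n_perm)` is reported alongside. The
percentile rule is applied per sign against the pooled max null, and the
resulting family-wise error rate (~5% two-sided) is verified by
simulation in the test suite rather than assumed. Neither the permutation
count nor the adjacency scheme is stated in the protocol; `n_perm = 1000`
and orthogonal adjacency are configuration defaults. Inside the
permutation loop, thresholding |rho| at the critical value of the
t-approximation replaces per-cell p-values; the two are provably
equivalent and the equivalence is unit-tested.

Change maps feeding the test are percent changes `100 (b - a) / |a|`
between time-point maps, computed on the *unbaselined* across-trial maps:
baseline-subtracted values cross zero, where relative change is
ill-defined. A guard treats |a| below 1e-6 of the map's dynamic range as
undefined (NA) rather than letting ratios explode.

## The synthetic study and its ground truth

`generate_recording()` builds 1000 Hz, 14-channel recordings in which two
sinusoidal 20 Hz sources drive the C3 and C4 clusters on a 1/f Gaussian
noise floor. The per-trial inter-cluster phase lag is von Mises
distributed with mean `phi` and concentration `kappa`, constant within a
trial; the across-trial expectation of the estimator is then available in
closed form,

$$E[\mathrm{ImCoh}] = |\sin\varphi| \cdot \frac{I_1(\kappa)}{I_0(\kappa)},$$

which `expected_imcoh()` evaluates and the test suite verifies against
direct numerical integration of the von Mises resultant. Event mode adds
the movement triad -- pre-movement ERD, movement ERD, post-movement ERS --
as a piecewise amplitude envelope with half-cosine transitions (defaults
0.6, 0.4 and 1.5 relative to baseline; transition width 250 ms, centred
between the analysis windows), movements every 10 s, and a force channel
with one deterministic half-cosine pulse (200 ms rise) per movement, so
threshold-crossing onset detection is exactly checkable.
`study_design()` crosses participants with intensities (sham, 0.5, 1.0,
1.5 mA) and time points (pre, post1, post2); an `effect_map` multiplies
`kappa` per cell, standing in for stimulation after-effects. The default
map emulates the qualitative published pattern (delayed increase at
0.5 mA, suppression at 1.0/1.5 mA) but its magnitudes are free parameters
of the simulation -- the source reports no generative effect sizes -- and
they are not estimates.

Defaults chosen once for realism: source amplitude 10 uV, noise exponent
1, source-to-noise amplitude ratio 1, `phi = pi/2` (the lag most visible
to ImCoh), `kappa = 4` (moderately consistent coupling, R ~ 0.86).

What the generator does *not* emulate: ocular/myogenic artifacts, bad
channels, realistic head geometry, or the tACS waveform itself. Passing
tests therefore demonstrate estimator and inference correctness, not
robustness to real-world artifact structure.

**A deliberate limitation worth knowing:** with exactly two generative
sources and homogeneous gains, the average reference turns the two
clusters into zero-lag mirror images and ImCoh collapses to zero -- an
algebraic property of rank-2 data, not an estimator failure. Real
high-density EEG has many sources and heterogeneous topographies, where
the average reference is innocuous. Parameter-recovery tests therefore
run on unreferenced epochs (and at a source-to-noise ratio of 50, where
the noise-free closed form applies); the full pipeline keeps the average
reference for its intended use on study-like data.

## Numerical choices

- Wavelet convolution is frequency-domain multiplication after symmetric
  zero-padding (mixed-radix FFT lengths), equal to direct convolution to
  1e-10 and unit-tested against it; kernels are truncated at 5 sigma_t.
- The 97.5th percentile of the null uses `quantile()` type 7 (the R
  default).
- Ties in Spearman ranks take average ranks; an exactly constant vector
  has no defined rank correlation and is flagged NA, never guessed.
- Cluster tie-breaks: `peak_beta()` takes the lowest frequency on exact
  ties; cluster lists are ordered by decreasing mass.
- Degenerate inputs error loudly: empty force traces, epochs outside the
  recording, windows with fewer than 2 grid points, all-rejected trial
  sets, misaligned subject identifiers.

## Problem sizes used by the tests and the acceptance script

Simulation sizes are chosen so the whole suite runs on a single CPU in
minutes while keeping Monte-Carlo error far below the tolerances tested:
parameter recovery uses 500 trials per (phi, kappa) condition with a
3-Monte-Carlo-SE band computed by numerical integration; null calibration
uses 500 independent datasets of n = 20 subjects on a reduced 27 x 26
grid with 500 permutations each; power uses 100 datasets with a planted
rho ~ 0.8 beta-band block; the end-to-end determinism check uses a
2-participant study with 5 resting and 4 event trials per block. The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
at comparable sizes from a caller-supplied seed.

## Interfaces

Recordings round-trip through EDF+ (`write_edf()` / `read_edf()`): 16-bit
continuous EDF with per-channel symmetric physical scaling and an
`EDF Annotations` signal carrying one `movement` time-stamped annotation
per onset. Pipeline artifacts are plain text where determinism matters --
the long-format trial table, peak-beta records and rejection report as
CSV, cluster results and configuration as JSON -- plus per-recording
ImCoh maps as RDS under `maps/`. `run_pipeline()` executes the whole
chain and is byte-reproducible given the same configuration; with fewer
than four participants the correlation stage is skipped and logged, since
a rank correlation over fewer subjects is meaningless.
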