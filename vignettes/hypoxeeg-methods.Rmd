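---
title: "Methods: spectral, aperiodic and network analysis of two-condition resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral, aperiodic and network analysis of two-condition resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hypoxeeg` implements a complete analysis chain for paired two-condition
resting-state EEG studies — the motivating design is sea level versus acute
high-altitude hypoxia in the same subjects — together with a synthetic-data
generator that makes every stage of the chain verifiable by parameter
recovery. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic validation
does and does not establish about real data.

## The measurement model

Each recording is a 64-channel, average-referenced multichannel time
series. The analysis extracts four families of quantities per subject and
condition:

1. **Relative band power.** The PSD is estimated per channel with Welch's
   method (4-s Hann windows, 50% overlap, hence 0.25 Hz resolution) and
   integrated by the trapezoid rule over the canonical bands
   δ 0.5–4, θ 4–8, α 8–13, β 13–30 Hz, normalized by the 0.5–30 Hz
   broadband integral. Bands are half-open `[low, high)`, so boundary
   frequencies are counted once and the four bands tile the broadband
   range: per channel the four relative powers sum to 1. Because the
   measure is a ratio of integrals it is invariant to global amplitude
   rescaling, but it is *compositional*: any manipulation that moves
   absolute power in one band necessarily moves the relative power of the
   others.

2. **Aperiodic (1/f) exponent.** The PSD between 4 and 40 Hz is decomposed
   into an aperiodic component and Gaussian oscillatory peaks, in the
   spirit of spectral parameterization ("specparam"-type) models. The
   exponent convention is χ ≥ 0 with PSD ∝ f^−χ: the log-log slope is −χ
   and a *flatter* spectrum means a *smaller* χ. The fit is knee-free —
   appropriate in 4–40 Hz, where resting spectra rarely show curvature —
   and proceeds as: (i) a robust lower-envelope line fit in log10-power
   versus log10-frequency (ordinary least squares, then refit on the
   points whose clipped positive residual falls at or below the 2.5th
   percentile, which makes the line ride the valleys between peaks);
   (ii) iterative extraction of up to 6 Gaussian peaks, each required to
   exceed 2 residual standard deviations and 0.05 log10 units, with widths
   constrained to 0.5–12 Hz; (iii) a final aperiodic refit on the
   peak-stripped spectrum. The peak model is Gaussian in (linear
   frequency, log power); widths below 0.5 Hz would chase noise bumps at
   the 0.25 Hz grid spacing, widths above 12 Hz would absorb the aperiodic
   curvature itself.

3. **wPLI functional connectivity.** Signals are band-filtered with a
   zero-phase 3rd-order Bessel band-pass, cut into non-overlapping 12-s
   epochs, and cross-spectra are estimated with 7 DPSS tapers
   (time-bandwidth 4). The weighted phase lag index per channel pair is
   |E{Im S_xy}| / E{|Im S_xy|}, evaluated per frequency bin and averaged
   with equal weight across the band's bins. wPLI discounts zero-lag
   interactions by construction — the imaginary cross-spectrum of an
   instantaneous mixture is zero — which is the reason it is preferred for
   sensor-space analysis, where volume conduction dominates. Two
   expectation scopes are provided: the default pools all epoch × taper
   estimates in one pass (the lower-variance estimator), while
   `per_epoch = TRUE` computes a wPLI matrix within each epoch and
   grand-averages afterwards. Both are tested; at the study's 25 epochs
   the pooled estimator has a visibly lower noise floor (the floor of the
   per-pair wPLI scales like the reciprocal square root of the number of
   pooled estimates). Pairs with a numerically zero denominator (identical
   or purely zero-lag-mixed signals) are set to 0 and counted.

4. **Graph topology.** The weighted wPLI matrix is proportionally
   thresholded — the top p fraction of connections is kept and binarized,
   for p from 5% to 40% in 1% steps — and on each binary graph the package
   computes global/nodal efficiency (mean inverse BFS shortest-path
   length; unreachable pairs contribute zero), transitivity (closed over
   connected triples, collectively normalized), nodal clustering
   (per-node normalization; degree < 2 gives 0), and degree. Each metric
   is summarized by the trapezoidal area under its threshold curve, which
   removes the dependence on any single threshold. The AUC is *not*
   divided by the 0.35 range width; only differences and correlations of
   AUCs are used downstream, so the convention is harmless, but it is
   fixed and documented. Edge count at threshold p is `round(p·n(n−1)/2)`
   (half-up), with ties broken by ascending (row, column) index — this
   makes edge sets deterministic and nested across thresholds, which in
   turn makes the efficiency-versus-threshold curve monotone.

Overall FC is the mean off-diagonal wPLI of the *non-thresholded* weighted
matrix; nodal strength is its row sums. Graph metrics are computed on the
thresholded binarized matrices, keeping changes in topology separate from
changes in overall connectivity strength. Region-level values are the mean
of channel-level values over a fixed five-region partition of the montage
(frontal, frontocentral, centroparietal, temporal, occipitoparietal).
No published standard assigns the 64 labels to these five regions, so the
partition used by `default_region_map()` is a package convention and can
be overridden.

## The inference layer

Condition contrasts (altitude minus sea level) are tested with a paired
sign-flip permutation test: the observed statistic is the mean paired
difference; the null distribution flips each subject's condition labels
independently (10,000 surrogates by default, exhaustive enumeration of all
2^n patterns available for n ≤ 20). The design is within-subject, so the
paired scheme is the default; an unpaired full-reshuffle variant is kept
behind the `scheme` argument for sensitivity analysis. Monte-Carlo
p-values use the add-one rule and are therefore never exactly zero. Tests
are two-sided throughout.

Effect sizes are Cohen's D in the pooled two-sample form — the standardized
difference of condition means — rather than the paired dz. With strongly
correlated conditions the pooled form yields small D alongside small paired
p-values, which is the regime such studies report; `form = "dz"` is
available.

Benjamini–Hochberg correction is applied within each analysis family,
defined as one metric at one scope level (for example, all four bands of
global relative power, or all region × band cells of nodal clustering).
This mirrors per-figure reporting; the family definition is a convention
the data cannot determine, so it is exposed rather than hard-coded deeper.

Age enters twice: as Pearson correlations between age and the headline
metrics (both conditions pooled), and as a confound to be removed —
metrics are replaced by their residuals from an ordinary least-squares
regression on age computed on the pooled observations, re-paired by
subject, and the permutation contrast repeated.

## The generative model

The generator exists to make the chain falsifiable: every downstream
quantity has a programmed ground truth. Each channel is the sum of

* an aperiodic 1/f background synthesized by frequency-domain shaping
  (amplitudes f^(−χ/2), random phases), which has *exactly* the target
  exponent in expectation — an AR-process approximation would not — and is
  scaled so that its 0.5–30 Hz variance is 1. Without that band
  normalization the in-band background would depend on recording length,
  because a pure f^−χ process hides most of its variance below the
  analysis range;
* band-limited Gaussian oscillations (white noise shaped by a Gaussian
  spectral window) at 2, 6, 10 and 20 Hz with amplitudes 0.35, 0.30,
  0.50 and 0.20 relative to the unit in-band background — α dominant,
  β weakest, peak heights chosen so that spectra look like resting EEG and
  the peak-stripping stage is genuinely exercised;
* shared phase-lagged narrowband sources injected into designated channel
  pairs. The phase lag is a constant rotation of the source's positive
  frequencies (not a time delay), keeping the lag frequency-independent
  within the band. Coupling strength is expressed relative to the band's
  total background RMS. Because *both* members of a study pair carry
  independent background, the wPLI response grows with the *square* of
  the shared-to-background amplitude ratio — a pair needs strength around
  0.5 for a clearly supra-floor wPLI, which informed the defaults below.

The default study conditions are 16 subjects, ages uniform in 19–45,
recorded in both conditions with identical per-subject age (the paired
design), 300 s at 256 Hz. The baseline exponent is 1.5 at the youngest
age, declining by 0.01 per year (so the oldest subjects are ~0.26 flatter),
with a between-subject SD of 0.05. Altitude applies: exponent −0.2, alpha
power ×0.7, delta power ×1.4, delta coupling ×1.6, theta coupling ×2.5.
The coupling layout is deterministic: δ pairs link frontocentral with
centroparietal/temporal sensors (strength 0.50), θ combines within-region
chains (0.50) with weak spokes from four midline hubs FCz/Cz/CPz/Pz
(0.22), and α pairs sit posteriorly (0.40). At sea level the θ spokes are
below the wPLI noise floor; the altitude boost lifts them into the
proportionally-thresholded edge set, which reshapes the binarized θ graph
toward a hub-centric, shorter-path topology — that is the mechanism by
which the programmed "θ integration increases at altitude" effect reaches
global-efficiency AUC, a metric that is blind to uniform weight increases
because proportional thresholding fixes the edge count.

Two knock-on effects of this model are worth stating because they are
physics, not bugs. First, relative power is compositional: flattening the
spectrum (χ −0.2) by itself shifts relative power from δ toward β, so at
default settings β relative power shows a genuine (programmed, if
indirect) increase at altitude. The α-band coupling SNR also shifts
slightly, because the α oscillation shrinks at altitude while the shared
α sources scale with the band background; truly untouched cells — β
connectivity and α/β topology — are the appropriate negative controls. Second, the
θ coupling boost raises θ overall FC as well as θ efficiency — a single
underlying manipulation surfacing in two measures, as it would in real
data.

What the generator does *not* emulate: ocular/muscle artifacts (the ICA
cleaning step of real pipelines is deliberately out of scope and replaced
by a pass-through hook), volume conduction (so sensor-space wPLI floors
here are purely finite-sample), spatially graded oscillation topographies,
non-stationarity within a recording, and any knee in the aperiodic
spectrum. Passing the recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to real-world
artifacts.

## Numerical choices

* **Zero-phase filtering.** All filters are applied forward-backward with
  odd reflection padding. The motivation is that wPLI is a phase metric:
  causal filtering would add frequency-dependent phase shifts
  *identically* to all channels (harmless for lags) but its transients
  and group delay complicate epoching; zero-phase application is the
  conservative choice. It squares the magnitude response, so the
  nominal −3 dB edges of the 3rd-order Bessel become −6 dB after the two
  passes; band integrals are computed from the Welch PSD of the broadband
  signal, not the band-filtered signals, so band power is unaffected.
* **FIR broadband conditioning** uses a windowed-sinc design with a
  transition width of about half the low edge, applied by FFT convolution
  (kernels reach a few thousand taps at 0.5 Hz edges).
* **Resampling** decimates with a zero-phase FIR anti-alias filter at 0.9
  of the target Nyquist (integer factors) or polyphase rational
  resampling otherwise; upsampling is refused.
* **DPSS tapers** are computed as eigenvectors of the standard symmetric
  tridiagonal operator and cached per (length, bandwidth, count); the
  dense eigendecomposition for 12-s epochs takes a few seconds once per
  session.
* **Degenerate cases** are pinned down by convention and tested:
  zero-denominator wPLI pairs → 0; edgeless graphs → efficiency 0;
  all-degree-≤1 graphs → transitivity 0; nodes with degree < 2 →
  clustering 0; unreachable pairs contribute zero inverse distance.
* **Determinism.** Every stochastic stage takes a seed; study-level
  randomness is derived from one master seed via a splitmix-style child
  seed function, so per-subject recordings are reproducible independently
  of generation order, and the permutation tests of each table cell get
  their own derived seed so results do not depend on evaluation order.

## Problem sizes used by the tests

The test suite validates estimator correctness at reduced scale (8–16
channels, 24–120 s, 128 Hz) and runs the full 16-subject, 64-channel,
300-s study once end to end; exponent-recovery checks use 20 replicates
per condition and the permutation calibration uses 2000 null replicates at
1000 permutations each. These sizes were chosen as the smallest at which
the quantities under test are stable enough to assert tight tolerances.

## Known limitations

* The five-region montage partition is a convention; region-level results
  depend on it.
* Exact specparam hyperparameters vary across published pipelines; the
  defaults here (threshold 2 SD, ≤6 peaks, widths 0.5–12 Hz) are
  documented and configurable, and the exponent is the robust quantity —
  peak parameters should be treated as descriptive.
* The pooled-epoch wPLI estimator is the default even though per-epoch
  averaging is closer to some published descriptions; both are available
  and agree to well within the between-subject variability at 25 epochs.
* Cohen's D in the pooled form understates the within-subject effect
  size; it is reported for comparability, not as the basis of the test
  (the permutation p is).
* EDF/BDF ingestion supports continuous uniform-rate recordings without
  annotation channels — sufficient for pre-cleaned exports, not a general
  EDF+ reader.
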