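---
title: "Methods: Korotkoff-sound processing, features and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Korotkoff-sound processing, features and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Korotkoff sounds (KS) are the pulse-synchronous sounds heard over the
brachial artery while a blood-pressure cuff deflates: a train of 10-40
short (under ~100 ms) damped-oscillation pulses whose loudness rises and
then falls across the deflation, with silent phases before and after.
Because KS arise from the interaction of blood flow with the artery wall,
their spectral and beat-to-beat statistics carry information about cardiac
output, and changes in those statistics can separate healthy subjects from
patients with chronic heart failure (CHF). `korosound` implements the full
chain from raw mono WAV recordings to a classification report, plus a
synthetic-record generator that supplies ground truth for every stage.

# Processing model

## Working rate

All processing happens at **800 Hz**. KS energy is concentrated below
400 Hz, and 800 Hz is the unique rate at which a 3-level wavelet-packet
tree produces eight sub-bands of exactly 50 Hz each (0-50 through
350-400 Hz), so the seven named energy bands at and above 50 Hz fall
precisely on tree leaves. Input records at other rates are polyphase-FIR
resampled (anti-aliased, so no out-of-band energy corrupts the band
ratios). Records are peak-normalised at load; every downstream feature is
therefore invariant to recording gain, which the test suite asserts on the
full 46-feature vector.

## Wiener denoising

The minimum-mean-square-error criterion is realised as a frequency-domain
Wiener filter: 40 ms Hann frames at 50% overlap, per-bin gains
$\xi/(1+\xi)$ with the a-priori SNR $\xi$ tracked by the decision-directed
rule (smoothing 0.98), a gain floor of 0.05 to avoid musical noise, and
overlap-add resynthesis normalised by the accumulated squared window so
that unit gain reconstructs the input exactly. The noise power spectrum is
the average periodogram of the silent lead-in (first 0.5 s by default) -
KS measurements always begin in silence before the first sound appears.
Gains never exceed 1, so denoising can only remove energy; a zero noise
profile passes the record through bit-faithfully (to ~1e-15).

## Shannon-energy envelope and segmentation

The record is cut into 40 ms frames with 50% overlap and each frame's
Shannon energy $E = -\tfrac1N \sum z_i^2 \ln z_i^2$ is computed. The
normalisation $z = x / \max|x|$ is taken **once over the record**, not per
frame: the Shannon transform's value lies in emphasising mid-amplitude
oscillation over both faint noise and isolated spikes, and renormalising
every frame to unit peak would erase exactly the amplitude contrast the
envelope must encode (a silence-only frame would be rescaled to look like a
pulse). The `shannon_energy()` function still exposes the self-normalising
form for single-frame use; the envelope path passes globally normalised
frames. The raw envelope is then z-scored (population standard deviation,
so the two-point series {0, 2} maps exactly to {-1, 1}).

Anchor points - one per Korotkoff sound - are local maxima of the
normalised envelope at or above 0.2 x its maximum peak. Because the
envelope is zero-mean, candidates must additionally be positive; a
fractional threshold on a signed series is otherwise ill-posed for
near-flat envelopes. Anchors closer than 100 ms are merged greedily left
to right, the taller envelope value surviving (the merge is a correction
for over-localisation, so the most salient peak should represent the
sound). Friction artifacts - isolated clicks from the stethoscope
diaphragm rubbing the skin during the silent phases - are screened by a
quasi-periodicity rule: the longest run of consecutive anchors whose gaps
lie in [0.3 s, 2.0 s] (40-200 beats/min) is taken as the KS train, and
anchors further than 2.0 s from that run are dropped. The record span is
then delimited as B = first anchor - 300 ms, E = last anchor + 500 ms,
clamped to the recording; per-beat windows extend 100 ms before to 300 ms
after each anchor (KS pulses are impact-led, so most energy trails the
envelope peak).

## The 46 features

Four blocks, all computed on the denoised signal restricted to [B, E]:

**Energy (19).** A 3-level orthogonal wavelet-packet decomposition
(Daubechies-8; orthogonality gives exact Parseval energy conservation,
asserted at 1e-6 relative) yields eight 50 Hz bands, re-labelled from tree
(Paley) order to ascending frequency order - each high-pass-plus-decimation
stage mirrors the spectrum, a classic correctness trap checked by
band-limited tone tests. The seven global ratios
$S_\mathrm{total}(j) = E(j)/E_\mathrm{total}$ are over the 50-400 Hz bands
of the whole span. Per beat, `en` = E(50-100)/E(50-400) and `en_h` =
E(150-400)/E(50-400); the 100-150 Hz band belongs to neither ratio, so
`en + mid + en_h = 1`. The spread/extremum features reconcile two scales:
`std_enr`, `std_enr_h` and the `enr`/`enr_h` extrema are computed on the
raw fractions x100 (percent, so `enr_max` can sit just below 100), while
`std_Ep`, `std_TM` and the `Ep`/`TM` extrema use the mean-normalised
series x100 (so a perfectly regular train scores exactly 100, and values
slightly above 100 are possible). Standard deviations are sample
(n-1) deviations.

**Statistical (12).** Mean, median, standard deviation, mean absolute
deviation, quartiles (linear interpolation), IQR, standardised skewness,
Pearson (non-excess) kurtosis, and the dominant 50-400 Hz periodogram
peak: its frequency, its power as a fraction of total periodogram power
(`dom_freq_mag`; the normalisation keeps the feature gain-invariant), and
its power as a fraction of 50-400 Hz power (`dom_freq_ratio`).

**Entropy (2).** Shannon entropy (bits) of a 128-bin amplitude histogram
and of the periodogram normalised to a probability distribution. A pure
tone scores near-zero spectral entropy, broadband noise scores high.

**MFCC (13).** Frame-wise (40 ms, 50% overlap, FFT zero-padded to 256
points) triangular Mel filterbank of 26 filters spanning 0-400 Hz, log
filter energies, then the order-13 DCT
$c(n_1)=\sum_m \log E(m)\cos\!\big(\tfrac{m-0.5}{M}n_1\pi\big)$, averaged
over frames. Filter energies are floored at $10^{-12}$ of the frame total;
a *relative* floor keeps the coefficients exactly gain-invariant (a gain
shifts all log energies by one constant, whose DCT vanishes for
$n_1 \ge 1$). The implementation is checked against a brute-force oracle
(naive DFT, explicit double loops) to 1e-9.

Feature sets: A = energy + statistical + entropy (33), B = statistical +
entropy + MFCC (27), C = all 46.

# Classification

Twelve presets share one protocol: stratified 80/20 split, min-max scaling
fitted on training rows only (test values are not clipped), 10-fold
stratified cross-validation on the training split with scaling refit
inside each fold, then a final fit and test evaluation. CHF is the
positive class. The preset hyperparameters - fine/medium/coarse trees
capped at 100/20/4 splits, k = 1/10 Euclidean and k = 10 cosine
neighbours (ties broken by the nearest neighbour's class), Gaussian and
Gaussian-KDE naive Bayes (rule-of-thumb bandwidth), and 30-learner
AdaBoost-on-stumps, bagged-tree and RUSBoost ensembles - are fixed in code
and recorded in each model's metadata.

The headline classifier is the **Bayesian-optimised RBF SVM**: a
Gaussian-process surrogate (squared-exponential kernel, length scale 0.2 on
the unit square, small noise nugget) with expected-improvement acquisition
over 500 random candidates per iteration, a 5-point Latin-hypercube
initial design and 30 total objective evaluations, searching
$\log_{10} c \in [-3, 3]$ and $\log_{10} \gamma \in [-4, 1]$, where $c$ is
the soft-margin penalty and $\gamma$ the RBF coefficient
$K(u,v)=\exp(-\gamma\lVert u-v\rVert^2)$ (the "kernel scale" axis is
searched directly as $\gamma$). The objective is 10-fold CV accuracy. The
trajectory is deterministic given the seed, and the best observed
objective is non-decreasing by construction.

Metrics follow the standard confusion-matrix identities (Acc, Se, Sp, Ps,
F1 = 2·Se·Ps/(Se+Ps)), asserted on every `metrics_report()` construction.
The worked example TP=29, FN=5, TN=22, FP=4 gives Acc 0.8500, Se 0.8529,
Sp 0.8462, Ps 0.8788 and F1 0.8657; note that an F1 of 0.882 sometimes
quoted next to these four values does not satisfy the F1 identity, so the
formula is implemented as defined and the discrepancy documented rather
than imitated.

# The synthetic generator

`generate_record()` emulates a cuff-deflation measurement: a silent
lead-in (2 s), `n_beats` pulses at jittered periods (default 0.8 s mean,
0.05 s sd), each pulse a sum of exponentially damped sinusoids - an impact
component near 80 Hz plus optional mid (130 Hz) and murmur (250 Hz)
components - Gaussian-windowed to under 150 ms, a rise-then-fall
deflation amplitude profile (Beta-shaped, floor 0.35 so the faintest beats
stay audible), white Gaussian noise at a programmed SNR (default 20 dB),
and Poisson-count friction clicks confined to the silent phases. Per-beat
lognormal jitter of the component amplitudes drives beat-to-beat
variability of the energy ratios; each pulse is then renormalised to the
profile amplitude so the jitter shapes the band mix without making beats
inaudible. Ground-truth beat times are the pulse energy centroids.
`generate_cohorts()` adds a +/-10% per-record jitter of the continuous
spec parameters for within-class variance. The healthy and CHF templates
differ in the direction observed when cardiac output falls: energy moves
out of 100-200 Hz into 50-100 Hz and above 200 Hz, and beat-to-beat
energy-ratio variability shrinks.

What the generator does **not** emulate: cuff-pressure dynamics, real
friction/motion artifact morphology inside the KS train, respiration or
pink physiological noise (a flag exists for none of these), and the
inter-subject variability of real cohorts. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline recovers programmed
signal statistics and that the classifier stack behaves correctly - not
that clinical accuracy on real recordings is reproduced.

# Numerical choices and degenerate inputs

- Envelope z-scoring uses the population standard deviation; a constant
  envelope is an error ("degenerate envelope").
- All-zero frames have Shannon energy 0 (the 0·log 0 convention); an
  all-zero record refuses feature extraction.
- Wavelet-packet inputs are zero-padded to a multiple of 8 samples
  (periodised transform; padding adds no energy).
- Fewer than 3 anchors skip artifact screening with a warning; fewer than
  2 beats abort extraction ("insufficient beats").
- Constant training columns scale to 0 with a warning; degenerate signals
  set skewness/kurtosis to 0 with a warning.
- Equal-rate resampling short-circuits, so it is bitwise idempotent.
- All randomness flows through explicit integer seeds; generators save and
  restore the caller's RNG state.

# Problem sizes used in validation

The shipped tests and the acceptance script validate on: 50 records at
15 dB SNR for segmentation recovery (about 1,250 beats), a contrasted
cohort of 50 + 50 records and a null cohort of 100 + 100 records for the
classification experiments, and 50-record batches for parameter-recovery
checks (interval variability within +/-3 of the programmed 15; band share
within 10 percentage points of the programmed FFT target, the bound set by
wavelet band leakage). These sizes give stable averages while keeping a
full run within a few minutes on one core.

# Known limitations

- The artifact screen assumes one contiguous KS train; a measurement
  interrupted mid-deflation could lose the shorter half.
- Anchor times are quantised to the 20 ms envelope hop.
- The BO surrogate uses fixed GP hyperparameters rather than marginal
  likelihood fits; with only 30 evaluations in 2-D this is ample, but a
  higher-dimensional search would want a fuller GP.
- The kernel-density naive Bayes evaluates one KDE per feature per class
  per test row; it is the slowest preset on large cohorts.
- Feature extraction assumes at least two detected beats and non-zero
  50-400 Hz energy; heavily clipped or DC-dominated recordings fail with
  informative errors rather than producing silent nonsense.
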