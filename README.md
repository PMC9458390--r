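# korosound

Signal processing, feature extraction and classification for **Korotkoff
sounds (KS)** — the pulse-synchronous sounds recorded over the brachial
artery during cuff-deflation blood-pressure measurement. KS recordings are
trains of 10–40 short damped pulses separated by quasi-periodic intervals,
bracketed by silent phases. Their band-energy distribution and beat-to-beat
variability shift with cardiac output, which makes them a candidate
non-invasive screen for chronic heart failure (CHF). This package is for
researchers in cardiovascular acoustics who want a complete, testable KS
pipeline, and for anyone needing a controlled synthetic KS test bed.

## What it implements

1. **Denoising** — a frequency-domain Wiener filter (40 ms Hann frames, 50%
   overlap, decision-directed a-priori SNR, gain floor 0.05) with the noise
   power spectrum estimated from the silent lead-in.
2. **Segmentation** — the normalised Shannon-energy envelope
   `P_j = (E_j − mean E)/std E` with `E_j = −(1/N) Σ z² ln z²`; anchor
   points are envelope peaks ≥ 0.2 × the maximum, anchors closer than
   100 ms merge, isolated friction clicks are screened by a
   quasi-periodicity rule, and the record span runs 300 ms before the first
   to 500 ms after the last anchor.
3. **Features (46)** — 19 energy features from a 3-level Daubechies-8
   wavelet-packet decomposition into eight 50 Hz bands at the 800 Hz
   working rate (seven global ratios `S_total(j) = E(j)/E_total` plus
   spreads/extrema of the per-beat low-ratio `en = E(50–100)/E(50–400)`,
   high-ratio `en_h = E(150–400)/E(50–400)`, mean-normalised total energy
   `Ep` and interval `TM` series); 12 time/frequency statistics; signal and
   spectral entropy; 13 MFCCs
   `c(n₁) = Σ_m log E(m) cos((m−0.5)/M · n₁π)`.
4. **Classification** — a Bayesian-optimised RBF SVM (Gaussian-process
   surrogate, expected-improvement acquisition, 30 evaluations over
   `log₁₀c ∈ [−3,3]`, `log₁₀γ ∈ [−4,1]`) plus eleven baseline presets
   (fine/medium/coarse decision trees, three KNN variants, two naive
   Bayes, three 30-learner ensembles), evaluated by Acc, Se, Sp, Ps and
   F1 = 2·Se·Ps/(Se+Ps) with CHF as the positive class, under an 80/20
   stratified split with 10-fold cross-validation.
5. **Valsalva analysis** — paired before/after variation
   `V = (Ns − Vm)/Ns × 100` of the 19 energy features.
6. **Synthetic records** — damped-sinusoid pulse trains with programmable
   band mix, period jitter, deflation amplitude profile, noise SNR and
   friction clicks, with ground-truth beat times.

## Worked example

```r
library(korosound)

g   <- generate_record(healthy_spec(), seed = 42)   # synthetic KS record
g$record
#> <audio_record> synthetic-42: 18912 samples @ 800 Hz (23.64 s), label=unlabeled

seg <- segment_record(denoise_record(g$record))
seg
#> <record_segmentation> 25 beats, B=1.72 s, E=21.86 s, mean Ti=0.806 s

fv <- extract_features(g$record)
round(fv[c("Stotal_50_100", "std_enr", "enr_max", "TM_max",
           "dom_freq", "H_freq", "c1")], 2)
#> Stotal_50_100       std_enr       enr_max        TM_max      dom_freq
#>         81.18          9.25         87.89        114.17         85.50
#>        H_freq            c1
#>          9.53          5.72
```

All 25 programmed beats are recovered (`B`/`E` bracket the train by
0.3/0.5 s); 81% of the 50–400 Hz energy sits in the 50–100 Hz band (the
healthy template's impact component), the per-beat low-frequency ratio
peaks at 87.9%, the interval series tops out 14% above its mean, and the
dominant spectral peak is at 85.5 Hz.

Classification metrics come from confusion counts:

```r
metrics_report(TP = 29, FN = 5, TN = 22, FP = 4)
#> <metrics_report> TP=29 FN=5 TN=22 FP=4 | Acc 0.8500 Se 0.8529 Sp 0.8462 Ps 0.8788 F1 0.8657
```

A full experiment — cohort simulation, feature extraction, and the
12-classifier × 3-feature-set grid — is three calls:

```r
cohort <- generate_cohorts(50, healthy_spec(), chf_spec(), seed = 11)
tbl    <- extract_feature_table(cohort)
run_experiment(tbl, seed = 3)
```

A thin command-line wrapper over the same functions ships in
`inst/cli/korosound` (subcommands `simulate`, `denoise`, `segment`,
`extract`, `valsalva`, `run`).

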