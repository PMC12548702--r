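# ioitrf

Does the brain's response to a sound depend on how long ago the previous
sound ended? In continuous, naturalistic soundscapes the auditory evoked
N1/P2 complex is *attenuated* when sound events follow each other closely:
the shorter the inter-onset interval (IOI), the smaller the response.
`ioitrf` is an R toolbox for quantifying this adaptation from continuous
audio and EEG, aimed at auditory/cognitive neuroscientists working with
encoding models of naturalistic listening.

## What it computes

The pipeline chains five stages:

1. **Onset detection** — three acoustic novelty functions (local energy,
   spectral flux, complex-domain prediction error), each log-compressed
   (`log(1 + γx)`, γ = 10), min-max normalized, averaged, and peak-picked
   with an adaptive threshold (Gaussian smoothing σ = 4 samples, running
   median over 1024 samples, offset `mean(x) + 0.05`).
2. **IOI binning** — the interval to the preceding onset is computed per
   event (intervals > 10 s excluded); events are partitioned into 2–8 bins
   with *uniform event counts* (quantile binning).
3. **TRF estimation** — the EEG `r(t, c)` is modelled as a lagged linear
   (forward) model of the binned onset features `s(t − τ)`:

   `r(t, c) = Σ_τ ω(τ, c) s(t − τ) + ε(t, c)`

   with the weights estimated by ridge regression,
   `w = (SᵀS + λI)⁻¹ Sᵀr`, over a lag window of [−100, 500] ms (61 lags at
   100 Hz). λ is selected on a 10⁻⁴…10⁴ grid by nested segment
   cross-validation (6 contiguous segments; rotating held-out segment).
4. **Peak statistics** — channel-averaged, baseline-corrected weight
   curves per bin yield N1 (minimum, 70–160 ms) and P2 (maximum,
   160–300 ms) amplitudes; logistic / exponential / quadratic curves are
   fit to amplitude vs. IOI; a *gradient score* (sum of consecutive
   amplitude differences across bins) is tested against 100 random
   reallocations of onsets to bins, with BH-FDR across bin models.
5. **Model comparison** — prediction accuracy (held-out Pearson r) of
   binned vs. single-onset vs. onset-count-matched models, merged-condition
   training, and generic leave-one-participant-out models, compared with
   paired Wilcoxon signed-rank tests (`ρ = |Z|/√n`).

A first-class synthetic generator (`simulate_subject()`) produces onset
trains with a right-skewed IOI law, tone-burst audio, and multichannel EEG
whose N1/P2 kernel amplitude follows a saturating recovery law
`a(IOI) = floor + (1 − floor)(1 − exp(−IOI/τ_rec))` — so every stage is
testable against ground truth without any data download.

## Worked example

Ten minutes of synthetic EEG, 5 IOI bins:

```r
library(ioitrf)
sub  <- simulate_subject(sim_config(duration = 600), recovery_params(), seed = 42)
spec <- make_uniform_bins(sub$onsets$ioi[sub$onsets$eligible], 5)
feats <- binned_onset_matrix(sub$onsets, spec, 100, ncol(sub$eeg$data))
fit  <- crossval_fit(feats, sub$eeg, cv_config())
pt   <- permutation_test(sub$onsets, sub$eeg, spec, cv_config(),
                         peak_windows(), n_perm = 100, seed = 7,
                         lambda = fit$lambda)
pt$peak_table
```

```
         bin_upper_edge n1_amplitude n1_latency_ms p2_amplitude p2_latency_ms
0.765521          0.766       -0.296           110        0.185           210
1.32137           1.321       -0.401           110        0.225           210
1.90778           1.908       -0.457           110        0.326           220
3.13102           3.131       -0.526           110        0.345           220
9.35278           9.353       -0.580           110        0.387           220
```

Each row is one IOI bin (labelled by its upper IOI edge in seconds): N1
grows from −0.30 to −0.58 and P2 from 0.19 to 0.39 as the preceding
interval lengthens — the adaptation profile the package is built to
measure. The gradient scores are far outside their permutation nulls
(`N1 = -0.284, P2 = 0.202, both p = 0.0099`, the add-one floor at 100
permutations), and the cross-validated prediction accuracy of this model
is `mean r = 0.033` at `λ = 1e-4` (weak by design: the default synthetic
world runs at −10 dB per-event SNR).

## Command line

```sh
exec/ioitrf simulate --out sim/ --seed 7 --duration 600
exec/ioitrf onsets sim/audio.wav --out onsets.tsv
exec/ioitrf run --out results/ --seed 7 --bins 2,3,4,5,6,7,8
```

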