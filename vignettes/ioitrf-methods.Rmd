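---
title: "IOI-dependent auditory adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IOI-dependent auditory adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ioitrf` measures how the auditory evoked N1/P2 complex adapts to the
inter-onset interval (IOI) between sound events in continuous soundscapes.
This vignette is the package's own account of its models, the parameters
that matter, the synthetic world used for validation, and the design
decisions taken where the method was genuinely open.

## 1. The forward model

The EEG is modelled as a lagged linear (forward) convolution model — a
temporal response function (TRF):

$$r(t, c) = \sum_\tau \omega(\tau, c)\, s(t - \tau) + \varepsilon(t, c),$$

where $s$ holds one binary onset column per IOI bin, $\tau$ ranges over
[−100, 500] ms (61 lags at 100 Hz), and $\omega$ is estimated per channel
by ridge regression, $w = (S^\top S + \lambda M)^{-1} S^\top r$.

**Assumptions.** Linearity and time invariance *within a bin*: every onset
assigned to a bin evokes the same kernel. The binning is exactly the
device that reintroduces a nonlinearity (amplitude depending on the
preceding interval) into an otherwise linear model. Features are binary
and not z-scored, and the EEG keeps its original units, so the weights
read directly as evoked-response amplitudes.

**Regularizer.** $M = I$ (standard ridge) by default — the simplest
faithful reading of the printed closed form. A banded second-derivative
(curvature) penalty is available via `penalty = "derivative"`; it smooths
weight curves across lags and measurably stabilizes per-subject peak
ordering, but it is not the default because the reference analysis used
plain regularized regression.

**Cross-validation.** Recordings are split into 6 *contiguous* segments
(no shuffling — autocorrelated EEG would leak across shuffled folds).
One segment is held out; the remaining five run an inner
leave-one-segment-out loop over $\lambda \in \{10^{-4}, \dots, 10^4\}$
(factor-10 steps, 9 values; the printed phrase "linear steps of 10" is
ambiguous and was read multiplicatively — additive steps would not
produce the printed endpoints). The model is refit on all training
segments at the winning $\lambda$ and scored on the held-out segment by
channel-mean Pearson correlation; rotating the held-out segment gives six
performances per recording. The returned model is refit on the whole
recording at the modal $\lambda^*$ (ties to the smaller, i.e. less
regularized, value). One caveat: the lagged design is built over the full
recording and row-sliced into segments, so events within one lag span
(600 ms) of a segment boundary leak marginally between folds; building
designs per segment would differ only in those boundary rows.

## 2. Onset detection

Three novelty functions are computed at the EEG rate (100 Hz) so onsets
align to EEG samples:

* **Energy**: squared waveform → 100 ms Hann smoothing → decimation →
  $\log(1 + \gamma x)$, $\gamma = 10$ → first difference → half-wave
  rectification.
* **Spectral flux**: STFT magnitudes, log-compressed, positive per-band
  first differences summed over bands, 1 s local average subtracted,
  clipped at zero.
* **Complex domain**: each STFT coefficient is predicted from the
  previous frame's magnitude, phase and phase rate (local stationarity);
  the novelty is the prediction-error magnitude with *per-band* decrease
  suppression before the band sum — applying the suppression after
  summing (the other possible reading) leaves a large fluctuating
  baseline and was rejected.

The three functions are min-max normalized to [0, 1] and averaged.
Peak picking smooths the combined novelty with a Gaussian window
($\sigma = 4$ samples), forms a local threshold as its 1024-sample running
median plus `mean(x) + 0.05`, and keeps strict local maxima of the
*smoothed* novelty above the threshold (plateau ties resolve to the first
sample; onset sample index is `floor(time * fs)`, 0-based, so a response
can never precede its event).

Whether the raw or the smoothed novelty is compared against the threshold
is ambiguous in the source description. Both were implemented and
evaluated against synthetic ground truth: the raw comparison recalls
every burst but *structurally* cannot stay silent on burst-free noise
(min-max normalization guarantees unit-height maxima in any input, so
some raw local maximum always clears a threshold built from location
statistics), whereas the smoothed comparison is silent on noise at the
cost of missing the quietest events. The smoothed reading is the default
because silence on unstructured input is the property a detector must
have to be trusted on real soundscapes.

**STFT window.** 2048 samples (46 ms) at the 44.1 kHz rate of real
soundscape audio — the field-standard novelty setting. At the 8 kHz rate
of the synthetic world, a 46 ms window loses weak narrowband bursts and a
literal 2048-sample window (256 ms) biases onset timing by ~25 ms, so
below 22.05 kHz the default is `2^round(log2(fs/8))` (~1/8 s; 1024 at
8 kHz), validated against generator ground truth. The hop always equals
`fs / 100` so every frame lands exactly on an EEG sample.

## 3. IOI features

IOIs are intervals to the *preceding* onset; the first event and events
with IOI > 10 s (the span over which N1 recovery has been reported) are
excluded before bin edges are computed. Binning is rank-based with
per-bin counts differing by at most one; reported edges are midpoints
between adjacent bins' extreme values, intervals are left-closed
(`[e_k, e_{k+1})`, last bin closed). Each bin's IOI coordinate downstream
is its upper data value. The permutation null shuffles the *allocation*
of onsets to bins (uniformly over label permutations, counts preserved)
so acoustic timing is intact but the IOI structure is destroyed. The
distance-weighted alternative encodes each onset's IOI min-max normalized
to [0, 1] in a single column; all-equal IOIs degenerate to a zero vector
and warn.

## 4. Peak statistics

Per bin, weights are averaged over the channel set (default: all
channels), baseline-corrected by the mean of the pre-onset lags
[−100, 0) ms, and scanned for the N1 minimum in [70, 160] ms and the P2
maximum in [160, 300] ms (first sample on ties). Baseline correction is
standard evoked-response practice; with 1/f noise it removes the random
curve offset that otherwise dominates per-bin amplitude error, and it can
be disabled (`peak_windows(baseline_window = NULL)`).

The **gradient score** is the sum of consecutive amplitude differences
across bins ordered by IOI — algebraically the last minus the first
amplitude (telescoping). The signed version is primary; an
absolute-difference variant sits behind `signed = FALSE`. Significance
comes from refitting the TRF under `n_perm = 100` random bin
reallocations and the two-sided add-one rule
$p = (1 + \#\{|g_0| \ge |g|\})/(n_{perm}+1)$, so $p \ge 1/101$ by
construction; across the seven bin models (2–8 bins) the per-component
p-values are Benjamini–Hochberg adjusted. Permutation refits reuse the
observed model's cross-validated $\lambda$ rather than rerunning the
nested search per permutation: the null construction only requires the
same estimator, and a fixed $\lambda$ keeps 100 refits tractable.

Amplitude-vs-IOI curves: logistic $A/(1+e^{-k(x-x_0)})$, exponential
$A(1-e^{-x/\tau})$, quadratic polynomial. Nonlinear families use five
deterministic multiplicative multi-starts around data-derived
initializations with Nelder–Mead; $R^2 = 1 - SSE/SST$ is defined as 0
when $SST = 0$ (constant amplitudes), and the exponential family, which
has no intercept, may legitimately score $R^2 < 0$. Three points are
allowed (the quadratic then interpolates exactly); fewer raise an error.

## 5. Model comparisons

Paired signed-rank tests: zeros dropped, mid-ranks for ties, exact
enumeration of sign assignments below 10 non-zero pairs, otherwise the
normal approximation with tie and continuity corrections;
$W$ is the positive-rank sum, $\rho = |Z|/\sqrt{n}$, Bonferroni within a
comparison family. Training-data matching draws 100 random onset subsets
of the per-bin count and averages their performances; merged-condition
training concatenates recordings (lagging per recording first, so lags
never cross the boundary) into a 12-segment rotation; the generic model
trains on all-but-one participant and tests on the held-out one.

## 6. The synthetic world

The generator emulates exactly the features the analysis depends on, and
its defaults were fixed a priori:

* **IOI law**: lognormal, `meanlog 0.53`, `sdlog 0.9` — the closed-form
  80th percentile is $e^{0.53 + 0.9 z_{0.8}} = 3.63$ s, anchoring the
  right-skewed interval distribution of naturalistic soundscapes in which
  80% of events follow within ~3.6 s.
* **Recovery law**: $a(\text{IOI}) = \text{floor} + (1-\text{floor})
  (1 - e^{-\text{IOI}/\tau_{rec}})$ with $\tau_{rec} = 1.5$ s and
  floor = 0.3 — a saturating-exponential stand-in consistent with
  recovery-function literature; it is *not* claimed to be the true
  physiological law.
* **Kernel**: negative Gaussian N1 (peak 110 ms, SD 20 ms, asymptotic
  amplitude 1) plus positive Gaussian P2 (220 ms, SD 30 ms, 0.7).
* **Channels**: 22, with a fixed fronto-central gain topography (max at
  FCz/Cz) matching the dimensionality of real recordings.
* **Noise**: 1/f (exponent 1), scaled to −10 dB per-event SNR (RMS of
  the fully recovered kernel on the best channel vs. noise RMS) — the
  lower edge of what evoked-response analyses tolerate.
* **Audio**: 8 kHz tone bursts (carriers 300–3000 Hz, rises 5–30 ms,
  RMS 0.1 with 3 dB SD log-normal level jitter) over a white floor 20 dB
  below nominal burst level. 8 kHz (vs. the 44.1 kHz of real playback)
  keeps synthesis desk-scale while Nyquist still covers the carriers.

**What the generator does not emulate** — and hence what a green test
does not establish: overlapping broadband sources, speech, reverberation
or spatialization; attention and condition effects; latency shifts with
IOI (amplitude only); non-stationary noise, artifacts, or channel
failures; RMS-equalized event levels (real soundscape sounds were
loudness-normalized; synthetic bursts jitter). Conclusions about real
data rest on the method, not on these tests.

## 7. Known limitations (measured by the acceptance suite)

* At the stated −10 dB world, per-subject *strict* monotonicity of all
  five bin amplitudes is met by most but not ≥18/20 subjects (P2
  especially: with floor 0.3 the largest achievable amplitude ratio is
  ~1.9, and the saturating tail differences sit near the per-bin noise
  floor). The permutation test itself rejects in 20/20 subjects for both
  components; the reference finding is about group-averaged curves,
  where the ordering is clear.
* The synthetic detector recall measures ~0.90 against the ≥0.95 target:
  the misses are the quietest bursts, compressed by min-max
  normalization against the loudest event. Burst-free noise yields ~0–1
  spurious onsets per 90 s.
* The per-subject prediction advantage of the true bin allocation over a
  permuted one is undetectable at −10 dB (the modulation carries a few
  percent of a small response variance); the mechanism is asserted at
  +5 dB.
* p-values from the mixed model use the residual-df t distribution
  (no Satterthwaite correction); at the event counts involved the
  difference is immaterial.
* EDF input is not supported (no EDF reader in the supported stack);
  EEG travels as float32 binary + JSON sidecar, audio as WAV.
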