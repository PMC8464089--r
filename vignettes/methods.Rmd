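---
title: "Methods: nonlinear EEG features, ranking and nested evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonlinear EEG features, ranking and nested evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific and numerical choices behind
`eegrhythms`: what each stage computes, which knobs matter, what the
synthetic data does and does not emulate, and where the design was
genuinely open.

## Signals and rhythms

The unit of analysis is a single-channel EEG segment: a finite numeric
vector (conventionally microvolts) with a sampling rate, by default
173.61 Hz and 4097 samples (23.6 s) — the format of the public Bonn
five-set benchmark that this workflow is built around. `load_bonn()` reads
the benchmark's on-disk convention (one directory per class, one plain-text
file per segment, one numeric sample per line) and accepts both folder
naming conventions (`Z/O/N/F/S` mapped to `A/B/C/D/E`).

`decompose()` extracts the four classical rhythms — delta 0.5–4 Hz, theta
4–8 Hz, alpha 8–14 Hz, beta 14–30 Hz — with fourth-order Butterworth
band-pass designs. Two decisions here are not dictated by the method
itself:

* **Phase handling.** The default is zero-phase forward–backward
  application (`signal::filtfilt`). The fractal measures downstream are
  sensitive to waveform shape, and a causal pass would distort each band
  with a different group delay; forward–backward filtering avoids that at
  the cost of squaring the magnitude response (the "fourth-order" contract
  refers to the designed prototype). `zero_phase = FALSE` selects a causal
  single pass; `bandpass_gain()` reports the analytic gain that matches
  the selected mode, and the test suite checks measured tone gains against
  it to within 10%.
* **Edge effects.** No samples are trimmed in the pipeline: features are
  computed on the full filtered length. Tests that probe steady-state
  gains trim edges explicitly (several seconds for the delta band, whose
  0.5 Hz edge rings for seconds).

The transfer-function (`b`, `a`) form is used directly: at 173.61 Hz the
largest pole magnitude over the four band designs is ≈ 0.9944, far enough
inside the unit circle that cascading second-order sections would add
complexity without measurable benefit in double precision. Filtering is
linear only to ≈ 1e−8 relative accuracy — an IIR recursion with poles near
the unit circle amplifies rounding — which is why the linearity test uses
that tolerance rather than machine epsilon.

## The six nonlinear measures

All six are computed on the original signal and on each of the four
rhythms, giving 30 features named `"MEASURE(SOURCE)"` (e.g. `KFD(Theta)`,
`HFD_kmax=45(Beta)`).

**Higuchi fractal dimension** (`higuchi_fd`). Curve lengths are averaged
over start phases for intervals `p = 1..p_max`, and the dimension is the
ordinary least-squares slope of `log A(p)` on `log(1/p)` using *all*
points, unweighted, in natural logs (the slope is base-invariant). The two
saturation points `p_max = 30` and `45` are both kept as separate features.
Degenerate input (a flat signal, zero curve length) is an error; the
feature assembly converts it to a flagged `NA`. A linear ramp gives exactly
1 (`A(p) = (Y−1)/p`), white noise 2 in expectation, and a Weierstrass
cosine series of dimension `D` is recovered to about ±0.1 at `n = 4096`.

**Katz fractal dimension** (`katz_fd`). The waveform is a planar curve
through `(j, T(j))` with *unit* sample spacing — the abscissa is the
index, not seconds. Scaling the x-axis to time would silently change `K`;
fixing unit spacing makes values comparable across sampling rates and is
the convention under which hand-computed reference values (line → 1,
zig-zag `[0,1,0,1]` → 1.365) hold. Base-10 logs as in the defining
formula. Constant signals are well-defined (a horizontal line, `K = 1`).
Katz's measure is deliberately *not* amplitude-invariant; amplitude is part
of what it encodes, which is also why it discriminates the high-amplitude
seizure-like class.

**Rescaled-range Hurst exponent** (`hurst_exponent`). Block lengths follow
the halving schedule `M, M/2, M/4, …` stopped at `min_block = 16`: below
roughly 16 points the per-block `R/S` statistic is too unstable to help the
fit. Blocks are non-overlapping; a trailing remainder is dropped. The
denominator is the population standard deviation
`sqrt(mean((T_j − a)^2))` — the defining expression is used with the square
restored, since without it the radicand can be negative. Blocks with zero
SD are excluded; if fewer than three block lengths survive, estimation is
refused (constant signals land here). The multiplicative constant in the
`E[R/S] = C·m^H` law is irrelevant to the slope and is not estimated.
Estimates are clipped to `[0, 1]` only at feature-assembly time, so the
raw estimator remains inspectable. Small-sample R/S bias is real (≈ +0.07
at `H = 0.3`, ≈ −0.04 at `H = 0.9`, `n = 4096`); the recovery tests assert
mean absolute error < 0.1 rather than unbiasedness.

**Lempel–Ziv complexity** (`lz_complexity`). Binarization: `u(j) = 1` iff
`T(j)` strictly exceeds the margin (signal mean or median); values *equal*
to the margin map to 0, a deterministic resolution of a case the defining
rule leaves open. Parsing is the LZ76 exhaustive-history variant: a
component ends at the first position where the current word no longer
occurs anywhere in the preceding history (occurrences may overlap the
component's own start), and a final incomplete component counts as one.
The production parser exploits that "occurs in the history" is monotone in
the word end (any occurrence must start before the component), so each
component end is found by binary search with C-level substring matching;
it is verified against a quadratic brute-force parser on *all* binary
strings up to length 12 and on random length-500 strings. Normalization is
`C(m) = c(m)/(m/log2 m)`, so i.i.d. random sequences concentrate near 1.
Both margins are kept as separate features (`LZC_mean`, `LZC_median`).

## ReliefF ranking

`relieff_rank()` is the standard multi-class extension: `k = 10` nearest
hits and, per other class, `k` nearest misses under Manhattan distance on
range-normalized features, miss contributions weighted by
`P(c)/(1 − P(class(R)))`, evaluated over all instances by default (the
result is then fully deterministic; optional subsampling is seeded). These
parameter choices are the common defaults of the algorithm family — the
workflow this package reproduces does not specify them. Zero-range
features get weight exactly 0 and contribute nothing to distances. Final
ties are broken by original column order. All 30 features are continuous,
so no nominal-feature branch exists.

## Nested cross-validated evaluation

`nested_cv_accuracy()` implements the leakage-aware protocol: stratified
ten-fold outer CV estimates accuracy; within each outer-training part a
stratified ten-fold inner CV selects the hyperparameter grid point with
the best mean inner accuracy (ties → the first, i.e. simplest, grid
point); the winner is refit on the full outer-training part. Z-score
standardization is always fitted on the respective training part only.
Accuracy is the mean of per-fold accuracies (×100); pooled-prediction
accuracy is available via `aggregate = "pooled"`. Per-class recall is
attached for imbalanced problems such as ABCD/E (400 vs 100), where plain
accuracy remains the headline metric.

Classifiers and grids (the study this mirrors names the classifier types
but not the grids; these are standard log-spaced ranges spanning under- to
over-fitting):

* **MLP**: one hidden layer with hyperbolic-tangent activation and softmax
  output, cross-entropy plus a small L2 penalty (1e−3), trained with
  L-BFGS; hidden sizes {2, 5, 10, 20, 40}. No installed R package offers a
  tanh single-hidden-layer network (`nnet` hard-codes a logistic hidden
  layer), so the package carries its own small implementation with
  analytic gradients; initialization is drawn from the supplied seed, so
  fits are reproducible.
* **Linear SVM**: cost {0.01, 0.1, 1, 10, 100} (`e1071`/libsvm — the same
  library family as the original workflow; multi-class by one-vs-one
  voting).
* **RBF SVM**: the same costs crossed with kernel width
  γ ∈ {1e−3 … 10}, log-spaced.

`sequential_curve()` evaluates top-`n` prefixes of a ranking for
`n = 1..N`, recording the optimal point — the *smallest* `n` attaining the
maximum — and the all-features (no-selection) accuracy. Two ranking modes
exist because the published style of reporting a single feature ranking is
not leakage-safe:

* `"global"` (default): rank once on the full matrix, mirroring a single
  published ranking table;
* `"foldwise"`: re-rank within each outer-training fold, so selection
  never sees held-out data. The per-fold rankings are returned, and a
  canary test (a feature equal to the held-out-fold indicator, hence
  constant on training) verifies its weight is exactly zero.

`run_problem_suite()` crosses the five standard problems (ABCD/E, AB/CD/E,
A/D/E, A/E, D/E) with the classifiers, ranking per problem on that
problem's segments, and emits the two summary tables (top-5 features per
problem; accuracy with/without selection). `run_pipeline()` adds
ingestion, persistence (`features.csv`, `ranking.csv`, `curves.csv`,
`report.md`, `config.yaml`), stage-timing logs (kept out of the
deterministic artifacts so identical seeds give byte-identical CSVs), and
resume-from-features re-entry.

## Synthetic data: what it does and does not show

Three generators make the whole pipeline testable offline:

* `generate_fgn()` — fractional Gaussian noise via Davies–Harte circulant
  embedding with explicit Hermitian coefficients. The synthesis is exact:
  the sample autocovariance matches the closed form
  `γ(k) = ½(|k+1|^{2H} − 2|k|^{2H} + |k−1|^{2H})`, which is what makes it
  a trustworthy oracle for the Hurst estimator (validation avoids
  mean-subtracted autocovariance estimates, which are biased low by
  `Var(x̄) ~ n^{2H−2}` under persistence). Embedding eigenvalues are
  checked non-negative at run time.
* `generate_weierstrass()` — the deterministic cosine series with
  `H = 2 − D`, frequency ratio λ = 2, truncated by default at the Nyquist
  harmonic: a known-dimension oracle for both fractal estimators.
* `generate_bonn_mimic()` — a five-class corpus built by spectral shaping
  (per-class band bumps plus a broadband floor, inverse FFT with random
  phases, class RMS in µV) with sharp biphasic transients added to the
  seizure-like class. The default profiles follow the benchmark's
  qualitative morphology: `A`/`B` alpha-dominant and rough (RMS 40–50 µV,
  high broadband floor), `C`/`D` theta/delta-dominant and intermediate,
  `E` a large-amplitude (250 µV) delta-dominated oscillation with spikes
  and almost no broadband floor — hence *smoother* (lower Katz dimension)
  despite being far larger. The profiles were calibrated once so the
  corpus reproduces the discriminative structure the workflow relies on
  (the Katz separation between `E` and `A` exceeds three pooled standard
  errors, in `E`-lower direction).

None of this is physiologically realistic EEG: there are no artifacts
(EMG/EOG), no non-stationarity within a segment, no recording noise model,
and class differences are cleaner than clinical data. Passing the pipeline
tests on this corpus demonstrates that the *machinery* — filtering,
estimators, ranking, nested CV — is correct and leakage-free; it does not
certify clinical accuracy figures, which require the real benchmark data
(supported via `load_bonn()` but not shipped).

## Problem sizes used by the tests

The test suite and the acceptance script choose sizes that keep a full run
in the minutes range on one CPU while leaving each check statistically
meaningful: estimator oracles at `n = 4096` with 20 seeds; the exhaustive
LZ76 cross-check up to string length 12; the end-to-end classification
checks on the default 500-segment corpus restricted to the balanced
two-class seizure-vs-normal problem (200 segments, all three classifiers,
ten-seed permutation null); determinism and suite-shape checks on reduced
corpora (12 segments per class, 256 samples) with small fold counts and
grids. The full-scale five-problem, three-classifier, 30-feature curve
suite is exposed by `run_problem_suite()` and is intended for real
analyses rather than routine testing.

## Known limitations

* The rescaled-range estimator carries the classical small-sample bias;
  no Anis–Lloyd correction is applied.
* The Katz dimension's amplitude dependence means feature values are not
  comparable across recordings with different gain; the nested-CV
  standardization operates per feature, not per recording.
* The MLP uses L-BFGS rather than the Levenberg–Marquardt training of the
  original Matlab toolchain; accuracies on real data will not match that
  toolchain digit-for-digit.
* `"global"` ranking mode reproduces the published reporting style but
  lets the ranking see test folds; use `"foldwise"` when an unbiased
  accuracy estimate is the goal.
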