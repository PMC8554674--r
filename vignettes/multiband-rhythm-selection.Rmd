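---
title: "Penalized multiband selection of dominant actigraphy periodicities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized multiband selection of dominant actigraphy periodicities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythm)
```

## The problem

Actigraphy records activity counts per fixed epoch (typically one minute)
over several consecutive days. The scientific question this package
addresses is population-level: *which periodic components dominate a
cohort's rest-activity pattern?* A mature adult circadian system is well
summarized by a single 24-hour component; an infant's is not — daytime naps
contribute half-day, one-third-day and shorter "day harmonic" components
whose relative strength changes with development. Methods that presuppose a
sinusoidal 24-hour rhythm (single-component cosinor, nonparametric
circadian variables) cannot rank those ultradian components, and
autocorrelation is biased by the presence of multiple periodicities.

## Model and estimator

### Periodicity signals

Each subject contributes `D` whole retained days, `L = D × epochs_per_day`
epochs. After mean-centering (removing only the zero-frequency bin, so the
recorded waveform is otherwise untouched), the one-sided DFT bins
`k = 1..⌊L/2⌋` correspond to periods `D·1440/k` minutes; the day harmonics
1440, 720, 480, 360 … minutes sit exactly on this grid. We define the
periodicity signal as the amplitude-scaled modulus `(2/L)·|c_k|`, so a pure
cosine of amplitude `a` at a grid frequency produces a signal of exactly
`a`. The `n × p` matrix of these signals over the cohort is `X`.

**Normalization choice.** Whether the "signal" should be the modulus or the
squared modulus is a genuine design choice; we use the modulus because it
makes the signal identical to the least-squares cosinor amplitude at the
same grid period (see *Cosinor equivalence* below), which gives the entries
of `X` a direct physical unit (activity counts). Selection *order* is
unaffected by this monotone choice; θ values and MSE scale are.

### Penalized diagonal selection

A diagonal matrix `Θ = diag(θ)`, `0 ≤ θ_j ≤ 1`, selects columns of `X` by
minimizing

$$g(\theta) = \|X - X\Theta\|_F^2 +
  \lambda \sum_j \left[\alpha\,\theta_j + (1-\alpha)\,\theta_j^2/2\right].$$

Because `‖X − XΘ‖²_F = Σ_j (1−θ_j)²‖x_j‖²` separates over columns, each
coordinate is a one-dimensional convex problem with closed-form solution

$$\theta_j = \mathrm{clip}\left(
  \frac{2\|x_j\|^2 - \alpha\lambda}{2\|x_j\|^2 + (1-\alpha)\lambda},
  \,0,\,1\right).$$

With `α = 1` (the default, pure L1), `θ_j` activates at
`λ*_j = 2‖x_j‖²`: periodicities enter the path in descending order of their
cohort-level spectral energy. The package evaluates the path only at these
entry knots plus `λ = 0` by default, because between knots no active set
changes and the MSE curve is smooth; a dense grid can be requested via
`pml_config(lambda_grid = …)`. Columns with `‖x_j‖² = 0` are held at
`θ_j = 0` for every λ (their stationarity condition is degenerate and they
carry no energy).

### Choosing the number of periodicities

The reconstruction criterion is `MSE = ‖X − XΘ‖²_F / (n·p)` (the
unnormalized Frobenius form is available; the two are monotone-equivalent —
normalization is our choice, made so values are comparable across cohort
sizes). No cross-validation is used: on held-out data the error curve of
this estimator is monotone, so there is no interior CV optimum; instead one
inspects the MSE drop as successive periodicities enter. `select_dominant(
path, "elbow")` automates the visual "kink" choice by maximizing the drop
ratio `(MSE_{m−1} − MSE_m)/(MSE_m − MSE_{m+1})`; this rule is an explicit,
documented stand-in for a judgment call, and an integer `n_select` is the
primary interface.

### Cosinor equivalence

At a Fourier grid period the regressors `cos(2πt/T)`, `sin(2πt/T)` and the
intercept are mutually orthogonal over the record, so the least-squares
cosinor amplitude `√(A² + B²)` equals the `(2/L)`-scaled DFT modulus
*exactly* (not just asymptotically). `cosinor_amplitudes()` implements the
fit and refuses off-grid periods, where the equivalence (and the linearity
of the fit) breaks down. The acceptance suite checks the across-subject
Pearson correlation between the two routes is 1 to 1e-10; this is an
algebraic identity, so it holds for any seed. The only nuance is the
Nyquist bin (even `L`), where the `2/L` scaling doubles the amplitude; it
is excluded from `cosinor_amplitudes()` and can be dropped from spectra
with `min_period`.

## Comparators

**Sequential Fisher g-test.** Under a Gaussian white-noise null the
one-sided periodogram ordinates (excluding Nyquist) are iid exponential and
`P(G > g)` for `G = max/sum` has the exact alternating series
`Σ_j (−1)^{j−1} C(N,j)(1−jg)^{N−1}`. The sequential variant tests the
largest ordinate, and upon significance removes it and renormalizes —
the classical ordered-ordinates recursion; each step therefore has a
different critical value through its `(g_s, N_s)`. Steps are declared
significant at the Bonferroni level `α/p`. Two interpretive choices are
deliberate and documented: (i) the cohort-level input is the *pooled*
ordinate `Σ_i X[i,j]²`, which makes the Fisher ranking identical (up to the
monotone square) to the PML energy ranking — a per-subject test can be run
by passing one row; (ii) the null at each step is the exponential null with
the reduced `N`. Pooled ordinates are Gamma-distributed rather than
exponential, so pooled-mode p-values are a ranking/stop device rather than
exact tail probabilities; the exactness and type-I calibration tests run in
single-subject mode, where the null is exact.

**Numerical evaluation of the series.** Terms are computed in log space.
The alternating sum is numerically exact whenever its largest term is
moderate (absolute error ≲ 1e-15 × max term), which covers every `g` whose
p-value is small enough to be interesting. The series only explodes when
`g` is far below the detection scale `log(N)/N`, where the null probability
is `1 − exp(−μ)` with `μ ≫ 30`; the implementation then returns 1, correct
to far below double precision.

**Autocorrelation.** `r_k` is the standard biased single-global-mean sample
ACF (the estimator that guarantees `|r_k| ≤ 1`). Peak detection
(`find_local_maxima`) requires a lag to dominate a ±window neighborhood,
which automatically excludes the zero-lag main lobe. A known property of
this estimator, verified numerically in our tests: for a 7-day record the
`(1 − k/n)` envelope displaces the one-day peak roughly 12 epochs *early*
(a noiseless 1440-min cosine peaks at lag ≈ 1428), and preset-level noise
scatters it by roughly ±15 epochs more. Peak locations from week-long
records are therefore only ~quarter-hour accurate, one reason spectral
selection is preferred for anything beyond confirming the dominant 24-hour
rhythm.

## Synthetic cohorts: what they do and do not establish

The generator draws, per subject,
`counts_t = max(0, baseline + Σ_m a_{i,m} cos(2πt/T_m + φ_{i,m}) + ε_t)`,
with truncated-normal amplitudes, fixed or uniform phases, Gaussian (or
negative-binomial) noise, optional integer rounding, and all-zero nonwear
days injected per day with a configurable probability. Per-subject RNG
substreams are derived from `(seed, subject_index)`, so cohorts are
reproducible under partial regeneration.

Preset regimes encode the developmental amplitude profiles the estimator is
meant to distinguish: `"6m"` (one-day rhythm only, small ultradian
residues), `"12m-one-nap"` (one-third-day emerging), `"12m-two-nap"`
(one-fourth/one-fifth-day), `"24m"` (strong 1440/720/480 triplet). The
defaults were fixed once, on field realism grounds, before any acceptance
measurement: one-day amplitude 150 counts with between-subject SD 20,
secondary amplitudes 40–100, epoch noise SD 100 — typical magnitudes for
1-minute Actiwatch-style counts — and baselines set to
`≥ 3 × (Σ amplitudes + 3·noise SD)` so the nonnegativity clip essentially
never binds and planted amplitudes pass unbiased into the spectrum. The
night-day component uses a cohort-aligned (fixed) phase; nap components use
uniform per-subject phases.

What a green test on these cohorts establishes: the estimator's selection
behavior under its own generative assumptions (stationary cosine mixtures,
day-aligned records, homoscedastic noise). What it does not establish:
performance under waveforms that are periodic but non-sinusoidal *within*
a band (square-wave-like rest/activity alternation concentrates energy
into harmonics), slow trends, missing epochs within days, or
developmental drift across the recording week. Nonwear handling is a
reproducible proxy (a day is dropped when ≥ 95 % of its epochs are zero,
inclusive at the boundary), not a reconstruction of diary-assisted manual
cleaning; removed days are concatenated rather than imputed, which
preserves within-day harmonic structure but discards phase coherence
across the gap — irrelevant here because the estimator uses only
magnitudes.

## Numerical choices and degenerate inputs

* Period-grid membership is tested to 1e-8 relative tolerance.
* Equal column energies enter the path at the same knot; the deterministic
  tie-break lists the longer period first (ties have measure zero on real
  data).
* `variance_fractions` refuses all-zero rows; `autocorrelation` refuses
  constant series; an all-nonwear subject raises an error rather than an
  empty series, forcing an explicit exclusion decision upstream.
* CSV exports write integers plainly and other numerics with `%.17g`, so
  round-trips are exact and repeated runs are byte-identical.
* Theta/MSE along the path are recomputed from the closed form on demand
  when `p × knots` would make storing the full theta matrix wasteful
  (> 2e6 entries); stored and recomputed paths are identical.

## Known limitations

* All subjects must share one epoch length and are truncated to a common
  number of days; spectra from unequal grids are never mixed.
* Pooled-mode Fisher p-values are not exact tail probabilities (see above).
* The elbow rule can be unstable when successive MSE drops are nearly
  equal; prefer an explicit `n_select` when the science dictates one.
* The L2-augmented (`α < 1`) θ is provided for completeness (it may help
  downstream prediction or curve reconstruction) but selection in this
  package always proceeds through the L1 entry order.
* Uneven sampling, missing epochs within retained days, and multitaper or
  Lomb–Scargle estimation are out of scope.
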