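---
title: "Band-limited functional connectivity and weighted graph topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-limited functional connectivity and weighted graph topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megconn)
```

## The model

megconn implements a resting-state functional-connectivity (FC) analysis
for multichannel neural recordings such as beamformed MEG virtual-sensor
time series. The statistical dependence between two source signals
$X_a, X_b$ over an analysis window is the zero-lag Pearson correlation

$$R(X_a, X_b) = \frac{C(X_a, X_b)}{S_{X_a} S_{X_b}},$$

with $C$ the sample covariance and $S$ the sample standard deviations.
An edge between $a$ and $b$ survives when the t transform of the
correlation,

$$T_p = \frac{R\sqrt{K - 2}}{\sqrt{1 - R^2}},$$

exceeds the two-sided Student-$t$ critical value with $K-2$ degrees of
freedom at level $\alpha$ (default 0.05), where $K$ is the number of data
points in the window. `criticalR()` inverts this relation so thresholding
can happen directly on $|R|$; `buildNetwork()` keeps the sign and
magnitude of surviving correlations (positive read as excitatory,
negative as inhibitory). The test is two-sided because inhibitory
(negative) connections are retained alongside excitatory ones.

The analysis is run separately in six canonical frequency bands —
delta 1–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–80 and ripple
80–250 Hz — after a 50 Hz notch removes mains interference. Band
intervals are half-open $[low, high)$ so a shared edge frequency belongs
to the upper band only.

## Graph topology metrics

Each surviving network $G$ with $N$ nodes is summarised by four weighted
metrics, implemented exactly in the conventions of the source analysis:

* **Degree** $d_i$ — the number of edges incident to node $i$;
  $DA = \tfrac1N \sum_i d_i$.
* **Strength** $S_i = \tfrac1N \sum_j w_{ij}$. Note the $1/N$ prefactor:
  the conventional definition is the plain sum, but the prefactor is
  kept as printed in the source; `nodeStrength(..., convention = "sum")`
  gives the standard reading.
* **Path length** $L_{ij}$ — the shortest-path distance with edge
  lengths $1/w_{ij}$, with $L_{ij} = 0$ when $j$ is unreachable from $i$
  or $i = j$, and $LA = \frac{1}{N(N-1)}\sum_{i,j} L_{ij}$. The
  zero-for-unreachable rule means fragmented networks *lower* the
  apparent path length; `pathLength(..., convention = "harmonic")`
  offers the harmonic-mean alternative that penalises fragmentation.
* **Clustering** $C_i = \frac{1}{d_i(d_i-1)}
  \sum_{j,k} (w_{ij} w_{jk} w_{ki})^{1/3}$ — the geometric-mean
  (Onnela-type) weighted triangle density. Weights are divided by the
  network maximum first so $C_i \in [0,1]$; this is a no-op when weights
  are correlation magnitudes. Nodes with $d_i < 2$ get $C_i = 0$ to
  avoid $0/0$. $CA$ is the mean over all $N$ nodes.

Metrics consume $|w|$: a negative correlation is display semantics, and
both $1/w$ and the cube root are ill-defined for negative weights.
Signed metric variants are deliberately out of scope. All four metrics
are verified against brute-force oracles (Floyd–Warshall on $1/w$
lengths; exhaustive triangle enumeration) on hundreds of random graphs
in the test suite.

## Group statistics

`compareGroups()` follows a normality-gated workflow: each group is
tested with Shapiro–Wilk and the groups jointly with a median-centred
Levene (Brown–Forsythe) homogeneity test, each at the 0.05 gate. One-way
ANOVA is used only when every gate passes; otherwise Kruskal–Wallis.
Pairwise follow-ups (Student t after ANOVA, Mann–Whitney after
Kruskal–Wallis) are Bonferroni-corrected over the number of group pairs,
so three groups give the familiar $p < .05/3 \approx .016$ family
threshold. Both raw and corrected p-values are always reported, since
significance policy differs between publications. No correction is
applied across the bands-by-metrics family, mirroring common practice in
this literature; that inflates the family-wise error across the 24
comparisons and should be kept in mind when reading the run report.
Metric–score correlations (`correlateWithScore()`) use Pearson when both
variables pass Shapiro–Wilk, Spearman otherwise.

The homogeneity test is a design choice: the source analysis names none,
and the median-centred Levene is the robust default. The gate is applied
per group on the compared variable (not on pooled residuals); with four
independent gates at 0.05 the all-null probability of choosing ANOVA is
$0.95^4 \approx 0.81$, which the tests assert.

## The synthetic cohort

`generateCohort()` builds the world the chain is exercised on, since the
motivating datasets of this kind are not publicly deposited. Per band,
independent unit-variance band-limited Gaussian sources are mixed
through the Cholesky factor of the band's target correlation matrix (for
one coupled pair this reduces to sharing a latent source at weight
$\sqrt r$), the bands are summed, and white sensor noise is added.
Defaults, chosen once:

* **Three groups of 15 subjects** (IED, nonIED, HC), 30 channels, one
  30-s window — the cohort geometry of the motivating study design.
* **Sampling rate 1000 Hz** rather than a production MEG rate: the
  ripple band needs at least 500 Hz by Nyquist, and 1000 Hz keeps a
  comfortable margin while staying desk-scale.
* **Coupling**: within-region (anterior/anterior or posterior/posterior)
  target correlation 0.35 in every band; long-range anterior–posterior
  coupling graded HC 0.30 > nonIED 0.18 > IED 0.08 in the beta and
  ripple bands (0.10 elsewhere). The grading encodes the working
  hypothesis that epileptiform activity strengthens local synchrony at
  the expense of long-range integration, with the unaffected group
  intermediate — a modeling choice, not an empirical claim.
* **Spikes**: the IED group carries Poisson(10) spike-and-slow-wave
  transients per 30-s window — a biphasic ~70 ms sharp wave followed by
  a ~200 ms slow wave of opposite polarity, at 6 times the channel RMS
  with ±10% jitter in amplitude and width; the morphology parameters are
  our choice since none are specified at the source. Injected events are
  returned as annotations, the ground truth for detection-style tests.
* **Noise**: white noise at 0.1 of the summed signal RMS.

Two implementation details matter for correctness:

* **Spectral leakage compensation.** Adjacent bands share edges, so a
  component generated in one band passes partially through the
  measurement filter of its neighbours, diluting planted correlations by
  roughly 4–5% and contaminating uncoupled bands. The generator computes
  the band-by-band leakage matrix from the actual filter responses and
  plants `solve(A, targets)` latent correlations, so the *measured*
  band-filtered correlation equals the requested coupling in
  expectation.
* **Circular filtering.** Band-limited sources are produced by
  multiplying white-noise spectra with the zero-phase Butterworth
  response on the FFT grid, which yields exactly stationary series with
  no start-up transient.

What a green test establishes: that the analysis chain recovers planted
second-order structure, calibrated thresholds and planted group effects
of realistic size. What it does not establish: the generator has no 1/f
background, no biophysical forward model, no volume conduction, no
sensor geometry, and its networks are far more homogeneous than real
cortex. With planted couplings of 0.08–0.35 and the uncorrected-$K$
threshold (see below), default networks are dense in every band, so
group differences express themselves in edge *weights* (strength,
clustering, path length) rather than edge *counts*; count contrasts
appear once long-range coupling is removed outright, which the tests do
explicitly.

## Numerical choices

* **Filters.** The band decomposition is an order-4 Butterworth bandpass
  applied at its exact forward–backward (zero-phase) magnitude response
  $|H(f)|^2$ in the frequency domain, with odd-reflection padding. A
  time-domain biquad cascade has the same transfer function but two
  practical defects at narrow normalised bands (delta at 1000 Hz lives
  at 0.002–0.008 of Nyquist): pole radii within $10^{-3}$ of the unit
  circle amplify roundoff, and start-up transients stretch over seconds,
  which measurably inflates the variance of correlations estimated from
  a 30-s window. The spectral application removes both while matching
  the reference design to well under $10^{-6}$ dB. The 50 Hz notch is an
  RBJ biquad (quality 50) applied the same way: essentially complete
  rejection at the mains frequency, under 1 dB ripple outside ±2 Hz.
* **$K$ is the raw sample count.** The threshold uses $K$ = samples in
  the window, uncorrected for the autocorrelation of band-limited
  signals, exactly as the source analysis does. This makes the nominal
  threshold generous: a band of width $B$ carries only about
  $2 B T$ statistically independent samples, so null correlations
  fluctuate far above `criticalR(K)`. `effectiveSampleCount()` exposes
  the honest count, and all tolerance reasoning in the tests uses it;
  an effective-size-corrected threshold would be a one-line change but
  is off to stay faithful.
* **Constant channels** are excluded from correlation (entries `NA`),
  never coerced to 0, and can never form edges.
* **Empty networks** return all-zero metrics with a warning.
* **Decimation** is not implemented; every band is filtered at the
  native rate. (An integer-factor decimation for the low bands would cut
  runtime but complicate the $K$ bookkeeping for no accuracy gain at
  desk scale.)
* **Seeds.** Every random quantity derives from one master seed;
  per-subject seeds are deterministic functions of it, and two runs of
  `runPipeline()` with the same configuration produce byte-identical
  tables.

## Known limitations

* The zero-for-unreachable path-length convention makes $LA$
  non-monotone in connectivity; comparisons of $LA$ between networks of
  very different density need care (use the harmonic option for a
  monotone alternative).
* The per-pair threshold applies no correction across the
  $N(N-1)/2$ pairs (per the source analysis); with dense true coupling
  this is immaterial, with sparse coupling it overstates edge counts.
  A Bonferroni-across-pairs option is available via the `alpha`
  argument (`alpha / nPairs`).
* Scores are simulated from group-level normal summaries; the
  correlation stage demonstrates plumbing and calibration, not a
  biological metric–cognition link.
* Dense default networks make the degree metric degenerate (constant
  across subjects) in strongly coupled bands; the rank-test fallback
  warns when this happens.
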