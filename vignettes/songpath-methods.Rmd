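---
title: "Path-length song complexity and operant preference analysis: methods"
author: "songpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-length song complexity and operant preference analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songpath)
```

# Scope

This vignette is the package's own account of its methods: the song
path-length metric and the conventions it depends on, the synthetic syllable
generator, the operant-session simulator, the hierarchical choice model, and
the design analysis. It also records the numerical choices that had to be
frozen for reproducibility, and what the synthetic data do and do not
emulate about real recordings.

# The path-length metric

Zebra finch song is a sequence of syllables. The metric treats a song
holistically: every syllable is rendered as a small color image of its
spectrogram, images are embedded in two dimensions, syllables of the same
type fall into clusters, and the song is scored by the shortest traversal of
its cluster centroids:

$$\mathrm{pathlength} = \min_{o \in S_k} \sum_{i=1}^{k-1}
  d(c_{o_i}, c_{o_{i+1}})$$

with $c_0,\dots,c_{k-1}$ the centroids and $d$ one of Euclidean, cosine,
Manhattan or Chebyshev distance. Intuitively, a song whose syllables are
acoustically similar occupies a compact region (short path), while a song
with many distinct syllable types spreads across the embedding (long path).

Conventions frozen in `minPathLength()`:

* The path is **open** (no return to the start): a "path", not a tour.
* Reversing an ordering leaves its length unchanged, so only $k!/2$
  distinct paths exist; enumeration deduplicates by keeping the
  representative whose first cluster id is smaller than its last.
* For $k \le 8$ all orderings are enumerated (and can be returned in full);
  for $9 \le k \le 15$ a Held–Karp subset dynamic program computes the
  identical minimum. Both routes are cross-checked against each other and
  against an independent brute-force oracle in the test suite.
* Ties are broken by the lexicographically smallest optimal ordering,
  considering both traversal directions, so results are deterministic.
* $k > 15$ is rejected: the exact dynamic program needs $2^k k$ memory and
  this is a desk-scale bound; reduce the cluster count instead.

Useful invariants, all asserted in the tests: scaling all centroids by $c>0$
scales Euclidean/Manhattan/Chebyshev path lengths by $c$ and leaves cosine
unchanged; translation leaves the first three invariant but not cosine;
duplicating a centroid is free; and removing a cluster never lengthens the
minimal path for metrics with the triangle inequality.

# From waveform to feature vector

`stftDb()` computes the imaging STFT with fixed parameters: FFT size 512,
Hann window of 256 samples, hop 8, frames fully inside the signal (no
centered padding), magnitude-squared power in dB ($10\log_{10}$). Two
conventions required decisions:

* **Dynamic-range floor.** dB values are clipped to 80 dB below the
  per-image maximum. Without a floor, near-silent frames dominate min–max
  normalization and a single quiet gap would wash out the image.
* **Per-image min–max normalization.** Normalization is per spectrogram,
  not global across a corpus; two syllables identical up to gain therefore
  produce identical images, which is the desired invariance for a
  structure metric.

`renderColormap()` maps normalized values through a diverging
blue–white–red transfer — $0 \to (0,0,1)$, $0.5 \to (1,1,1)$,
$1 \to (1,0,0)$, piecewise linear per channel — and stretches the time axis
by linear interpolation to match the 257-bin frequency axis, giving a square
canvas independent of syllable duration. A constant (fully silent) image is
mapped to the midpoint color with a warning.

`resizeFlatten()` reduces the square image to 28 × 28 pixels per channel
with center-aligned bilinear interpolation (output pixel centers map to
$(i+0.5)\,s - 0.5$ in source coordinates, so 2× decimation equals block
averaging) and flattens in fixed row-major, channel-interleaved order:
pixel (1,1) R,G,B, pixel (1,2) R,G,B, …  The result is always a
2352-element vector in $[0,1]$, for syllables of any duration.

Because the colormap transfer and the dB floor are package conventions (no
single canonical choice exists), absolute path-length values are comparable
only within a pipeline that uses the same conventions; relative comparisons
between songs processed identically are the meaningful quantity.

`zscoreFeatures()` standardizes each of the 2352 features across syllables
with the sample standard deviation (denominator $n-1$); zero-variance
features are set to 0 and flagged in `metadata()$constant_features` rather
than producing NaNs. Two syllables that differ by a constant feature offset
therefore remain distinguishable while dead pixels are neutral.

# Embedding and clustering

`embed2D()` offers two deterministic projections of the z-scored feature
matrix:

* **manifold** (default): a Laplacian eigenmap on a locally scaled
  k-nearest-neighbor graph. Edge weights are
  $\exp(-d_{ij}^2/\sigma_i\sigma_j)$ with $\sigma_i$ the distance to the
  `n_neighbors`-th neighbor (local scaling adapts to density); the graph
  keeps all points tied at the k-th neighbor distance, so exact duplicates
  receive identical neighborhoods; a tiny uniform coupling keeps the graph
  connected; the embedding is the pair of eigenvectors of the normalized
  graph Laplacian with the smallest non-trivial eigenvalues. Like other
  neighborhood-graph methods it preserves local structure and separates
  syllable types into compact clusters.
* **pca**: the first two principal components, as a fast linear
  cross-check.

Defaults are 15 neighbors and a recorded `min_dist` of 0.1. The
minimum-distance parameter is provenance only: the eigenmap has no direct
analogue, but recording it keeps embedding configurations comparable across
tools that do use it. Both methods are exactly deterministic — eigenvector
signs are fixed by convention (largest-magnitude entry positive) — so the
`seed` argument is metadata that makes repeated-embedding stability reports
self-describing rather than a source of randomness.

`clusterSyllables()` implements the two standard validation routes:
k-means (`stats::kmeans`, 10 starts, fixed seed) and a density-based method
(DBSCAN: core points have at least `min_cluster_size` neighbors within
`eps`, clusters are connected components of core points, border points join
the nearest core cluster, the rest are noise, labeled −1). The default
`eps` is the 75th percentile of the per-point distance to its
`min_cluster_size`-th neighbor. Cluster ids are relabeled by descending
size with centroid-coordinate tie-breaks, so the labeling is invariant to
input row order.

`clusterCentroids()` excludes noise points and aggregates per cluster.
The arithmetic mean is the default. A per-axis geometric mean is offered as
an alternative aggregation, but a geometric mean of signed embedding
coordinates is ill-defined; when an axis contains non-positive values the
implementation shifts that axis so its minimum is +1, takes the geometric
mean, and shifts back (or rejects, with `shift = FALSE`). The arithmetic
default avoids this artificial dependence on the coordinate origin.

`stabilityReport()` re-embeds per seed, recomputes each bird's path length
and reports Spearman rank correlations of birds' path lengths across
embeddings — the relevant robustness check, since downstream conclusions
depend on the ordering of birds, not on absolute path values.

# The synthetic syllable generator

`synthSyllable()` renders a harmonic stack whose fundamental sweeps
linearly between two endpoint frequencies, with per-harmonic rolloff,
RMS-matched Gaussian broadband noise mixed in by `noise_fraction`, optional
sinusoidal amplitude modulation, 5-ms raised-cosine ramps (the same
click-avoidance concern that makes the playback controller let interrupted
audio run out), and peak normalization to 0.9. Synthesis is a pure function
of the spec and sample rate: the noise component uses a local RNG stream
seeded by the spec, leaving the caller's RNG untouched. Defaults are 44.1
kHz, mono 16-bit PCM on disk.

These controls map directly onto the acoustic features used to match
stimulus sets (`acousticFeatures()`): noise fraction drives Wiener entropy,
sweep extent drives frequency modulation, harmonicity drives goodness of
pitch, AM rate drives the envelope-derivative measure. Acoustic feature
framing is 512-sample Hann windows with 75% overlap — deliberately
independent of the imaging STFT, whose 8-sample hop is chosen for image
detail rather than feature stability. The envelope is the magnitude of the
analytic (Hilbert) signal.

What the generator emulates: controllable spectral structure, harmonicity,
noisiness, AM, duration; five-syllable motifs with 25-ms silent gaps.
What it does not: natural within-type variability of real renditions
(jitter must be injected via parameters), segmentation noise (inputs are
born pre-segmented), reverberation and recording-channel effects, and the
temporal fine structure of real zebra finch syllables. Passing tests on
synthetic syllables therefore validate the pipeline's contracts and
invariances, not the biological discriminability of real song — which is
exactly what a stimulus-construction tool needs.

`featureMatchReport()` summarizes candidate stimulus sets per feature by
medians and IQRs and standardizes the median difference by the pooled
IQR-based scale (mean IQR / 1.349, the normal-theory IQR-to-SD conversion).
The default flag threshold of 0.5 scale units is a convention — judgments
of "similar acoustic features" are usually made by eye from box plots, and
0.5 approximates where box-plot bodies visibly separate. With small sets
(n ≈ 20) the sampling error of a median is itself a sizeable fraction of
this scale, so single-feature flags near the threshold should be read as
prompts for inspection, not verdicts.

# The operant session simulator

`simulateSession()` reproduces the trial logic of the two-choice apparatus:
a 10-min silent baseline with both perches active, a 30-min playback phase
in which a 2-s dwell on a perch triggers a random stimulus of that perch's
category, and a 10-min silent post phase. Playback trials are spaced by
dwell + stimulus duration + a 5-s inter-trial interval plus exponential
"think time"; if the jittered schedule would overrun the session only the
jitter is compressed, so the minimum spacing always holds. A session that
cannot physically contain the requested trial count is rejected. Choices
are Bernoulli draws on the long-path perch at
$p = \mathrm{logit}^{-1}(\mu + b)$ with $b \sim N(0, \sigma_b)$ per bird;
interruptions are flagged with configurable probability but still count as
responses, because the perch trigger *is* the choice (a flag excludes them
if desired). The default 120 playback trials reflect what a 30-min session
typically yields. `simulateExperiment()` counter-balances the long-path
side and the replication/extension session order across birds.

`baselineBiasScreen()` implements the pre-session side-bias state machine
with the bias ratio $\max(\text{side counts})/\text{total}$ and threshold
0.80, where equality triggers (the boundary is biased): first baseline
biased → rerun; second baseline biased *toward the same side* → retest on a
later day; retest still biased the same way → exclude. A follow-up biased
toward the *other* side is not persistent bias and clears the screen — the
state machine tracks the side, not just the magnitude. Decisions are
invariant to relabeling left and right.

Baseline and post phases carry no audio; their perch triggers feed the
screen and descriptive summaries, and enter the choice model only when a
phase effect is requested, coded against the session's long-path side.

# The hierarchical choice model

`fitChoiceGlmm()` estimates the probability of choosing the long-path
stimulus with a Bayesian binomial-logit model: population log-odds $\mu$, a
random intercept per bird, optional treatment-coded fixed effects (phase,
experiment, session order) and an optional stimulus random intercept.
Priors are weakly informative: $N(0, 1.5)$ on $\mu$ and fixed effects
(roughly flat on the probability scale) and half-$N(0,1)$ on random-effect
SDs. These keep the posterior proper under complete separation (every bird
choosing long on every trial), which small pilot datasets can produce.

Implementation notes:

* Bernoulli trials are aggregated to binomial cells on the full
  (bird × phase × experiment × session order × stimulus) cross before
  sampling. The likelihood is identical, the MCMC is orders of magnitude
  cheaper, and the cell partition is the same for every nested model.
* Sampling uses JAGS (4 chains, 1000 adaptation, 1000 burn-in, 2000
  retained iterations by default, per-chain seeds derived from one seed).
  Convergence is checked by split-R̂ on the population-level parameters
  against a 1.01 threshold; failures set `converged = FALSE` and warn —
  never silently.
* The reported preference ratio is
  $\mathrm{logit}^{-1}(\text{posterior mean of } \mu)$, with a central 95%
  credible interval on the log-odds scale.

**Model comparison.** `compareModels()` ranks models by approximate
leave-one-out expected log predictive density. LOO is computed at the level
of individual Bernoulli trials — trials within a cell that share an outcome
have identical leave-one-out predictive densities, so each cell-outcome
pair is evaluated once and replicated by its count. Importance weights
($1/p(y_i\mid\theta^{(s)})$) are truncated at $\sqrt{S}$ times their mean
before normalization, which bounds the estimator's variance; for single
Bernoulli observations the raw weights are already mild, so truncated
importance sampling is accurate here. (Computing LOO on whole binomial
cells instead would make the weights heavy-tailed and the comparison SEs
uselessly wide — this is why the observation level is the right one.)
The SE of each pairwise elpd difference uses the paired pointwise
differences, and models within one SE of the best are flagged as
statistically indistinguishable.

# Design analysis

`retrodesign()` answers the planning question: if the true effect is $A$
(log-odds of a hypothetical preference ratio) and the design yields
standard error $s$, what are the power, the probability that a significant
estimate has the wrong sign (Type S), and the expected exaggeration of a
significant estimate (Type M)? With $\lambda = A/s$ and $z^*$ the two-sided
critical value,

$$\text{power} = \Phi(\lambda - z^*) + \Phi(-\lambda - z^*), \qquad
  \text{Type S} = \frac{\Phi(-\lambda - z^*)}{\text{power}},$$
$$\text{Type M} = \frac{E\left[\,|\lambda + Z|\; \mathbf 1\{|\lambda + Z| >
  z^*\}\right]}{\text{power} \cdot \lambda},$$

evaluated in closed truncated-normal form (the two one-sided pieces are
$\lambda\Phi(\lambda - z^*) + \varphi(\lambda - z^*)$ and
$-\lambda\Phi(-z^* - \lambda) + \varphi(z^* + \lambda)$). A seeded
Monte-Carlo mode provides an independent oracle, and the tests require
agreement within Monte-Carlo error. The reference distribution is normal by
default with an optional t degrees-of-freedom parameter. For $A = 0$,
power equals $\alpha$ and Type S equals 0.5 by symmetry while Type M is
undefined and reported as `NA`.

The default standard error is $s = 0.22$: the expected *maximum* SE of the
planned 22-bird × ~120-response hierarchical design, obtained by simulation
(`seDistribution()`), and the value under which the planning table's printed
power/Type S/Type M figures are jointly consistent — using the mean
simulated SE instead would overstate the design's safety margins, so
planning on the maximum is the conservative choice. At this SE, strong and
moderate preferences (0.70, 0.65) are detected with power ≥ 0.8, negligible
Type S and Type M ≤ ~1.12, while weak preferences (0.60, 0.55) give power
0.45 and 0.15 with exaggeration factors ~1.5 and ~2.7. Values are reported
at full precision; note that the 0.60 row's Type M evaluates to 1.474 (some
summaries elsewhere round this region to 1.4).

`seDistribution()` simulates the hierarchical design per scenario (bird
intercept SD 0.5, slope SD 0.25 by default — assumptions, exposed in the
configuration) and estimates the population-effect SE by an intercept-only
binomial logistic fit with a cluster-robust (sandwich) variance clustered on
bird. This is a fast, conservative approximation to the mixed-model SE; the
closed-form pooled-binomial SE is recovered within 10% when the
between-bird SDs are zero. The mean estimated SE sits essentially at the
between-bird floor $\sigma_b/\sqrt{B}$; in finite samples the concavity of
the square root lets it dip ~1–2% below.

# Problem sizes and test design

The suite exercises the full pipeline at sizes chosen to keep feedback
tight while preserving statistical meaning: featurization contracts on 50
random syllables spanning 20–500 ms; embedding/clustering fixtures of 30–60
syllables in 3–5 types; path-search oracle equivalence on 100 random
centroid sets with $k \in [3,8]$ across all four metrics (plus spot checks
to $k = 10$); parameter recovery over 20 replicate simulated experiments of
22 birds × 120 trials with shortened MCMC (2 chains × 1000 draws), asserting
posterior-mean recovery within ±0.05 on the preference-ratio scale and
≥ 16/20 credible-interval coverage; and the design-analysis closed forms
against a seeded Monte-Carlo oracle.

# Known limitations

* Absolute path lengths depend on the declared imaging conventions
  (colormap transfer, dB floor, resize kernel) and on the embedding method;
  only within-pipeline comparisons are meaningful.
* The manifold embedding is a spectral method; it preserves neighborhood
  structure but its coordinates are not interchangeable with those of other
  nonlinear embeddings, and cluster-to-cluster distances in any 2-D
  embedding are a lossy summary of the 2352-dimensional geometry.
* The density clustering is classic DBSCAN with a single `eps`; strongly
  varying within-song cluster densities may require per-bird tuning of
  `min_cluster_size`/`eps`.
* Exact path minimization stops at $k = 15$ clusters by design.
* The session simulator models choice, timing and interruption structure,
  not motivational drift within a session or inter-session memory.
* LOO uses truncated importance sampling without the Pareto-smoothed tail
  diagnostics; for the single-Bernoulli weights used here the truncated
  estimator is accurate, but cell-level (binomial) reuse of the machinery
  would not be.
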