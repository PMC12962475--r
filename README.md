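# songpath

**songpath** implements a holistic measure of birdsong complexity — the
*path length* of a song — and the full analysis pipeline of an operant
two-choice preference experiment built around it, for zebra finch
(*Taeniopygia guttata*) song research.

Female songbirds evaluate male song when choosing mates, but single acoustic
features (duration, repertoire size, pitch) explain preference only weakly.
Path length instead scores a song holistically: each syllable is rendered as
a fixed-size spectrogram image, the images are embedded in two dimensions,
similar syllables form clusters, and the song's score is the length of the
shortest traversal of its cluster centroids. A song whose syllables are
similar (tight, few clusters) gets a short path; a song with a wide diversity
of syllable types gets a long one. The package provides everything needed to
construct controlled synthetic stimuli, compute the metric, and analyze (or
plan, via simulation and design analysis) a two-choice preference test of
whether females prefer long-path songs.

## The metric

For a bird with syllable clusters having centroids
$c_0, \dots, c_{k-1}$ in the 2-D embedding, the path length under an
ordering $o$ is

$$L(o) = \sum_{i=1}^{k-1} d(c_{o_i}, c_{o_{i+1}}),$$

and the song's path length is $\min_o L(o)$ over all $k!$ orderings (an open
Hamiltonian path; $k!/2$ distinct paths by reversal symmetry). Distances $d$
can be Euclidean, cosine, Manhattan or Chebyshev. Exhaustive enumeration is
used for $k \le 8$ and a Held–Karp dynamic program for $9 \le k \le 15$.

The preference experiment is analyzed with a Bayesian hierarchical logistic
model: per-trial choice (1 = long-path stimulus) with a random intercept per
bird, `choice ~ (1 | bird)`, optionally extended with phase, experiment,
session-order fixed effects and a stimulus random effect, compared by
approximate leave-one-out cross-validation. Design planning uses the
Gelman–Carlin quantities: power, Type S (sign) error and Type M
(exaggeration) error of the planned design.

## Worked example

Five synthetic syllable types (eight renditions each), featurized to
2352-element spectrogram pixel vectors, embedded, clustered and scored:

```r
library(songpath)

types <- list(c(700, 900), c(1400, 1400), c(2600, 1900),
              c(3400, 3400), c(900, 2200))
specs <- list()
for (ty in seq_along(types)) for (r in 1:8)
  specs[[length(specs) + 1]] <- syllableSpec(
    sprintf("t%d_%d", ty, r), duration_s = 0.08,
    f0_start_hz = types[[ty]][1] * (1 + 0.02 * (r - 4) / 8),
    f0_end_hz   = types[[ty]][2] * (1 + 0.02 * (r - 4) / 8),
    n_harmonics = 1 + ty %% 3, noise_fraction = 0.1, rng_seed = 10 * ty + r)

fm  <- zscoreFeatures(featurizeSyllables(lapply(specs, synthSyllable)))
emb <- embed2D(fm, seed = 42)
cl  <- clusterSyllables(emb, "kmeans", k = 5)
cs  <- clusterCentroids(emb, cl)
minPathLength(cs, metric = "euclidean")
#> PathLengthResult: k = 5, metric = euclidean
#>   min path = 6.4931 along order (1 -> 2 -> 0 -> 4 -> 3); 60 orderings considered
```

The five syllable types form five clusters and the song's path length is the
shortest centroid traversal (6.49 embedding units here); `60` is the number
of distinct orderings examined (5!/2).

Planning the 22-bird experiment — power, Type S and Type M at the design's
expected maximum standard error (0.22 log-odds) for hypothetical preference
ratios:

```r
retrodesignTable()
#>     pr log_odds power   type_s type_m
#> 1 0.55    0.201 0.149 1.36e-02   2.71
#> 2 0.60    0.405 0.454 1.58e-04   1.47
#> 3 0.65    0.619 0.803 1.13e-06   1.12
#> 4 0.70    0.847 0.971 3.19e-09   1.02
```

A strong preference (0.70) is detected with power 0.97 and essentially no
sign or exaggeration risk; a weak one (0.55) would be detected rarely
(power 0.15) and, when detected, overestimated 2.7-fold.

Simulating the planned experiment at a true preference ratio of 0.70 and
recovering it with the hierarchical model:

```r
logs <- simulateExperiment(n_birds = 22, mu = prToLogodds(0.70),
                           sigma_b = 0.5, n_trials = 120, seed = 1)
fitChoiceGlmm(logs, seed = 1)
#> PreferenceEstimate [choice ~ (1 | bird)]
#>   population logit: 0.949 (95% CI 0.703 to 1.186)
#>   preference ratio: 0.721
#>   LOO elpd: -1537.0 (SE 22.5); converged: TRUE
```

The posterior mean preference ratio (0.72) recovers the simulated truth
(0.70) and the credible interval covers the true log-odds (0.847).

A thin command-line front end over these functions is installed at
`inst/scripts/songpath.R` (subcommands `synth`, `motif`, `featurize`,
`embed`, `pathlen`, `simulate`, `analyze`, `retrodesign`, `se-sim`).

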