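# Shared fixtures and independent oracles, all built in code at test time.

# A batch of random syllable specs spanning the generator's parameter space.
randomSyllableSpecs <- function(n, seed, dur_range = c(0.02, 0.5)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    syllableSpec(sprintf("rand_%03d", i),
                 duration_s = runif(1, dur_range[1], dur_range[2]),
                 f0_start_hz = runif(1, 400, 4000),
                 f0_end_hz = runif(1, 400, 4000),
                 n_harmonics = sample(1:4, 1),
                 harmonic_rolloff = runif(1, 0.4, 1),
                 noise_fraction = runif(1),
                 am_rate_hz = sample(c(0, 10, 25), 1),
                 rng_seed = 1000 + i)
  })
}

# Three well-separated syllable types, n_per copies each with small jitter.
threeTypeFeatureMatrix <- function(n_per = 20, seed = 5, sr = 22050) {
  set.seed(seed)
  types <- list(
    list(f0s = 600,  f0e = 900,  nh = 1, nf = 0.05),
    list(f0s = 1800, f0e = 1800, nh = 3, nf = 0.05),
    list(f0s = 3500, f0e = 2200, nh = 1, nf = 0.6))
  specs <- list(); labels <- integer()
  for (ty in seq_along(types)) {
    p <- types[[ty]]
    for (r in seq_len(n_per)) {
      specs[[length(specs) + 1L]] <- syllableSpec(
        sprintf("t%d_%02d", ty, r), duration_s = 0.08,
        f0_start_hz = p$f0s * runif(1, 0.97, 1.03),
        f0_end_hz = p$f0e * runif(1, 0.97, 1.03),
        n_harmonics = p$nh, noise_fraction = p$nf,
        rng_seed = 100 * ty + r)
      labels <- c(labels, ty)
    }
  }
  fm <- featurizeSyllables(lapply(specs, synthSyllable, sample_rate_hz = sr))
  list(fm = zscoreFeatures(fm), labels = labels)
}

# Two "birds" of duplicated syllable rows: bird A sings one syllable type,
# bird B five distinct types (point masses in feature space).
twoBirdFeatureMatrix <- function(sr = 22050) {
  mk <- function(f0, id, seed) synthSyllable(
    syllableSpec(id, duration_s = 0.06, f0_start_hz = f0, f0_end_hz = f0,
                 rng_seed = seed), sample_rate_hz = sr)
  wavesA <- rep(list(mk(800, "a", 1)), 10)
  typesB <- lapply(c(600, 1200, 1900, 2600, 3400),
                   function(f) mk(f, paste0("b", f), 2))
  wavesB <- rep(typesB, each = 4)
  ids <- c(sprintf("A_%02d", 1:10), sprintf("B_%02d", 1:20))
  fm <- featurizeSyllables(c(wavesA, wavesB), ids = ids,
                           bird_id = c(rep("A", 10), rep("B", 20)))
  zscoreFeatures(fm)
}

# ---- independent path-length oracle ----------------------------------------
# Brute force over all k! orderings, with its own permutation generator and
# its own distance computations (base R dist/crossprod).

permsCache <- new.env(parent = emptyenv())

oraclePerms <- function(k) {
  key <- as.character(k)
  if (!is.null(permsCache[[key]])) return(permsCache[[key]])
  p <- if (k == 1L) matrix(1L, 1, 1) else {
    sub <- oraclePerms(k - 1L)
    do.call(rbind, lapply(seq_len(k), function(first) {
      cbind(first, matrix(setdiff(seq_len(k), first)[sub], nrow(sub), k - 1L))
    }))
  }
  permsCache[[key]] <- p
  p
}

oracleDistMatrix <- function(pts, metric) {
  switch(metric,
    euclidean = as.matrix(dist(pts, method = "euclidean")),
    manhattan = as.matrix(dist(pts, method = "manhattan")),
    chebyshev = as.matrix(dist(pts, method = "maximum")),
    cosine = {
      nrm <- sqrt(rowSums(pts^2))
      1 - tcrossprod(pts / nrm)
    })
}

oracleMinPath <- function(pts, metric) {
  k <- nrow(pts)
  d <- oracleDistMatrix(pts, metric)
  if (k == 1L) return(0)
  perms <- oraclePerms(k)
  perms <- perms[perms[, 1L] < perms[, k], , drop = FALSE]
  lens <- numeric(nrow(perms))
  for (s in seq_len(k - 1L))
    lens <- lens + d[cbind(perms[, s], perms[, s + 1L])]
  min(lens)
}

makeCentroidSet <- function(pts) {
  new("CentroidSet", centroids = as.matrix(pts),
      cluster_sizes = rep(1L, nrow(pts)), aggregation = "arithmetic")
}
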