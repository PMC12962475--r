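#' @import methods
#' @importFrom stats approx cor dist dnorm fft integrate kmeans median plogis
#'   pnorm prcomp qlogis qnorm qt pt quantile rbinom rexp rnorm runif sd var
#'   setNames aggregate binomial glm rt update
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData "colData<-" "assay<-"
#' @importFrom S4Vectors metadata "metadata<-" DataFrame
NULL

## ---------------------------------------------------------------------------
## Waveforms and syllable specifications
## ---------------------------------------------------------------------------

#' Parametric description of a synthetic syllable
#'
#' A \code{SyllableSpec} holds the control knobs of the syllable synthesizer:
#' a harmonic stack whose fundamental sweeps linearly from \code{f0_start_hz}
#' to \code{f0_end_hz}, per-harmonic amplitude rolloff, a broadband-noise
#' mixing fraction, and an optional sinusoidal amplitude modulation. These are
#' the handles used to construct stimulus syllables with controlled entropy,
#' frequency modulation, pitch goodness and amplitude modulation.
#'
#' @slot id character label for the syllable.
#' @slot duration_s duration in seconds (> 0).
#' @slot f0_start_hz,f0_end_hz fundamental-frequency sweep endpoints in Hz.
#' @slot n_harmonics number of harmonics (>= 1).
#' @slot harmonic_rolloff per-harmonic amplitude decay factor in (0, 1].
#' @slot noise_fraction proportion of broadband noise mixed in, in [0, 1].
#' @slot am_rate_hz amplitude-modulation rate in Hz (0 = none).
#' @slot rng_seed integer seed governing the noise component.
#'
#' @seealso [syllableSpec()], [synthSyllable()]
#' @export
setClass("SyllableSpec",
  representation(
    id = "character",
    duration_s = "numeric",
    f0_start_hz = "numeric",
    f0_end_hz = "numeric",
    n_harmonics = "integer",
    harmonic_rolloff = "numeric",
    noise_fraction = "numeric",
    am_rate_hz = "numeric",
    rng_seed = "integer"
  )
)

setValidity("SyllableSpec", function(object) {
  msg <- character()
  if (length(object@duration_s) != 1L || !is.finite(object@duration_s) ||
      object@duration_s <= 0)
    msg <- c(msg, "duration_s must be a single positive number")
  if (object@noise_fraction < 0 || object@noise_fraction > 1)
    msg <- c(msg, "noise_fraction must lie in [0, 1]")
  if (object@f0_start_hz <= 0 || object@f0_end_hz <= 0)
    msg <- c(msg, "f0 endpoints must be positive")
  if (object@n_harmonics < 1L)
    msg <- c(msg, "n_harmonics must be >= 1")
  if (object@harmonic_rolloff <= 0 || object@harmonic_rolloff > 1)
    msg <- c(msg, "harmonic_rolloff must lie in (0, 1]")
  if (object@am_rate_hz < 0)
    msg <- c(msg, "am_rate_hz must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Mono audio waveform
#'
#' Thin carrier for mono PCM audio: a numeric sample vector in [-1, 1] plus a
#' sample rate. Waveforms are what the synthesizer emits, what motifs are
#' assembled from, and what the spectrogram featurizer consumes.
#'
#' @slot samples numeric vector of samples, each in [-1, 1].
#' @slot sample_rate_hz integer sample rate in Hz.
#'
#' @seealso [synthSyllable()], [assembleMotif()], [readWav()], [writeWav()]
#' @export
setClass("Waveform",
  representation(samples = "numeric", sample_rate_hz = "integer")
)

setValidity("Waveform", function(object) {
  msg <- character()
  if (length(object@sample_rate_hz) != 1L || object@sample_rate_hz <= 0L)
    msg <- c(msg, "sample_rate_hz must be a single positive integer")
  if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-9)
    msg <- c(msg, "samples must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Feature matrix (pixel features x syllables)
## ---------------------------------------------------------------------------

#' Syllable pixel-feature matrix
#'
#' A \code{SongFeatureMatrix} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the single assay
#' \code{"pixels"} holds the 2352 spectrogram pixel features (28 x 28 pixels x
#' 3 color channels) as rows and the syllables as columns. \code{colData}
#' carries per-syllable annotation (\code{syllable_id}, optional
#' \code{bird_id}, and, once computed, the two embedding coordinates
#' \code{umap1}, \code{umap2} and a \code{cluster} label). Whether the assay
#' has been feature-wise z-scored is recorded in \code{metadata()$zscored},
#' and indices of constant (zero-variance) features in
#' \code{metadata()$constant_features}.
#'
#' @seealso [featurizeSyllables()], [zscoreFeatures()], [embed2D()]
#' @export
setClass("SongFeatureMatrix", contains = "SummarizedExperiment")

setValidity("SongFeatureMatrix", function(object) {
  msg <- character()
  if (!"pixels" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'pixels' is required")
  if (nrow(object) != 2352L)
    msg <- c(msg, "feature matrix must have exactly 2352 pixel features")
  if (!"syllable_id" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'syllable_id'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Embedding, clustering, centroids, path lengths
## ---------------------------------------------------------------------------

#' Two-dimensional syllable embedding
#'
#' @slot coords n x 2 numeric matrix of embedding coordinates, one row per
#'   syllable (columns \code{umap1}, \code{umap2}).
#' @slot method embedding method label: \code{"manifold"} (Laplacian eigenmap
#'   on a local-scaled k-nearest-neighbor graph) or \code{"pca"}.
#' @slot seed integer seed recorded with the embedding.
#' @slot params list of embedding parameters (neighbor count, min distance).
#' @export
setClass("Embedding2D",
  representation(coords = "matrix", method = "character", seed = "integer",
                 params = "list")
)

setValidity("Embedding2D", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have exactly 2 columns")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  if (length(msg)) msg else TRUE
})

#' Syllable clustering
#'
#' Cluster labels are integers in \code{0:(k-1)}; the density-based method may
#' additionally assign \code{-1} for noise points. Labels are relabeled by
#' descending cluster size so that output is invariant to input row order.
#'
#' @slot labels integer vector of per-syllable cluster ids (-1 = noise).
#' @slot k number of non-noise clusters.
#' @slot method \code{"kmeans"} or \code{"density"}.
#' @export
setClass("Clustering",
  representation(labels = "integer", k = "integer", method = "character")
)

setValidity("Clustering", function(object) {
  msg <- character()
  lab <- object@labels[object@labels >= 0L]
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(lab) && (min(lab) < 0L || max(lab) >= object@k))
    msg <- c(msg, "non-noise labels must lie in [0, k)")
  if (length(msg)) msg else TRUE
})

#' Cluster centroids in the embedding plane
#'
#' @slot centroids k x 2 matrix of centroid coordinates.
#' @slot cluster_sizes integer counts of non-noise syllables per cluster.
#' @slot aggregation \code{"arithmetic"} or \code{"geometric"}.
#' @export
setClass("CentroidSet",
  representation(centroids = "matrix", cluster_sizes = "integer",
                 aggregation = "character")
)

setValidity("CentroidSet", function(object) {
  msg <- character()
  if (nrow(object@centroids) < 1L) msg <- c(msg, "need at least one centroid")
  if (ncol(object@centroids) != 2L) msg <- c(msg, "centroids must be 2-D")
  if (any(!is.finite(object@centroids))) msg <- c(msg, "centroids must be finite")
  if (length(object@cluster_sizes) != nrow(object@centroids))
    msg <- c(msg, "cluster_sizes length must match centroid count")
  if (length(msg)) msg else TRUE
})

#' Shortest-Hamiltonian-path result
#'
#' The path length of a song is the minimum, over all orderings of its k
#' syllable clusters, of the summed centroid-to-centroid distances along the
#' ordering (an open path: no return to the start). For k <= 8 orderings are
#' enumerated exhaustively, exploiting reversal symmetry (k!/2 distinct
#' paths); for 9 <= k <= 15 a Held-Karp dynamic program is used.
#'
#' @slot k cluster count.
#' @slot metric distance metric: euclidean, cosine, manhattan or chebyshev.
#' @slot min_path minimal path length (embedding units).
#' @slot argmin_order integer cluster sequence attaining the minimum
#'   (lexicographically smallest among ties; 0-based cluster ids).
#' @slot per_order_lengths data.frame of all k!/2 reversal-deduplicated
#'   orderings and their lengths (populated only for k <= 8 when requested).
#' @slot n_orders_considered number of distinct orderings examined.
#' @export
setClass("PathLengthResult",
  representation(k = "integer", metric = "character", min_path = "numeric",
                 argmin_order = "integer", per_order_lengths = "data.frame",
                 n_orders_considered = "numeric")
)

setValidity("PathLengthResult", function(object) {
  msg <- character()
  if (object@min_path < 0) msg <- c(msg, "min_path must be >= 0")
  if (!setequal(object@argmin_order, seq_len(object@k) - 1L))
    msg <- c(msg, "argmin_order must be a permutation of 0:(k-1)")
  if (nrow(object@per_order_lengths) &&
      object@min_path > min(object@per_order_lengths$length) + 1e-12)
    msg <- c(msg, "min_path must not exceed any enumerated order length")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Operant choice experiment
## ---------------------------------------------------------------------------

#' Operant two-choice session log
#'
#' One bird's session: a 10-min silent baseline on two active perches, a
#' 30-min playback phase in which a 2-s perch dwell triggers a stimulus from
#' that perch's category, and a 10-min silent post-playback phase. The
#' \code{records} data.frame has one row per trial with columns
#' \code{phase} (baseline/playback/post), \code{t_start_s}, \code{perch}
#' (left/right), \code{stimulus_category} (long/short/none),
#' \code{stimulus_id} and \code{interrupted}.
#'
#' @slot bird_id bird label.
#' @slot session_order \code{"first"} or \code{"second"}.
#' @slot experiment \code{"replication"} or \code{"extension"}.
#' @slot side_assignment perch carrying the long-path stimuli
#'   (\code{"left"} or \code{"right"}); fixed within a session.
#' @slot records trial records (see Details).
#' @export
setClass("SessionLog",
  representation(bird_id = "character", session_order = "character",
                 experiment = "character", side_assignment = "character",
                 records = "data.frame")
)

setValidity("SessionLog", function(object) {
  msg <- character()
  req <- c("phase", "t_start_s", "perch", "stimulus_category", "stimulus_id",
           "interrupted")
  if (!all(req %in% names(object@records)))
    msg <- c(msg, paste("records must contain columns:",
                        paste(req, collapse = ", ")))
  if (!object@side_assignment %in% c("left", "right"))
    msg <- c(msg, "side_assignment must be 'left' or 'right'")
  if (length(msg) == 0L) {
    r <- object@records
    if (any(r$t_start_s < 0)) msg <- c(msg, "t_start_s must be >= 0")
    ph <- split(r$t_start_s, r$phase)
    if (any(vapply(ph, is.unsorted, logical(1))))
      msg <- c(msg, "trial times must be non-decreasing within each phase")
  }
  if (length(msg)) msg else TRUE
})

#' Posterior preference estimate from the hierarchical choice model
#'
#' @slot posterior_mean_logit posterior mean of the population log-odds of
#'   choosing the long-path stimulus.
#' @slot ci95_low,ci95_high bounds of the central 95\% credible interval
#'   (log-odds scale).
#' @slot pr_mean posterior mean mapped to the preference-ratio scale,
#'   \code{plogis(posterior_mean_logit)}.
#' @slot model_label formula-style description of the fitted model.
#' @slot loo_elpd,loo_se approximate leave-one-out expected log predictive
#'   density (truncated importance sampling at the level of individual
#'   Bernoulli trials) and its standard error.
#' @slot fixed_effects posterior summary of fixed-effect coefficients.
#' @slot diagnostics list with split-Rhat values, effective sample sizes and
#'   sampler settings.
#' @slot converged logical: all split-Rhat below the configured threshold.
#' @slot draws matrix of retained posterior draws of monitored parameters.
#' @slot log_lik draws x (2 cells) matrix of per-trial log-likelihoods: the
#'   success (long-choice) columns for every cell, then the failure columns.
#' @slot cells aggregated binomial cell data the model was fit to.
#' @export
setClass("PreferenceEstimate",
  representation(posterior_mean_logit = "numeric", ci95_low = "numeric",
                 ci95_high = "numeric", pr_mean = "numeric",
                 model_label = "character", loo_elpd = "numeric",
                 loo_se = "numeric", fixed_effects = "data.frame",
                 diagnostics = "list", converged = "logical",
                 draws = "matrix", log_lik = "matrix", cells = "data.frame")
)

setValidity("PreferenceEstimate", function(object) {
  msg <- character()
  if (object@ci95_low > object@posterior_mean_logit + 1e-9 ||
      object@ci95_high < object@posterior_mean_logit - 1e-9)
    msg <- c(msg, "posterior mean must lie inside the 95% interval")
  if (abs(object@pr_mean - plogis(object@posterior_mean_logit)) > 1e-9)
    msg <- c(msg, "pr_mean must equal plogis(posterior_mean_logit)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Design analysis
## ---------------------------------------------------------------------------

#' Design-analysis (retrodesign) result
#'
#' Power, Type S error (probability that a statistically significant estimate
#' has the wrong sign) and Type M error (expected exaggeration factor of a
#' significant estimate) for a true effect \code{A} on the log-odds scale
#' measured with standard error \code{s} at two-sided level \code{alpha}.
#'
#' @slot power probability of statistical significance.
#' @slot type_s significant-and-wrong-sign share of significant results.
#' @slot type_m expected |estimate| / |A| conditional on significance
#'   (\code{NA} when A = 0, where it is undefined).
#' @slot effect the true effect A (log-odds).
#' @slot se the assumed standard error s.
#' @slot alpha two-sided test level.
#' @slot method \code{"analytic"} or \code{"mc"}.
#' @export
setClass("RetrodesignResult",
  representation(power = "numeric", type_s = "numeric", type_m = "numeric",
                 effect = "numeric", se = "numeric", alpha = "numeric",
                 method = "character")
)

setValidity("RetrodesignResult", function(object) {
  msg <- character()
  if (object@power < 0 || object@power > 1)
    msg <- c(msg, "power must lie in [0, 1]")
  if (object@type_s < 0 || object@type_s > 1)
    msg <- c(msg, "type_s must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
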