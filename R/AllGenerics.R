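#' @rdname Waveform-class
#' @param object,x a package object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname Waveform-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname Waveform-class
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' @rdname Embedding2D-class
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @rdname Clustering-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname Clustering-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname CentroidSet-class
#' @export
setGeneric("centroidCoords", function(x) standardGeneric("centroidCoords"))

#' @rdname PathLengthResult-class
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))

#' @rdname PathLengthResult-class
#' @export
setGeneric("argminOrder", function(x) standardGeneric("argminOrder"))

#' @rdname SongFeatureMatrix-class
#' @export
setGeneric("isZscored", function(x) standardGeneric("isZscored"))

#' @rdname SongFeatureMatrix-class
#' @export
setGeneric("syllableIds", function(x) standardGeneric("syllableIds"))

#' @rdname PreferenceEstimate-class
#' @export
setGeneric("prMean", function(x) standardGeneric("prMean"))

#' @rdname PreferenceEstimate-class
#' @export
setGeneric("credibleInterval", function(x) standardGeneric("credibleInterval"))

## -- accessor methods --------------------------------------------------------

#' @rdname Waveform-class
#' @export
setMethod("samples", "Waveform", function(x) x@samples)

#' @rdname Waveform-class
#' @export
setMethod("sampleRate", "Waveform", function(x) x@sample_rate_hz)

#' @rdname Waveform-class
#' @export
setMethod("durationS", "Waveform",
          function(x) length(x@samples) / x@sample_rate_hz)

#' @rdname Waveform-class
#' @export
setMethod("length", "Waveform", function(x) length(x@samples))

#' @rdname Embedding2D-class
#' @export
setMethod("embeddingCoords", "Embedding2D", function(x) x@coords)

#' @rdname Clustering-class
#' @export
setMethod("clusterLabels", "Clustering", function(x) x@labels)

#' @rdname Clustering-class
#' @export
setMethod("nClusters", "Clustering", function(x) x@k)

#' @rdname CentroidSet-class
#' @export
setMethod("centroidCoords", "CentroidSet", function(x) x@centroids)

#' @rdname PathLengthResult-class
#' @export
setMethod("pathLength", "PathLengthResult", function(x) x@min_path)

#' @rdname PathLengthResult-class
#' @export
setMethod("argminOrder", "PathLengthResult", function(x) x@argmin_order)

#' @rdname SongFeatureMatrix-class
#' @export
setMethod("isZscored", "SongFeatureMatrix",
          function(x) isTRUE(S4Vectors::metadata(x)$zscored))

#' @rdname SongFeatureMatrix-class
#' @export
setMethod("syllableIds", "SongFeatureMatrix",
          function(x) as.character(SummarizedExperiment::colData(x)$syllable_id))

#' @rdname PreferenceEstimate-class
#' @export
setMethod("prMean", "PreferenceEstimate", function(x) x@pr_mean)

#' @rdname PreferenceEstimate-class
#' @export
setMethod("credibleInterval", "PreferenceEstimate",
          function(x) c(lower = x@ci95_low, upper = x@ci95_high))

## -- show methods ------------------------------------------------------------

#' @rdname Waveform-class
#' @export
setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %d Hz (%.3f s)\n",
              length(object@samples), object@sample_rate_hz,
              durationS(object)))
})

#' @rdname SyllableSpec-class
#' @export
setMethod("show", "SyllableSpec", function(object) {
  cat(sprintf(
    "SyllableSpec '%s': %.3f s, f0 %.0f->%.0f Hz, %d harmonics (rolloff %.2f),\n  noise %.2f, AM %.1f Hz, seed %d\n",
    object@id, object@duration_s, object@f0_start_hz, object@f0_end_hz,
    object@n_harmonics, object@harmonic_rolloff, object@noise_fraction,
    object@am_rate_hz, object@rng_seed))
})

#' @rdname Embedding2D-class
#' @export
setMethod("show", "Embedding2D", function(object) {
  cat(sprintf("Embedding2D (%s): %d syllables, seed %d\n",
              object@method, nrow(object@coords), object@seed))
})

#' @rdname Clustering-class
#' @export
setMethod("show", "Clustering", function(object) {
  n_noise <- sum(object@labels == -1L)
  cat(sprintf("Clustering (%s): k = %d over %d syllables (%d noise)\n",
              object@method, object@k, length(object@labels), n_noise))
})

#' @rdname CentroidSet-class
#' @export
setMethod("show", "CentroidSet", function(object) {
  cat(sprintf("CentroidSet: %d clusters (%s mean), sizes %s\n",
              nrow(object@centroids), object@aggregation,
              paste(object@cluster_sizes, collapse = ", ")))
})

#' @rdname PathLengthResult-class
#' @export
setMethod("show", "PathLengthResult", function(object) {
  cat(sprintf(
    "PathLengthResult: k = %d, metric = %s\n  min path = %.4f along order (%s); %s orderings considered\n",
    object@k, object@metric, object@min_path,
    paste(object@argmin_order, collapse = " -> "),
    format(object@n_orders_considered, big.mark = ",")))
})

#' @rdname SessionLog-class
#' @export
setMethod("show", "SessionLog", function(object) {
  tab <- table(object@records$phase)
  cat(sprintf(
    "SessionLog: bird %s (%s session, %s experiment), long-path side = %s\n  trials: %s\n",
    object@bird_id, object@session_order, object@experiment,
    object@side_assignment,
    paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
})

#' @rdname PreferenceEstimate-class
#' @export
setMethod("show", "PreferenceEstimate", function(object) {
  cat(sprintf(
    "PreferenceEstimate [%s]\n  population logit: %.3f (95%% CI %.3f to %.3f)\n  preference ratio: %.3f\n  LOO elpd: %.1f (SE %.1f); converged: %s\n",
    object@model_label, object@posterior_mean_logit, object@ci95_low,
    object@ci95_high, object@pr_mean, object@loo_elpd, object@loo_se,
    object@converged))
})

#' @rdname RetrodesignResult-class
#' @export
setMethod("show", "RetrodesignResult", function(object) {
  cat(sprintf(
    "RetrodesignResult (%s): effect %.4f, SE %.3f, alpha %.3f\n  power = %.4f, Type S = %.3g, Type M = %s\n",
    object@method, object@effect, object@se, object@alpha, object@power,
    object@type_s,
    if (is.na(object@type_m)) "undefined (A = 0)"
    else sprintf("%.3f", object@type_m)))
})
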