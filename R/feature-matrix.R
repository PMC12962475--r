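## SongFeatureMatrix construction, z-scoring, accessors and CSV round trip.

#' Construct a SongFeatureMatrix
#'
#' @param features syllables x 2352 numeric matrix of pixel features (one
#'   row per syllable, matching the CSV layout).
#' @param ids character syllable labels.
#' @param bird_id optional bird label(s), recycled to the syllable count.
#' @return a [SongFeatureMatrix-class].
#' @export
songFeatureMatrix <- function(features, ids = rownames(features),
                              bird_id = NULL) {
  features <- as.matrix(features)
  if (ncol(features) != 2352L)
    stop("expected 2352 feature columns (28 x 28 x 3), got ", ncol(features))
  if (is.null(ids)) ids <- paste0("syl_", seq_len(nrow(features)))
  cd <- S4Vectors::DataFrame(syllable_id = as.character(ids))
  if (!is.null(bird_id))
    cd$bird_id <- rep_len(as.character(bird_id), nrow(features))
  assay <- t(features)
  rownames(assay) <- sprintf("px%04d", seq_len(2352L))
  colnames(assay) <- cd$syllable_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pixels = assay), colData = cd)
  S4Vectors::metadata(se)$zscored <- FALSE
  S4Vectors::metadata(se)$constant_features <- integer()
  new("SongFeatureMatrix", se)
}

#' @rdname SongFeatureMatrix-class
#' @param x a \code{SongFeatureMatrix}.
#' @return \code{featureValues()} returns the syllables x 2352 matrix (rows
#'   in CSV orientation).
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "SongFeatureMatrix"))
  t(SummarizedExperiment::assay(x, "pixels"))
}

#' Z-score a feature matrix
#'
#' Feature-wise (per pixel feature, across syllables) z-scoring with the
#' sample standard deviation (denominator n - 1). Zero-variance features are
#' set to 0 and their indices recorded in
#' \code{metadata()$constant_features}. Requires at least two syllables.
#'
#' @param x a [SongFeatureMatrix-class].
#' @return the z-scored [SongFeatureMatrix-class]
#'   (\code{isZscored(x)} becomes \code{TRUE}).
#' @export
zscoreFeatures <- function(x) {
  stopifnot(is(x, "SongFeatureMatrix"))
  if (ncol(x) < 2L)
    stop("z-scoring needs at least 2 syllables")
  a <- SummarizedExperiment::assay(x, "pixels")
  mu <- rowMeans(a)
  s <- apply(a, 1L, sd)
  const <- which(s == 0)
  s[const] <- 1
  z <- (a - mu) / s
  z[const, ] <- 0
  SummarizedExperiment::assay(x, "pixels") <- z
  S4Vectors::metadata(x)$zscored <- TRUE
  S4Vectors::metadata(x)$constant_features <- as.integer(const)
  x
}

#' Write / read the feature-matrix CSV
#'
#' The CSV layout is one row per syllable with header
#' \code{syllable_id, px0001..px2352} plus, when present, \code{bird_id},
#' \code{umap1}, \code{umap2} and \code{cluster} columns. The round trip is
#' lossless up to numeric printing precision.
#'
#' @param x a [SongFeatureMatrix-class].
#' @param path CSV file path.
#' @return \code{readFeatureCSV()} returns a [SongFeatureMatrix-class];
#'   \code{writeFeatureCSV()} returns \code{path} invisibly.
#' @export
writeFeatureCSV <- function(x, path) {
  stopifnot(is(x, "SongFeatureMatrix"))
  df <- data.frame(syllable_id = syllableIds(x), check.names = FALSE)
  cd <- SummarizedExperiment::colData(x)
  if ("bird_id" %in% colnames(cd)) df$bird_id <- cd$bird_id
  df <- cbind(df, as.data.frame(featureValues(x)))
  for (col in c("umap1", "umap2", "cluster"))
    if (col %in% colnames(cd)) df[[col]] <- cd[[col]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  px <- grep("^px[0-9]{4}$", names(df), value = TRUE)
  if (length(px) != 2352L)
    stop("expected 2352 px#### columns, found ", length(px))
  fm <- songFeatureMatrix(as.matrix(df[, px]), ids = df$syllable_id,
                          bird_id = if ("bird_id" %in% names(df)) df$bird_id)
  cd <- SummarizedExperiment::colData(fm)
  for (col in c("umap1", "umap2", "cluster"))
    if (col %in% names(df)) cd[[col]] <- df[[col]]
  SummarizedExperiment::colData(fm) <- cd
  fm
}

#' @rdname SongFeatureMatrix-class
#' @export
setMethod("show", "SongFeatureMatrix", function(object) {
  cat(sprintf("SongFeatureMatrix: %d pixel features x %d syllables%s\n",
              nrow(object), ncol(object),
              if (isZscored(object)) " (z-scored)" else ""))
  cd <- SummarizedExperiment::colData(object)
  extra <- setdiff(colnames(cd), "syllable_id")
  if (length(extra))
    cat("  annotation:", paste(extra, collapse = ", "), "\n")
})
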