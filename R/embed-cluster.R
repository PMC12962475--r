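## 2-D embedding of the z-scored pixel-feature matrix, syllable clustering,
## per-cluster centroids, and stability of downstream path lengths across
## repeated embeddings.

#' Embed syllables in two dimensions
#'
#' Projects the z-scored feature matrix to two dimensions. Two methods are
#' available:
#' \describe{
#'   \item{manifold}{a Laplacian eigenmap on a locally scaled
#'     k-nearest-neighbor graph: Gaussian edge weights
#'     \code{exp(-d_ij^2 / (sigma_i * sigma_j))} with \code{sigma_i} the
#'     distance to the \code{n_neighbors}-th neighbor, symmetrized; the
#'     embedding is the pair of eigenvectors of the normalized graph
#'     Laplacian with the smallest non-trivial eigenvalues. Like other
#'     neighborhood-graph embeddings it preserves local structure and
#'     separates syllable types into compact clusters.}
#'   \item{pca}{the first two principal components; linear, always
#'     available, useful as a fast cross-check.}
#' }
#' Both methods are deterministic: the same matrix and parameters always
#' yield identical coordinates (eigenvector signs are fixed by convention);
#' the \code{seed} is recorded in the result so that repeated-embedding
#' stability analyses are reproducible end to end.
#'
#' @param x a z-scored [SongFeatureMatrix-class] with >= 10 syllables.
#' @param method \code{"manifold"} (default) or \code{"pca"}.
#' @param seed integer seed recorded with the embedding (default 42).
#' @param n_neighbors neighborhood size for the manifold method (default 15;
#'   shrunk with a warning when fewer syllables are available).
#' @param min_dist minimum-distance parameter recorded for provenance
#'   (default 0.1; the eigenmap has no direct analogue, see the vignette).
#' @return an [Embedding2D-class].
#' @export
embed2D <- function(x, method = c("manifold", "pca"), seed = 42L,
                    n_neighbors = 15L, min_dist = 0.1) {
  stopifnot(is(x, "SongFeatureMatrix"))
  method <- match.arg(method)
  if (!isZscored(x))
    stop("feature matrix must be z-scored before embedding")
  n <- ncol(x)
  if (n < 10L) stop("embedding needs at least 10 syllables, got ", n)
  X <- featureValues(x)  # syllables x features
  if (n_neighbors >= n) {
    warning("n_neighbors (", n_neighbors, ") >= number of syllables (", n,
            "); shrinking to ", n - 1L)
    n_neighbors <- n - 1L
  }
  coords <- switch(method,
    pca = {
      pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
      sc <- pc$x[, 1:2, drop = FALSE]
      if (ncol(sc) < 2L) sc <- cbind(sc, 0)
      sc
    },
    manifold = laplacianEigenmap(X, n_neighbors)
  )
  coords <- apply(coords, 2L, fixSign)
  dimnames(coords) <- list(syllableIds(x), c("umap1", "umap2"))
  new("Embedding2D", coords = coords, method = method,
      seed = as.integer(seed),
      params = list(n_neighbors = n_neighbors, min_dist = min_dist))
}

# Locally scaled Laplacian eigenmap to 2-D. A tiny uniform coupling keeps the
# graph connected so exactly one trivial (constant) eigenvector exists.
laplacianEigenmap <- function(X, k) {
  n <- nrow(X)
  d <- as.matrix(dist(X))
  sigma <- apply(d, 1L, function(r) sort(r)[k + 1L])  # k-th neighbor (excl self)
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1)
  W <- exp(-d^2 / outer(sigma, sigma))
  # keep only kNN edges (union-symmetrized); all points tied with the k-th
  # neighbor distance are included, so exact duplicates get identical
  # neighborhoods regardless of row order
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    thr <- sort(d[i, ])[k + 1L]
    keep[i, d[i, ] <= thr] <- TRUE
    keep[i, i] <- FALSE
  }
  keep <- keep | t(keep)
  W[!keep] <- 0
  W <- W + 1e-8
  diag(W) <- 0
  dg <- rowSums(W)
  Dm <- 1 / sqrt(dg)
  Lsym <- diag(n) - (Dm %o% Dm) * W
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  # ascending eigenvalues are at the end; skip the trivial one
  v <- e$vectors[, c(n - 1L, n - 2L), drop = FALSE]
  coords <- v * Dm
  # unit-variance axes for a stable display scale
  apply(coords, 2L, function(u) {
    s <- sd(u)
    if (s > 0) u / s else u
  })
}

# Deterministic sign convention: the entry of largest magnitude is positive.
fixSign <- function(u) {
  i <- which.max(abs(u))
  if (u[i] < 0) -u else u
}

#' Append embedding coordinates to a feature matrix
#'
#' Adds the two embedding coordinates as \code{umap1}/\code{umap2} columns of
#' the feature matrix's \code{colData}, matching the CSV layout in which the
#' coordinates are appended to the pixel features.
#'
#' @param x a [SongFeatureMatrix-class].
#' @param e the matching [Embedding2D-class].
#' @return the annotated [SongFeatureMatrix-class].
#' @export
appendEmbedding <- function(x, e) {
  stopifnot(is(x, "SongFeatureMatrix"), is(e, "Embedding2D"),
            nrow(e@coords) == ncol(x))
  cd <- SummarizedExperiment::colData(x)
  cd$umap1 <- e@coords[, 1]
  cd$umap2 <- e@coords[, 2]
  SummarizedExperiment::colData(x) <- cd
  x
}

#' Cluster syllables in the embedding plane
#'
#' Either k-means (\code{stats::kmeans} with a fixed seed and \code{nstart =
#' 10}) or a density-based method (DBSCAN-style: core points have at least
#' \code{min_cluster_size} neighbors within \code{eps}; clusters are
#' connected components of core points; border points join the nearest core
#' cluster; remaining points are labeled noise, \code{-1}). Cluster ids are
#' relabeled by descending cluster size (ties broken by centroid
#' coordinates) so the labeling is invariant to input row order.
#'
#' @param e an [Embedding2D-class].
#' @param method \code{"kmeans"} or \code{"density"}.
#' @param k number of clusters (k-means only; must not exceed the number of
#'   points).
#' @param min_cluster_size density method: minimum neighborhood size for a
#'   core point (default 5).
#' @param eps density method: neighborhood radius. Default: the 75th
#'   percentile of each point's distance to its
#'   \code{min_cluster_size}-th neighbor.
#' @param seed RNG seed for the k-means starts (default 42).
#' @return a [Clustering-class].
#' @export
clusterSyllables <- function(e, method = c("kmeans", "density"), k = NULL,
                             min_cluster_size = 5L, eps = NULL, seed = 42L) {
  stopifnot(is(e, "Embedding2D"))
  method <- match.arg(method)
  pts <- e@coords
  n <- nrow(pts)
  if (method == "kmeans") {
    if (is.null(k)) stop("k-means requires k")
    if (k > n) stop("k (", k, ") exceeds number of points (", n, ")")
    km <- withLocalSeed(seed, kmeans(pts, centers = k, nstart = 10L,
                                     iter.max = 100L))
    labels <- km$cluster - 1L
  } else {
    labels <- dbscanLabels(pts, min_cluster_size, eps)
  }
  relabelBySize(labels, pts, method)
}

dbscanLabels <- function(pts, min_pts, eps) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  if (is.null(eps)) {
    kdist <- apply(d, 1L, function(r) sort(r)[min(min_pts + 1L, n)])
    eps <- as.numeric(quantile(kdist, 0.75))
  }
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts  # neighborhood includes the point itself
  labels <- rep(-1L, n)
  if (any(core)) {
    adj <- nb[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[core] <- as.integer(comp) - 1L
    for (i in which(!core)) {
      near <- which(core & nb[i, ])
      if (length(near)) {
        j <- near[which.min(d[i, near])]
        labels[i] <- labels[j]
      }
    }
  }
  labels
}

# Relabel clusters 0..k-1 by descending size; ties broken by centroid
# coordinates (lexicographic), so labels do not depend on input row order.
relabelBySize <- function(labels, pts, method) {
  ids <- sort(unique(labels[labels >= 0L]))
  if (!length(ids)) stop("density clustering found no clusters (all noise); ",
                         "decrease min_cluster_size or increase eps")
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  cx <- vapply(ids, function(i) mean(pts[labels == i, 1]), numeric(1))
  cy <- vapply(ids, function(i) mean(pts[labels == i, 2]), numeric(1))
  ord <- order(-sizes, cx, cy)
  remap <- integer(max(ids) + 1L)
  remap[ids[ord] + 1L] <- seq_along(ids) - 1L
  out <- labels
  out[labels >= 0L] <- remap[labels[labels >= 0L] + 1L]
  new("Clustering", labels = out, k = length(ids), method = method)
}

#' Per-cluster centroids
#'
#' Computes one 2-D centroid per cluster, excluding noise points. The default
#' is the arithmetic mean. The geometric aggregation computes per-axis
#' geometric means; because embedding coordinates can be negative (where a
#' geometric mean is ill-defined), any axis whose minimum is <= 0 is first
#' shifted so its minimum equals +1, the geometric mean taken, and the shift
#' removed. With \code{shift = FALSE}, non-positive coordinates are rejected
#' instead.
#'
#' @param e an [Embedding2D-class].
#' @param cl the matching [Clustering-class].
#' @param aggregation \code{"arithmetic"} (default) or \code{"geometric"}.
#' @param shift logical; apply the positivity shift for the geometric mean
#'   (default TRUE).
#' @return a [CentroidSet-class].
#' @export
clusterCentroids <- function(e, cl, aggregation = c("arithmetic", "geometric"),
                             shift = TRUE) {
  stopifnot(is(e, "Embedding2D"), is(cl, "Clustering"),
            length(cl@labels) == nrow(e@coords))
  aggregation <- match.arg(aggregation)
  keep <- cl@labels >= 0L
  pts <- e@coords[keep, , drop = FALSE]
  lab <- cl@labels[keep]
  ids <- seq_len(cl@k) - 1L
  if (aggregation == "geometric") {
    off <- vapply(1:2, function(ax) {
      m <- min(pts[, ax])
      if (m <= 0) {
        if (!shift) stop("geometric aggregation requires positive ",
                         "coordinates; axis ", ax, " has minimum ", m,
                         " (use shift = TRUE)")
        1 - m
      } else 0
    }, numeric(1))
    shifted <- sweep(pts, 2L, off, `+`)
    cent <- t(vapply(ids, function(i) {
      exp(colMeans(log(shifted[lab == i, , drop = FALSE]))) - off
    }, numeric(2)))
  } else {
    cent <- t(vapply(ids, function(i) {
      colMeans(pts[lab == i, , drop = FALSE])
    }, numeric(2)))
  }
  colnames(cent) <- c("umap1", "umap2")
  new("CentroidSet", centroids = cent,
      cluster_sizes = vapply(ids, function(i) sum(lab == i), integer(1)),
      aggregation = aggregation)
}

#' Path-length stability across repeated embeddings
#'
#' Re-embeds the feature matrix once per seed, recomputes each bird's
#' shortest-path length over its syllable-cluster centroids, and summarizes
#' how stable the birds' path lengths are across embeddings via pairwise
#' Spearman rank correlations between seeds. Requires a \code{bird_id}
#' column in the feature matrix's \code{colData}.
#'
#' @param x a z-scored [SongFeatureMatrix-class] with \code{bird_id}
#'   annotation.
#' @param seeds integer vector of at least 2 embedding seeds.
#' @param metric distance metric for the path length (default
#'   \code{"euclidean"}).
#' @param method embedding method passed to [embed2D()].
#' @param cluster_method \code{"density"} (default) or \code{"kmeans"}.
#' @param k cluster count per bird (k-means only).
#' @param min_cluster_size density-method parameter (default 2: birds
#'   contribute few syllables per type in small stimulus sets).
#' @return list with \code{path_lengths} (birds x seeds matrix),
#'   \code{spearman} (pairwise correlation matrix between seeds, or
#'   \code{NA} with a message for a single bird), and \code{mean_spearman}.
#' @export
stabilityReport <- function(x, seeds, metric = "euclidean",
                            method = "manifold",
                            cluster_method = c("density", "kmeans"),
                            k = NULL, min_cluster_size = 2L) {
  stopifnot(is(x, "SongFeatureMatrix"), length(seeds) >= 2L)
  cluster_method <- match.arg(cluster_method)
  cd <- SummarizedExperiment::colData(x)
  if (!"bird_id" %in% colnames(cd))
    stop("stabilityReport requires a bird_id column in colData")
  birds <- unique(as.character(cd$bird_id))
  pl <- matrix(NA_real_, length(birds), length(seeds),
               dimnames = list(birds, paste0("seed_", seeds)))
  for (j in seq_along(seeds)) {
    emb <- embed2D(x, method = method, seed = seeds[j])
    for (b in birds) {
      rows <- which(cd$bird_id == b)
      sub <- new("Embedding2D", coords = emb@coords[rows, , drop = FALSE],
                 method = emb@method, seed = emb@seed, params = emb@params)
      cl <- clusterSyllables(sub, method = cluster_method, k = k,
                             min_cluster_size = min_cluster_size)
      cs <- clusterCentroids(sub, cl)
      pl[b, j] <- pathLength(minPathLength(cs, metric = metric))
    }
  }
  if (length(birds) < 2L) {
    return(list(path_lengths = pl, spearman = NA,
                mean_spearman = NA,
                message = "rank correlation undefined for a single bird"))
  }
  rho <- cor(pl, method = "spearman")
  off <- rho[upper.tri(rho)]
  list(path_lengths = pl, spearman = rho, mean_spearman = mean(off))
}
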