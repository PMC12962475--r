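# Embedding, clustering, centroids and path-length stability.

test_that("embedding is deterministic and separates syllable types", {
  res <- threeTypeFeatureMatrix(n_per = 12, seed = 5)
  e1 <- embed2D(res$fm, seed = 42)
  e2 <- embed2D(res$fm, seed = 42)
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))

  sil <- cluster::silhouette(res$labels, dist(embeddingCoords(e1)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # the PCA route separates the same structure
  ep <- embed2D(res$fm, method = "pca")
  silp <- cluster::silhouette(res$labels, dist(embeddingCoords(ep)))
  expect_gt(mean(silp[, "sil_width"]), 0.5)
})

test_that("embedding preconditions are enforced", {
  small <- threeTypeFeatureMatrix(n_per = 3, seed = 2)  # 9 syllables
  expect_error(embed2D(small$fm), "at least 10")

  res <- threeTypeFeatureMatrix(n_per = 4, seed = 3)   # 12 syllables
  expect_warning(e <- embed2D(res$fm, n_neighbors = 15), "shrinking")
  expect_equal(e@params$n_neighbors, 11L)

  raw <- featurizeSyllables(lapply(randomSyllableSpecs(10, 4), synthSyllable,
                                   sample_rate_hz = 16000L))
  expect_error(embed2D(raw), "z-scored")
})

pointMassEmbedding <- function() {
  pts <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c(5, 5), 10), ncol = 2, byrow = TRUE))
  new("Embedding2D", coords = pts, method = "pca", seed = 1L,
      params = list(n_neighbors = 5L, min_dist = 0.1))
}

test_that("k-means and density clustering agree on separated point masses", {
  e <- pointMassEmbedding()
  km <- clusterSyllables(e, "kmeans", k = 2)
  expect_equal(nClusters(km), 2L)
  expect_equal(as.vector(table(clusterLabels(km))), c(10L, 10L))

  dn <- clusterSyllables(e, "density", min_cluster_size = 5)
  expect_equal(nClusters(dn), 2L)
  expect_false(any(clusterLabels(dn) == -1L))

  expect_equal(mclust::adjustedRandIndex(clusterLabels(km),
                                         clusterLabels(dn)), 1)

  one <- clusterSyllables(e, "kmeans", k = 1)
  expect_true(all(clusterLabels(one) == 0L))
  expect_error(clusterSyllables(e, "kmeans", k = 21), "exceeds")
})

test_that("cluster labels are invariant to input row order", {
  res <- threeTypeFeatureMatrix(n_per = 10, seed = 8)
  e <- embed2D(res$fm)
  cl <- clusterSyllables(e, "kmeans", k = 3)
  perm <- sample(seq_len(nrow(embeddingCoords(e))))
  ep <- new("Embedding2D", coords = embeddingCoords(e)[perm, ],
            method = e@method, seed = e@seed, params = e@params)
  clp <- clusterSyllables(ep, "kmeans", k = 3)
  expect_identical(clusterLabels(clp), clusterLabels(cl)[perm])
})

test_that("centroids follow the stated aggregation rules", {
  e <- new("Embedding2D", coords = rbind(c(0, 0), c(2, 2), c(7, 3)),
           method = "pca", seed = 1L, params = list())
  cl <- new("Clustering", labels = c(0L, 0L, 1L), k = 2L, method = "kmeans")
  cs <- clusterCentroids(e, cl)
  expect_equal(unname(centroidCoords(cs)[1, ]), c(1, 1))
  expect_equal(unname(centroidCoords(cs)[2, ]), c(7, 3))  # singleton

  eg <- new("Embedding2D", coords = rbind(c(1, 1), c(4, 4)),
            method = "pca", seed = 1L, params = list())
  clg <- new("Clustering", labels = c(0L, 0L), k = 1L, method = "kmeans")
  gs <- clusterCentroids(eg, clg, aggregation = "geometric")
  expect_equal(unname(centroidCoords(gs)[1, ]), c(2, 2))  # sqrt(1*4), no shift

  en <- new("Embedding2D", coords = rbind(c(-1, 2), c(3, 2)),
            method = "pca", seed = 1L, params = list())
  expect_error(clusterCentroids(en, clg, aggregation = "geometric",
                                shift = FALSE), "positive")
  shifted <- clusterCentroids(en, clg, aggregation = "geometric")
  expect_true(all(is.finite(centroidCoords(shifted))))

  # arithmetic centroid lies inside the cluster bounding box
  set.seed(6)
  for (i in 1:5) {
    pts <- matrix(rnorm(20), ncol = 2)
    er <- new("Embedding2D", coords = pts, method = "pca", seed = 1L,
              params = list())
    cr <- new("Clustering", labels = rep(0L, 10), k = 1L, method = "kmeans")
    cen <- centroidCoords(clusterCentroids(er, cr))[1, ]
    expect_true(all(cen >= apply(pts, 2, min) & cen <= apply(pts, 2, max)))
  }
})

test_that("noise points are excluded from centroids", {
  pts <- rbind(matrix(rnorm(20, sd = 0.05), ncol = 2),
               matrix(rnorm(20, mean = 5, sd = 0.05), ncol = 2),
               c(50, 50))  # an outlier far from both masses
  e <- new("Embedding2D", coords = pts, method = "pca", seed = 1L,
           params = list())
  cl <- clusterSyllables(e, "density", min_cluster_size = 5, eps = 1)
  expect_equal(nClusters(cl), 2L)
  expect_equal(clusterLabels(cl)[21], -1L)
  cs <- clusterCentroids(e, cl)
  expect_equal(sum(cs@cluster_sizes), 20L)
})

test_that("path lengths rank a diverse singer above a one-syllable singer", {
  fm <- twoBirdFeatureMatrix()
  rep <- stabilityReport(fm, seeds = c(7, 11, 13))
  expect_true(all(rep$path_lengths["B", ] > rep$path_lengths["A", ]))
  expect_equal(rep$path_lengths["A", 1], 0)  # one syllable type: k = 1

  same <- stabilityReport(fm, seeds = c(7, 7))
  expect_equal(unname(same$spearman[1, 2]), 1)

  solo <- fm[, SummarizedExperiment::colData(fm)$bird_id == "B"]
  solo <- new("SongFeatureMatrix", solo)
  rep1 <- stabilityReport(solo, seeds = c(1, 2))
  expect_true(is.na(rep1$mean_spearman))
  expect_match(rep1$message, "single bird")
})
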