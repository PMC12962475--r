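# STFT, colormap rendering, resize/flatten and z-scoring.

test_that("STFT dimensions follow the framing arithmetic", {
  w <- synthSyllable(syllableSpec("a", duration_s = 0.1))
  db <- stftDb(w)
  expect_equal(nrow(db), 257L)                       # n_fft/2 + 1
  expect_equal(ncol(db), floor((4410 - 256) / 8) + 1)  # 520

  w2 <- synthSyllable(syllableSpec("b", duration_s = 0.05), 16000L)
  expect_equal(ncol(stftDb(w2)), floor((800 - 256) / 8) + 1)

  short <- new("Waveform", samples = numeric(100), sample_rate_hz = 44100L)
  expect_error(stftDb(short), "at least 256")
})

test_that("a silent signal maps to a uniform dB floor", {
  w <- new("Waveform", samples = numeric(2000), sample_rate_hz = 44100L)
  db <- stftDb(w)
  expect_equal(length(unique(as.vector(db))), 1L)
})

test_that("the tone peak lands on the DFT-oracle bin", {
  sr <- 44100
  w <- synthSyllable(syllableSpec("tone", duration_s = 0.05,
                                  f0_start_hz = 1000, f0_end_hz = 1000), sr)
  db <- stftDb(w)
  # independent oracle: naive DFT of the first Hann-windowed frame
  frame <- samples(w)[1:256] * (0.5 - 0.5 * cos(2 * pi * (0:255) / 256))
  pw <- vapply(0:256, function(k)
    Mod(sum(frame * exp(-2i * pi * k * (0:255) / 512)))^2, numeric(1))
  oracle_bin <- which.max(pw) - 1L
  expect_equal(which.max(db[, 1]) - 1L, oracle_bin)
  expect_equal(oracle_bin, round(1000 * 512 / 44100))  # 12
})

test_that("the blue-white-red transfer hits its anchor colors", {
  cm <- songpath:::bwrColormap(c(0, 0.25, 0.5, 1))
  expect_equal(unname(cm[1, ]), c(0, 0, 1))
  expect_equal(unname(cm[2, ]), c(0.5, 0.5, 1))
  expect_equal(unname(cm[3, ]), c(1, 1, 1))
  expect_equal(unname(cm[4, ]), c(1, 0, 0))
  # monotone per channel on each half of the domain
  t_lo <- seq(0, 0.5, length.out = 21)
  t_hi <- seq(0.5, 1, length.out = 21)
  expect_true(all(diff(songpath:::bwrColormap(t_lo)[, "r"]) >= 0))
  expect_true(all(diff(songpath:::bwrColormap(t_hi)[, "g"]) <= 0))
  expect_true(all(diff(songpath:::bwrColormap(t_hi)[, "b"]) <= 0))
})

test_that("rendering is square, normalized, and warns on constant input", {
  db <- stftDb(synthSyllable(syllableSpec("sq", duration_s = 0.08)))
  img <- renderColormap(db)
  expect_equal(dim(img), c(257L, 257L, 3L))
  expect_gte(min(img), 0); expect_lte(max(img), 1)

  expect_warning(flat <- renderColormap(matrix(5, 10, 20)), "constant")
  expect_true(all(flat == 1))  # midpoint color is white
})

test_that("resizeFlatten yields the exact 2352-element contract", {
  white <- array(1, dim = c(64, 64, 3))
  v <- resizeFlatten(white)
  expect_length(v, 2352L)
  expect_true(all(v == 1))

  # 56x56 checkerboard of 2x2 uniform blocks decimates to the block colors
  blue <- c(0, 0, 1); red <- c(1, 0, 0)
  img <- array(0, dim = c(56, 56, 3))
  for (i in 1:56) for (j in 1:56) {
    block_col <- if ((ceiling(i / 2) + ceiling(j / 2)) %% 2 == 0) blue else red
    img[i, j, ] <- block_col
  }
  v2 <- resizeFlatten(img)
  expected <- numeric(0)
  for (i in 1:28) for (j in 1:28)
    expected <- c(expected, if ((i + j) %% 2 == 0) blue else red)
  expect_equal(v2, expected)
})

test_that("featurization is deterministic and gain-invariant", {
  w <- synthSyllable(syllableSpec("det", duration_s = 0.07,
                                  noise_fraction = 0.4))
  v1 <- resizeFlatten(renderColormap(stftDb(w)))
  v2 <- resizeFlatten(renderColormap(stftDb(w)))
  expect_identical(v1, v2)

  half <- new("Waveform", samples = samples(w) * 0.5,
              sample_rate_hz = sampleRate(w))
  expect_equal(resizeFlatten(renderColormap(stftDb(half))), v1,
               tolerance = 1e-12)
})

test_that("feature vectors stay in [0,1] with length 2352 across durations", {
  specs <- randomSyllableSpecs(5, seed = 7)
  fm <- featurizeSyllables(lapply(specs, synthSyllable, sample_rate_hz = 22050L))
  vals <- featureValues(fm)
  expect_equal(dim(vals), c(5L, 2352L))
  expect_gte(min(vals), 0); expect_lte(max(vals), 1)
})

test_that("z-scoring uses the sample SD and flags constant features", {
  m <- matrix(0.5, 2, 2352)
  m[, 1] <- c(1, 3) / 3  # keep within [0,1]
  fm <- zscoreFeatures(songFeatureMatrix(m))
  vals <- featureValues(fm)
  # two values d apart map to +/- 1/sqrt(2) under the sample-SD convention
  expect_equal(unname(vals[, 1]), c(-1, 1) / sqrt(2))
  expect_true(all(vals[, -1] == 0))
  expect_true(all(seq(2, 2352) %in%
                    S4Vectors::metadata(fm)$constant_features))
  expect_true(isZscored(fm))

  expect_error(zscoreFeatures(songFeatureMatrix(m[1, , drop = FALSE])),
               "at least 2")
})

test_that("z-scored columns have mean 0 and SD 1 at tight tolerance", {
  set.seed(3)
  fm <- featurizeSyllables(lapply(randomSyllableSpecs(12, seed = 12),
                                  synthSyllable, sample_rate_hz = 16000L))
  z <- featureValues(zscoreFeatures(fm))
  const <- S4Vectors::metadata(zscoreFeatures(fm))$constant_features
  live <- setdiff(seq_len(2352), const)
  expect_lt(max(abs(colMeans(z[, live]))), 1e-9)
  expect_lt(max(abs(apply(z[, live], 2, sd) - 1)), 1e-9)
})

test_that("the feature CSV round-trips with embedding columns", {
  res <- threeTypeFeatureMatrix(n_per = 4, seed = 9)
  fm <- appendEmbedding(res$fm, embed2D(res$fm, n_neighbors = 5))
  f <- tempfile(fileext = ".csv")
  writeFeatureCSV(fm, f)
  header <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(gsub('"', "", header[1]), "syllable_id")
  expect_true(all(c('"px0001"', '"px2352"', '"umap1"', '"umap2"') %in% header))
  back <- readFeatureCSV(f)
  expect_equal(featureValues(back), featureValues(fm), tolerance = 1e-9)
  expect_equal(syllableIds(back), syllableIds(fm))
  expect_equal(SummarizedExperiment::colData(back)$umap1,
               unname(SummarizedExperiment::colData(fm)$umap1),
               tolerance = 1e-9)
  unlink(f)
})
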