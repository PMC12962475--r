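# Syllable synthesis, motif assembly, acoustic features, WAV round trip.

test_that("a pure tone has the requested length and spectral peak", {
  w <- synthSyllable(syllableSpec("tone", duration_s = 0.1,
                                  f0_start_hz = 1000, f0_end_hz = 1000))
  expect_equal(length(w), 4410L)
  expect_lte(max(abs(samples(w))), 1)
  expect_equal(max(abs(samples(w))), 0.9, tolerance = 1e-12)
  # spectral argmax of the full signal within one DFT bin of 1000 Hz
  pw <- Mod(fft(samples(w)))^2
  n <- length(w)
  peak_hz <- (which.max(pw[1:(n / 2)]) - 1) * 44100 / n
  expect_lt(abs(peak_hz - 1000), 44100 / n + 1e-9)
})

test_that("synthesis is a pure function of spec and sample rate", {
  spec <- syllableSpec("noisy", noise_fraction = 0.5, am_rate_hz = 20,
                       rng_seed = 77)
  w1 <- synthSyllable(spec)
  w2 <- synthSyllable(spec)
  expect_identical(samples(w1), samples(w2))
  # and the global RNG stream is untouched
  set.seed(9); before <- rnorm(3)
  set.seed(9); invisible(synthSyllable(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noise has higher Wiener entropy than a tone, chirp higher FM", {
  tone <- synthSyllable(syllableSpec("t", noise_fraction = 0))
  noise <- synthSyllable(syllableSpec("n", noise_fraction = 1, rng_seed = 3))
  ft <- acousticFeatures(tone); fn <- acousticFeatures(noise)
  expect_gt(fn$wiener_entropy, ft$wiener_entropy)
  expect_lte(fn$wiener_entropy, 0)
  expect_lte(ft$wiener_entropy, 0)

  flat <- acousticFeatures(synthSyllable(
    syllableSpec("flat", duration_s = 0.2, f0_start_hz = 1000,
                 f0_end_hz = 1000)))
  chirp <- acousticFeatures(synthSyllable(
    syllableSpec("chirp", duration_s = 0.2, f0_start_hz = 500,
                 f0_end_hz = 2000)))
  expect_equal(flat$fm, 0, tolerance = 44100 / 512)  # within one bin width
  expect_gt(chirp$fm, flat$fm)
})

test_that("Wiener entropy is zero exactly for a flat power spectrum", {
  expect_equal(songpath:::wienerEntropy(matrix(1, 257, 1)), 0)
  expect_lt(songpath:::wienerEntropy(matrix(c(rep(1, 256), 100), 257, 1)), 0)
})

test_that("an all-zero signal yields the sentinel entropy with a warning", {
  w <- new("Waveform", samples = numeric(1000), sample_rate_hz = 44100L)
  expect_warning(f <- acousticFeatures(w), "all-zero")
  expect_identical(f$wiener_entropy, -Inf)
})

test_that("motif assembly follows the exact length formula", {
  syl <- synthSyllable(syllableSpec("a", duration_s = 0.1))
  motif <- assembleMotif(rep(list(syl), 5))
  expect_equal(length(motif), 5 * 4410 + 4 * 1102)

  one <- assembleMotif(list(syl))
  expect_identical(samples(one), samples(syl))

  s16 <- synthSyllable(syllableSpec("b", duration_s = 0.05), 16000L)
  expect_equal(length(assembleMotif(list(s16, s16))), 2 * 800 + 400)

  # property: sum of lengths + (n-1) * round(gap * sr), random n and gaps
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    gap <- runif(1, 0, 0.1)
    parts <- lapply(seq_len(n), function(i)
      synthSyllable(syllableSpec(paste0("p", i),
                                 duration_s = runif(1, 0.02, 0.2)), 22050L))
    expected <- sum(vapply(parts, length, numeric(1))) +
      (n - 1) * round(gap * 22050)
    expect_equal(length(assembleMotif(parts, gap_s = gap)), expected)
  }
})

test_that("invalid synthesis inputs are rejected clearly", {
  expect_error(assembleMotif(list(
    synthSyllable(syllableSpec("a"), 44100L),
    synthSyllable(syllableSpec("b"), 16000L))), "sample rate")
  expect_error(synthSyllable(syllableSpec("hi", f0_start_hz = 30000)),
               "Nyquist")
  expect_error(syllableSpec("bad", noise_fraction = 1.5), "noise_fraction")
  expect_error(syllableSpec("bad", duration_s = -1), "duration_s")
})

test_that("feature match report flags only genuine mismatches", {
  set.seed(1)
  fa <- do.call(rbind, lapply(randomSyllableSpecs(8, seed = 21),
                              function(s) acousticFeatures(synthSyllable(s, 22050L))))
  rep_same <- featureMatchReport(fa, fa)
  expect_true(all(rep_same$std_diff == 0))
  expect_false(any(rep_same$flagged))

  short <- do.call(rbind, lapply(1:6, function(i) acousticFeatures(
    synthSyllable(syllableSpec(paste0("s", i),
                               duration_s = runif(1, 0.05, 0.06)), 22050L))))
  long <- do.call(rbind, lapply(1:6, function(i) acousticFeatures(
    synthSyllable(syllableSpec(paste0("l", i),
                               duration_s = runif(1, 0.2, 0.3)), 22050L))))
  rep_dur <- featureMatchReport(short, long)
  expect_true(rep_dur$flagged[rep_dur$feature == "duration_s"])

  # two draws from one generator spec (n = 20 each, only the noise seed
  # varies) stay mostly unflagged, and far below a clearly mismatched pair:
  # with 20 syllables the median's sampling error alone spans a sizeable
  # fraction of the IQR scale, so individual features can brush the 0.5
  # threshold even for identically distributed sets
  draw <- function(seed_base) do.call(rbind, lapply(1:20, function(i)
    acousticFeatures(synthSyllable(
      syllableSpec(paste0("g", i), duration_s = 0.1, f0_start_hz = 900,
                   f0_end_hz = 1400, n_harmonics = 2, noise_fraction = 0.5,
                   rng_seed = seed_base + i), 22050L))))
  rep_gen <- featureMatchReport(draw(0), draw(5000))
  expect_lt(sum(rep_gen$flagged), nrow(rep_gen) / 2)
  expect_false(rep_gen$flagged[rep_gen$feature == "duration_s"])
  # a relaxed threshold absorbs the sampling noise of same-generator draws
  expect_false(any(featureMatchReport(draw(0), draw(5000),
                                      threshold = 1.5)$flagged))
})

test_that("WAV files round-trip at 16-bit precision", {
  w <- synthSyllable(syllableSpec("io", duration_s = 0.05,
                                  noise_fraction = 0.3))
  f <- tempfile(fileext = ".wav")
  writeWav(w, f)
  r <- readWav(f)
  expect_equal(sampleRate(r), 44100L)
  expect_equal(length(r), length(w))
  expect_lt(max(abs(samples(r) - samples(w))), 1 / 32767 + 1e-9)
  unlink(f)
})
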