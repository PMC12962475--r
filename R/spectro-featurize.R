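## Spectrogram imaging pipeline: STFT in dB -> square blue-white-red
## colormapped image -> bilinear resize to 28 x 28 x 3 -> 2352-element pixel
## vector in [0, 1].

#' Short-time Fourier transform in decibels
#'
#' Computes the magnitude-squared STFT of a waveform with the imaging
#' parameters used throughout the featurization pipeline: Hann window of
#' \code{win_length} samples, hop \code{hop_length}, zero-padded to
#' \code{n_fft} (no centered padding; frames lie fully inside the signal, so
#' the frame count is \code{floor((N - win_length)/hop_length) + 1}). Power
#' is expressed in dB (10 log10) and clipped to an 80-dB dynamic range below
#' the per-image maximum, so that subsequent min-max normalization is not
#' dominated by silence.
#'
#' @param w a [Waveform-class] of at least \code{win_length} samples.
#' @param n_fft FFT size (default 512); the frequency axis has
#'   \code{n_fft/2 + 1} bins.
#' @param win_length analysis window length (default 256).
#' @param hop_length hop between frames (default 8).
#' @param floor_db dynamic-range clip below the maximum, in dB (default 80).
#' @return numeric matrix, \code{n_fft/2 + 1} frequency rows (DC first) by
#'   one column per frame.
#' @examples
#' db <- stftDb(synthSyllable(syllableSpec("tone", duration_s = 0.1)))
#' dim(db)  # 257 x 520
#' @export
stftDb <- function(w, n_fft = 512L, win_length = 256L, hop_length = 8L,
                   floor_db = 80) {
  stopifnot(is(w, "Waveform"))
  x <- samples(w)
  if (length(x) < win_length)
    stop("waveform too short for STFT: need at least ", win_length,
         " samples, got ", length(x))
  fr <- frameSignal(x, win_length, hop_length) * hannWindow(win_length)
  padded <- rbind(fr, matrix(0, n_fft - win_length, ncol(fr)))
  pow <- (abs(stats::mvfft(padded))[seq_len(n_fft %/% 2 + 1L), ,
                                    drop = FALSE])^2
  db <- 10 * log10(pmax(pow, .Machine$double.xmin))
  pmax(db, max(db) - floor_db)
}

# Diverging blue -> white -> red transfer, piecewise linear per channel:
# 0 -> (0,0,1), 0.5 -> (1,1,1), 1 -> (1,0,0).
bwrColormap <- function(t) {
  lo <- pmin(2 * t, 1)
  hi <- pmin(2 - 2 * t, 1)
  cbind(r = lo, g = pmin(lo, hi), b = hi)
}

#' Render a dB spectrogram as a square colormapped image
#'
#' Min-max normalizes the dB matrix to [0, 1] (per image, so two syllables
#' identical up to gain map to identical images), resamples the time axis by
#' linear interpolation to match the frequency-axis pixel count (a square
#' canvas independent of syllable duration), and maps values through a
#' diverging blue-white-red transfer: 0 maps to blue (0,0,1), 0.5 to white
#' (1,1,1) and 1 to red (1,0,0), piecewise-linearly per channel. A constant
#' input matrix carries no contrast and is mapped uniformly to the midpoint
#' color, with a warning.
#'
#' @param db_matrix frequency x time dB matrix from [stftDb()].
#' @return numeric array \code{n x n x 3} with values in [0, 1], where
#'   \code{n} is the number of frequency bins.
#' @export
renderColormap <- function(db_matrix) {
  stopifnot(is.matrix(db_matrix), nrow(db_matrix) > 0L, ncol(db_matrix) > 0L)
  rng <- range(db_matrix)
  if (rng[1] == rng[2]) {
    warning("constant spectrogram: mapping uniformly to the midpoint color")
    norm <- matrix(0.5, nrow(db_matrix), ncol(db_matrix))
  } else {
    norm <- (db_matrix - rng[1]) / (rng[2] - rng[1])
  }
  n <- nrow(norm)
  if (ncol(norm) != n) {
    # stretch/compress time axis onto the square canvas
    if (ncol(norm) == 1L) {
      norm <- norm[, rep(1L, n), drop = FALSE]
    } else {
      at <- seq(1, ncol(norm), length.out = n)
      norm <- t(apply(norm, 1L, function(row) approx(seq_along(row), row,
                                                     xout = at)$y))
    }
  }
  rgb <- bwrColormap(as.vector(norm))
  array(rgb, dim = c(n, n, 3L))
}

# Center-aligned bilinear resampling of a matrix to out_h x out_w: output
# pixel centers map to (i + 0.5) * scale - 0.5 in source coordinates, so 2x
# decimation equals block averaging.
bilinearResize <- function(m, out_h, out_w) {
  srcPos <- function(n_out, n_in) {
    p <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
    pmin(pmax(p, 0), n_in - 1)
  }
  interpAxis <- function(mat, pos) {  # interpolate along rows of mat
    i0 <- floor(pos)
    i1 <- pmin(i0 + 1, nrow(mat) - 1)
    f <- pos - i0
    mat[i0 + 1L, , drop = FALSE] * (1 - f) + mat[i1 + 1L, , drop = FALSE] * f
  }
  tmp <- interpAxis(m, srcPos(out_h, nrow(m)))
  t(interpAxis(t(tmp), srcPos(out_w, ncol(m))))
}

#' Resize a spectrogram image to 28 x 28 and flatten
#'
#' Bilinearly resizes each color channel to 28 x 28 pixels (center-aligned
#' sampling) and flattens in fixed row-major, channel-interleaved order:
#' pixel (1,1) R, G, B, then pixel (1,2) R, G, B, and so on row by row. The
#' result is the 2352-element feature vector (28 x 28 x 3) with every value
#' in [0, 1].
#'
#' @param img numeric array h x w x 3 with values in [0, 1] (any h, w).
#' @return numeric vector of length 2352.
#' @export
resizeFlatten <- function(img) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("image values must lie in [0, 1]")
  small <- vapply(1:3, function(ch) bilinearResize(img[, , ch], 28L, 28L),
                  matrix(0, 28, 28))
  as.vector(aperm(small, c(3L, 2L, 1L)))
}

#' Featurize syllables into a pixel-feature matrix
#'
#' Runs the full imaging pipeline on each syllable — [stftDb()],
#' [renderColormap()], [resizeFlatten()] — and assembles the 2352-element
#' vectors into a [SongFeatureMatrix-class] (features as rows, syllables as
#' columns). Featurization is deterministic: an identical waveform always
#' yields an identical vector.
#'
#' @param waveforms list of [Waveform-class] syllables.
#' @param ids character syllable labels (default \code{syl_1, syl_2, ...}).
#' @param bird_id optional per-syllable bird labels (recycled if length 1).
#' @param ... passed to [stftDb()].
#' @return a [SongFeatureMatrix-class] with assay \code{"pixels"}.
#' @examples
#' specs <- lapply(1:3, function(i) syllableSpec(paste0("s", i),
#'   f0_start_hz = 500 * i, f0_end_hz = 500 * i))
#' fm <- featurizeSyllables(lapply(specs, synthSyllable))
#' dim(fm)  # 2352 x 3
#' @export
featurizeSyllables <- function(waveforms, ids = NULL, bird_id = NULL, ...) {
  stopifnot(length(waveforms) > 0L)
  if (is.null(ids)) ids <- paste0("syl_", seq_along(waveforms))
  vecs <- vapply(waveforms,
                 function(w) resizeFlatten(renderColormap(stftDb(w, ...))),
                 numeric(2352L))
  songFeatureMatrix(t(vecs), ids = ids, bird_id = bird_id)
}
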