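## Frame-based acoustic features used to match stimulus syllables: Wiener
## entropy, frequency modulation, goodness of pitch, amplitude modulation,
## peak frequency, cepstral pitch and RMS amplitude.

hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

# Frame a signal into columns (no centering/padding; frames fully inside).
frameSignal <- function(x, win, hop) {
  n_frames <- max(1L, floor((length(x) - win) / hop) + 1L)
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(x[idx], nrow = win)
}

# One-sided power spectra of framed, Hann-windowed signal: (win/2+1) x frames.
framePowerSpectra <- function(x, win, hop) {
  fr <- frameSignal(x, win, hop) * hannWindow(win)
  sp <- stats::mvfft(fr)
  (abs(sp)[seq_len(win %/% 2 + 1L), , drop = FALSE])^2
}

# Wiener entropy of one or more power spectra (columns = frames):
# mean over frames of ln(geometric mean / arithmetic mean). <= 0 always,
# = 0 iff each frame's spectrum is flat.
wienerEntropy <- function(power) {
  power <- as.matrix(power)
  per_frame <- apply(power, 2L, function(p) {
    if (all(p == 0)) return(NA_real_)
    mean(log(pmax(p, .Machine$double.xmin))) - log(mean(p))
  })
  mean(per_frame)
}

# Magnitude of the analytic signal (FFT-based Hilbert envelope).
hilbertEnvelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Extract acoustic features from a waveform
#'
#' Computes the frame-based acoustic features used to check that stimulus
#' syllables are matched on everything except the property under study:
#' \describe{
#'   \item{wiener_entropy}{mean over frames of the log ratio of geometric to
#'     arithmetic mean of the power spectrum; 0 for a flat (white) spectrum,
#'     strongly negative for pure tones. Always <= 0.}
#'   \item{fm}{frequency modulation: mean absolute frame-to-frame change of
#'     the spectral peak frequency (Hz per frame).}
#'   \item{goodness_of_pitch}{mean per-frame peak cepstral magnitude within
#'     the 400-1000 Hz pitch band; high for strongly periodic sounds.}
#'   \item{am}{amplitude modulation: mean absolute time derivative of the
#'     Hilbert (analytic-signal) envelope, in 1/s.}
#'   \item{peak_frequency_hz}{frequency of the maximum of the frame-averaged
#'     power spectrum.}
#'   \item{mean_pitch_hz}{mean cepstral pitch estimate over frames (400-1000
#'     Hz search band).}
#'   \item{rms_amplitude}{root mean square of the samples.}
#' }
#' Analysis frames use a 512-sample Hann window with 75\% overlap (hop 128)
#' by default; this framing is independent of the imaging STFT used for
#' featurization.
#'
#' @param w a [Waveform-class].
#' @param window analysis window length in samples (default 512; shrunk to
#'   the largest power of two that fits a short waveform).
#' @param hop hop size in samples (default \code{window / 4}).
#' @return one-row \code{data.frame} with columns \code{duration_s},
#'   \code{wiener_entropy}, \code{fm}, \code{goodness_of_pitch}, \code{am},
#'   \code{peak_frequency_hz}, \code{mean_pitch_hz}, \code{rms_amplitude}.
#' @examples
#' acousticFeatures(synthSyllable(syllableSpec("tone")))
#' @export
acousticFeatures <- function(w, window = 512L, hop = window %/% 4L) {
  stopifnot(is(w, "Waveform"))
  x <- samples(w)
  if (!length(x)) stop("waveform is empty")
  sr <- sampleRate(w)
  if (length(x) < window) {
    window <- 2^floor(log2(length(x)))
    hop <- max(1L, window %/% 4L)
  }
  if (all(x == 0)) {
    warning("all-zero signal: Wiener entropy undefined, reporting -Inf")
    return(data.frame(duration_s = durationS(w), wiener_entropy = -Inf,
                      fm = 0, goodness_of_pitch = 0, am = 0,
                      peak_frequency_hz = NA_real_, mean_pitch_hz = NA_real_,
                      rms_amplitude = 0))
  }
  pow <- framePowerSpectra(x, window, hop)
  freqs <- (seq_len(nrow(pow)) - 1L) * sr / window
  peak_per_frame <- freqs[apply(pow, 2L, which.max)]
  fm <- if (ncol(pow) > 1L) mean(abs(diff(peak_per_frame))) else 0

  # cepstral pitch: quefrency band for 400-1000 Hz
  q_lo <- max(2L, floor(sr / 1000))
  q_hi <- min(window - 1L, ceiling(sr / 400))
  cep <- apply(pow, 2L, function(p) {
    full <- c(p, rev(p[2:(length(p) - 1L)]))
    cc <- Re(fft(log(pmax(full, .Machine$double.xmin)), inverse = TRUE)) /
      length(full)
    band <- cc[(q_lo + 1L):(q_hi + 1L)]
    c(gof = max(abs(band)), q = q_lo + which.max(abs(band)) - 1L)
  })

  env <- hilbertEnvelope(x)
  am <- if (length(env) > 1L) mean(abs(diff(env))) * sr else 0

  data.frame(
    duration_s = durationS(w),
    wiener_entropy = wienerEntropy(pow),
    fm = fm,
    goodness_of_pitch = mean(cep["gof", ]),
    am = am,
    peak_frequency_hz = freqs[which.max(rowMeans(pow))],
    mean_pitch_hz = mean(sr / cep["q", ]),
    rms_amplitude = sqrt(mean(x^2))
  )
}

#' Compare acoustic features of two syllable sets
#'
#' Summarizes each acoustic feature in two syllable sets (medians and
#' interquartile ranges) and reports a standardized median difference:
#' the difference of medians divided by the pooled IQR-based scale
#' (mean IQR / 1.349, the IQR-to-SD conversion for a normal distribution).
#' Features whose absolute standardized difference exceeds \code{threshold}
#' are flagged as mismatched. Used to verify that long- and short-path
#' stimulus syllables have similar spectral and temporal properties.
#'
#' @param set_a,set_b data.frames of per-syllable features as returned by
#'   [acousticFeatures()] (one row per syllable), non-empty.
#' @param threshold flag threshold on the absolute standardized median
#'   difference (default 0.5).
#' @return data.frame with one row per feature: \code{median_a},
#'   \code{median_b}, \code{iqr_a}, \code{iqr_b}, \code{std_diff},
#'   \code{flagged}.
#' @export
featureMatchReport <- function(set_a, set_b, threshold = 0.5) {
  stopifnot(nrow(set_a) > 0L, nrow(set_b) > 0L)
  feats <- intersect(names(set_a), names(set_b))
  feats <- feats[vapply(set_a[feats], is.numeric, logical(1))]
  rows <- lapply(feats, function(f) {
    a <- set_a[[f]]; b <- set_b[[f]]
    iqr_a <- stats::IQR(a); iqr_b <- stats::IQR(b)
    scale <- mean(c(iqr_a, iqr_b)) / 1.349
    dmed <- median(a) - median(b)
    std <- if (scale > 0) dmed / scale else if (dmed == 0) 0 else Inf
    data.frame(feature = f, median_a = median(a), median_b = median(b),
               iqr_a = iqr_a, iqr_b = iqr_b, std_diff = std,
               flagged = is.infinite(std) || abs(std) > threshold)
  })
  do.call(rbind, rows)
}
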