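## Syllable synthesis: parametric harmonic-stack chirps with controlled noise
## and amplitude modulation, assembled into n-syllable motifs with silent gaps.

# Evaluate expr with the RNG seeded locally; the caller's RNG state is
# untouched (synthesis must be a pure function of its arguments).
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct a syllable specification
#'
#' @param id character label.
#' @param duration_s syllable duration in seconds.
#' @param f0_start_hz,f0_end_hz fundamental-frequency sweep endpoints (Hz).
#' @param n_harmonics number of harmonics in the stack (>= 1).
#' @param harmonic_rolloff amplitude ratio between successive harmonics,
#'   in (0, 1].
#' @param noise_fraction proportion of broadband noise mixed into the
#'   syllable, in [0, 1] (0 = fully tonal, 1 = pure noise).
#' @param am_rate_hz sinusoidal amplitude-modulation rate in Hz (0 = none).
#' @param rng_seed integer seed for the noise component.
#' @return a [SyllableSpec-class].
#' @examples
#' syllableSpec("sweep", f0_start_hz = 600, f0_end_hz = 1800)
#' @export
syllableSpec <- function(id, duration_s = 0.1, f0_start_hz = 1000,
                         f0_end_hz = 1000, n_harmonics = 1,
                         harmonic_rolloff = 0.7, noise_fraction = 0,
                         am_rate_hz = 0, rng_seed = 1) {
  new("SyllableSpec", id = as.character(id), duration_s = duration_s,
      f0_start_hz = f0_start_hz, f0_end_hz = f0_end_hz,
      n_harmonics = as.integer(n_harmonics),
      harmonic_rolloff = harmonic_rolloff, noise_fraction = noise_fraction,
      am_rate_hz = am_rate_hz, rng_seed = as.integer(rng_seed))
}

#' Synthesize one syllable
#'
#' Renders a harmonic stack whose fundamental sweeps linearly from
#' \code{f0_start_hz} to \code{f0_end_hz}, with per-harmonic amplitude decay
#' \code{harmonic_rolloff^(h-1)}, mixes in \code{noise_fraction} Gaussian
#' broadband noise (RMS-matched to the tonal part), applies optional
#' sinusoidal amplitude modulation, 5-ms raised-cosine onset/offset ramps to
#' avoid clicks, and peak-normalizes to 0.9. The output is a deterministic
#' function of \code{(spec, sample_rate_hz)}: repeated calls are
#' bit-identical.
#'
#' @param spec a [SyllableSpec-class].
#' @param sample_rate_hz output sample rate (default 44100).
#' @return a [Waveform-class] of \code{round(duration_s * sample_rate_hz)}
#'   samples.
#' @examples
#' w <- synthSyllable(syllableSpec("tone", duration_s = 0.1))
#' length(w)  # 4410
#' @export
synthSyllable <- function(spec, sample_rate_hz = 44100L) {
  stopifnot(is(spec, "SyllableSpec"))
  validObject(spec)
  sr <- as.integer(sample_rate_hz)
  nyq <- sr / 2
  if (spec@f0_start_hz >= nyq || spec@f0_end_hz >= nyq)
    stop("fundamental frequency must stay below the Nyquist frequency (",
         nyq, " Hz)")
  n <- round(spec@duration_s * sr)
  t <- (seq_len(n) - 1L) / sr
  # linear chirp phase: f(t) = f0 + (f1 - f0) * t / T
  sweep <- (spec@f0_end_hz - spec@f0_start_hz) / spec@duration_s
  phase0 <- spec@f0_start_hz * t + 0.5 * sweep * t^2
  tonal <- numeric(n)
  for (h in seq_len(spec@n_harmonics)) {
    fh_max <- h * max(spec@f0_start_hz, spec@f0_end_hz)
    if (fh_max >= nyq) break  # drop aliasing harmonics silently
    tonal <- tonal + spec@harmonic_rolloff^(h - 1) * sin(2 * pi * h * phase0)
  }
  sig <- tonal
  if (spec@noise_fraction > 0) {
    noise <- withLocalSeed(spec@rng_seed, rnorm(n))
    rms <- function(x) sqrt(mean(x^2))
    if (rms(tonal) > 0) noise <- noise * (rms(tonal) / rms(noise))
    sig <- (1 - spec@noise_fraction) * tonal + spec@noise_fraction * noise
  }
  if (spec@am_rate_hz > 0)
    sig <- sig * (0.5 + 0.5 * cos(2 * pi * spec@am_rate_hz * t))
  # 5 ms raised-cosine ramps
  nr <- min(round(0.005 * sr), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1L) / nr))
    sig[seq_len(nr)] <- sig[seq_len(nr)] * ramp
    sig[n - seq_len(nr) + 1L] <- sig[n - seq_len(nr) + 1L] * ramp
  }
  peak <- max(abs(sig))
  if (peak > 0) sig <- sig * (0.9 / peak)
  new("Waveform", samples = sig, sample_rate_hz = sr)
}

#' Assemble a motif from syllables
#'
#' Concatenates syllable waveforms with a silent gap between consecutive
#' syllables (default 25 ms, the gap used in five-syllable song motifs). The
#' output length is the sum of the syllable lengths plus
#' \code{(n - 1) * round(gap_s * sr)} zero samples.
#'
#' @param syllables non-empty list of [Waveform-class] objects sharing one
#'   sample rate.
#' @param gap_s silent gap between syllables, seconds (default 0.025).
#' @return a [Waveform-class].
#' @examples
#' syl <- synthSyllable(syllableSpec("a", duration_s = 0.1))
#' motif <- assembleMotif(rep(list(syl), 5))
#' length(motif)  # 5*4410 + 4*1102
#' @export
assembleMotif <- function(syllables, gap_s = 0.025) {
  if (!length(syllables)) stop("need at least one syllable")
  stopifnot(all(vapply(syllables, is, logical(1), "Waveform")), gap_s >= 0)
  srs <- vapply(syllables, sampleRate, integer(1))
  if (length(unique(srs)) != 1L)
    stop("all syllables must share one sample rate; got: ",
         paste(unique(srs), collapse = ", "))
  gap <- numeric(round(gap_s * srs[1]))
  parts <- vector("list", 2L * length(syllables) - 1L)
  parts[seq(1L, length(parts), by = 2L)] <- lapply(syllables, samples)
  if (length(syllables) > 1L)
    parts[seq(2L, length(parts), by = 2L)] <- list(gap)
  new("Waveform", samples = unlist(parts, use.names = FALSE),
      sample_rate_hz = srs[1])
}
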