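#' Read and write mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE I/O for the mono PCM files the pipeline exchanges.
#' \code{writeWav()} quantizes samples to signed 16-bit integers;
#' \code{readWav()} accepts 8-, 16- or 32-bit integer PCM and returns the
#' first channel scaled to [-1, 1].
#'
#' @param w a [Waveform-class].
#' @param path file path.
#' @return \code{readWav()} returns a [Waveform-class]; \code{writeWav()}
#'   returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(synthSyllable(syllableSpec("a", duration_s = 0.05)), f)
#' w <- readWav(f)
#' @export
writeWav <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  sr <- as.integer(sampleRate(w))
  pcm <- as.integer(round(pmax(-1, pmin(1, samples(w))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname writeWav
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sr <- NA_integer_; bits <- NA_integer_; n_chan <- 1L; out <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      n_chan <- fmt[2]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0L) readBin(con, raw(), n = extra)
    } else if (tag == "data") {
      if (is.na(bits)) stop("malformed WAV: data chunk before fmt")
      n <- size %/% (bits %/% 8L)
      out <- switch(as.character(bits),
        "8"  = (readBin(con, integer(), n = n, size = 1, signed = FALSE) - 128) / 128,
        "16" = pmax(-1, readBin(con, integer(), n = n, size = 2,
                                endian = "little") / 32767),
        "32" = readBin(con, integer(), n = n, size = 4, endian = "little") / 2147483648,
        stop("unsupported bit depth: ", bits))
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(out)) stop("no data chunk found in ", path)
  if (n_chan > 1L) out <- out[seq(1L, length(out), by = n_chan)]
  new("Waveform", samples = out, sample_rate_hz = as.integer(sr))
}
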