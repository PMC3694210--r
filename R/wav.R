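# Minimal PCM-16 mono RIFF/WAVE reader and writer. No WAV package ships with
# the target environment, so the container format is handled here; only the
# canonical 16-bit mono linear-PCM layout is supported.

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to signed 16-bit.
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("samples must be a non-empty numeric vector")
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")        # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono linear PCM is supported: ", path)
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit PCM is supported: ", path)
    } else if (id == "data") {
      if (is.null(sample_rate)) stop("data chunk before fmt chunk: ", path)
      pcm <- readBin(con, "integer", size / 2, size = 2,
                     endian = "little", signed = TRUE)
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}
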