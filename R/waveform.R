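#' Construct a waveform record
#'
#' A waveform is a uniformly sampled, possibly multi-channel time series
#' recorded at one station. Seismic records are sampled at 200 Hz (three
#' orthogonal ground-motion components); acoustic records carry four
#' microphone channels at a much higher rate. All channels of one record
#' share a common start time (stations are GPS-synchronized).
#'
#' @param samples numeric vector (single channel), matrix with one column
#'   per channel and one row per sample, or list of per-channel vectors
#'   (which must all have the same length).
#' @param rate sampling rate in Hz; must be positive.
#' @param start_time record start in seconds (common epoch across stations).
#' @param station_id station identifier.
#' @param modality `"seismic"` or `"acoustic"`.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate, start_time = 0, station_id = "sta",
                     modality = c("seismic", "acoustic")) {
  modality <- match.arg(modality)
  if (is.list(samples)) {
    lens <- lengths(samples)
    if (length(unique(lens)) > 1)
      stop("channels of record '", station_id,
           "' have mismatched lengths: ", paste(lens, collapse = ", "))
    samples <- do.call(cbind, samples)
  }
  if (!is.matrix(samples)) samples <- matrix(as.numeric(samples), ncol = 1)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("sampling rate must be a single positive number")
  if (any(!is.finite(samples)))
    stop("waveform '", station_id, "' contains non-finite samples")
  structure(
    list(samples = samples, rate = rate, start_time = start_time,
         station_id = as.character(station_id), modality = modality),
    class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> station %s [%s], %d channel(s), %d samples @ %g Hz (%.2f s)\n",
              x$station_id, x$modality, ncol(x$samples), nrow(x$samples),
              x$rate, nrow(x$samples) / x$rate))
  invisible(x)
}

n_channels <- function(w) ncol(w$samples)
duration <- function(w) nrow(w$samples) / w$rate

#' Stack all channels of a waveform
#'
#' Sums the channels sample-by-sample into a single channel. Coherent signal
#' adds linearly across channels while independent noise adds in power only,
#' so stacking the four microphone channels of one station increases the
#' signal-to-noise ratio.
#'
#' @param w a [waveform()].
#' @return A single-channel `waveform` with all metadata preserved.
#' @export
stack_channels <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (n_channels(w) < 1)
    stop("record '", w$station_id, "' has no channels")
  out <- w
  out$samples <- matrix(rowSums(w$samples), ncol = 1)
  out
}

#' Resample a waveform to a lower analysis rate
#'
#' Applies a zero-phase low-pass anti-alias filter (8th-order Butterworth at
#' 80% of the target Nyquist, run forwards and backwards) and then resamples
#' by linear interpolation onto the target time grid. Used to bring acoustic
#' records down to a common analysis rate so that seismic and acoustic
#' spectrograms share comparable time resolution.
#'
#' @param w a [waveform()].
#' @param target_rate new sampling rate in Hz, at most `w$rate`.
#' @return A `waveform` at `target_rate`.
#' @export
decimate_waveform <- function(w, target_rate) {
  stopifnot(inherits(w, "waveform"))
  if (target_rate > w$rate)
    stop("target rate exceeds the record's sampling rate")
  if (target_rate == w$rate) return(w)
  bf <- signal::butter(4, 0.8 * target_rate / w$rate, type = "low")
  n_out <- floor(nrow(w$samples) / w$rate * target_rate)
  t_old <- (seq_len(nrow(w$samples)) - 1) / w$rate
  t_new <- (seq_len(n_out) - 1) / target_rate
  out <- apply(w$samples, 2, function(ch) {
    filt <- signal::filtfilt(bf, ch)
    stats::approx(t_old, filt, xout = t_new, rule = 2)$y
  })
  w$samples <- matrix(out, ncol = n_channels(w))
  w$rate <- target_rate
  w
}

#' Extract a time window from a waveform
#'
#' @param w a [waveform()].
#' @param start,end window limits in the same epoch as `w$start_time`.
#' @return A `waveform` covering the requested interval.
#' @export
window_waveform <- function(w, start, end) {
  stopifnot(inherits(w, "waveform"), end > start)
  i0 <- max(1L, floor((start - w$start_time) * w$rate) + 1L)
  i1 <- min(nrow(w$samples), ceiling((end - w$start_time) * w$rate))
  if (i1 <= i0) stop("window outside record '", w$station_id, "'")
  w$samples <- w$samples[i0:i1, , drop = FALSE]
  w$start_time <- w$start_time + (i0 - 1L) / w$rate
  w
}

# ---- plain-text waveform I/O -------------------------------------------------
# One CSV per record: commented header lines carry the metadata, then one
# column per channel. Chosen over binary containers so that fixtures remain
# human-readable and diff-able.

#' Write a waveform to CSV
#'
#' The file holds `# key=value` comment lines (rate, start_time, station_id,
#' modality) followed by one column per channel.
#'
#' @param w a [waveform()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rate=%.10g", w$rate),
    sprintf("# start_time=%.10g", w$start_time),
    sprintf("# station_id=%s", w$station_id),
    sprintf("# modality=%s", w$modality)), con)
  utils::write.table(
    w$samples, con, sep = ",", row.names = FALSE,
    col.names = paste0("ch", seq_len(n_channels(w))))
  invisible(path)
}

#' Read a waveform from CSV
#'
#' @param path file written by [write_waveform_csv()].
#' @return A [waveform()].
#' @export
read_waveform_csv <- function(path) {
  hdr <- readLines(path, n = 16L)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  need <- c("rate", "start_time", "station_id", "modality")
  if (!all(need %in% names(meta)))
    stop("waveform CSV '", path, "' is missing metadata header lines")
  dat <- utils::read.csv(path, comment.char = "#")
  waveform(as.matrix(dat), rate = as.numeric(meta[["rate"]]),
           start_time = as.numeric(meta[["start_time"]]),
           station_id = meta[["station_id"]], modality = meta[["modality"]])
}

# ---- WAV I/O ----------------------------------------------------------------

#' Write a waveform as a 16-bit PCM WAV file
#'
#' Samples are scaled by `scale` (default: the maximum absolute amplitude)
#' to span the 16-bit range. WAV carries no epoch, so `start_time`,
#' `station_id` and `modality` are not preserved; use the CSV writer when
#' metadata must round-trip.
#'
#' @param w a [waveform()].
#' @param path output path.
#' @param scale amplitude mapped to full scale; defaults to `max(abs(samples))`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, scale = NULL) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  if (is.null(scale)) scale <- max(abs(x), 1e-12)
  pcm <- as.integer(pmax(-32767, pmin(32767, round(x / scale * 32767))))
  nch <- n_channels(w)
  # interleave channels
  pcm <- as.vector(t(matrix(pcm, ncol = nch)))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate) * nch * 2L, con, size = 4, endian = "little")
  writeBin(nch * 2L, con, size = 2, endian = "little")    # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file as a waveform
#'
#' @param path WAV file path.
#' @param station_id,modality,start_time metadata to attach (WAV stores none).
#' @return A [waveform()] with samples in `[-1, 1]`.
#' @export
read_wav <- function(path, station_id = "sta", modality = "acoustic",
                     start_time = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("'", path, "' is not a RIFF/WAV file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("'", path, "' is not a WAV file")
  rate <- NULL; nch <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in '", path, "'")
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM WAV is supported")
      nch <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM WAV is supported")
      seek(con, len - 16L, origin = "current")
    } else if (id == "data") {
      pcm <- readBin(con, "integer", len / 2L, size = 2, signed = TRUE,
                     endian = "little")
      break
    } else {
      seek(con, len, origin = "current")
    }
  }
  x <- matrix(pcm / 32767, ncol = nch, byrow = TRUE)
  waveform(x, rate = rate, start_time = start_time,
           station_id = station_id, modality = modality)
}
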