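#' Compute a magnitude spectrogram
#'
#' Short-time Fourier transform of a (single-channel) waveform with a Hann
#' window, returning the magnitude image truncated above `f_max`. Rumbles
#' live between 20 and 40 Hz, so frequencies above the seismometer's flat
#' response limit carry no usable signal and are dropped.
#'
#' @param w a [waveform()]; multi-channel records are stacked first.
#' @param window_length STFT window in seconds (default 0.5 s resolves a
#'   20-40 Hz contour at 2 Hz).
#' @param overlap fraction of window overlap in `[0, 1)` (default 0.9,
#'   giving a 0.05 s time bin at the defaults).
#' @param f_max highest frequency retained, in Hz; must not exceed Nyquist.
#' @return An object of class `spectrogram`: list with `mag` (freq x time,
#'   non-negative), `freq` (Hz, ascending), `time` (bin centres, seconds in
#'   the record's epoch), `dt` (bin spacing), `start_time`, `station_id`,
#'   `modality`.
#' @export
compute_spectrogram <- function(w, window_length = 0.5, overlap = 0.9,
                                f_max = 100) {
  stopifnot(inherits(w, "waveform"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (f_max > w$rate / 2)
    stop("f_max (", f_max, " Hz) exceeds the Nyquist frequency (",
         w$rate / 2, " Hz)")
  n_win <- round(window_length * w$rate)
  if (n_win < 8) stop("window too short: fewer than 8 samples")
  if (n_win > nrow(w$samples))
    stop("window longer than record '", w$station_id, "'")
  if (n_channels(w) > 1) w <- stack_channels(w)
  hop <- max(1L, round(n_win * (1 - overlap)))
  sg <- signal::specgram(as.vector(w$samples), n = n_win, Fs = w$rate,
                         window = signal::hanning(n_win), overlap = n_win - hop)
  keep <- sg$f <= f_max
  mag <- abs(sg$S[keep, , drop = FALSE])
  # bin centres on the record's absolute time axis
  tt <- w$start_time + ((seq_len(ncol(mag)) - 1) * hop + n_win / 2) / w$rate
  structure(
    list(mag = mag, freq = sg$f[keep], time = tt, dt = hop / w$rate,
         start_time = w$start_time, station_id = w$station_id,
         modality = w$modality),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> station %s [%s], %d freq x %d time bins, dt=%.3g s, f in [%g, %g] Hz\n",
              x$station_id, x$modality, nrow(x$mag), ncol(x$mag), x$dt,
              min(x$freq), max(x$freq)))
  invisible(x)
}

#' Enhancement parameters for structure-tensor spectrogram filtering
#'
#' @param gradient_scale Gaussian smoothing (in bins) applied before
#'   differentiation.
#' @param integration_scale Gaussian smoothing (in bins) of the tensor
#'   components; sets the neighbourhood over which anisotropy is judged.
#' @param coherence_exponent exponent applied to the coherence map; larger
#'   values suppress weakly oriented structure harder.
#' @param floor minimum weight in `[0, 1]` so that no pixel is zeroed
#'   entirely.
#' @return An `enhancement_params` list.
#' @export
enhancement_params <- function(gradient_scale = 1, integration_scale = 3,
                               coherence_exponent = 1, floor = 0.05) {
  stopifnot(gradient_scale > 0, integration_scale > 0,
            floor >= 0, floor <= 1)
  structure(list(gradient_scale = gradient_scale,
                 integration_scale = integration_scale,
                 coherence_exponent = coherence_exponent, floor = floor),
            class = "enhancement_params")
}

# Separable Gaussian smoothing with replicated edges. sigma in bins.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], r), v, rep(v[n], r))
    stats::filter(padded, k, sides = 2)[(r + 1):(r + n)]
  }
  m <- apply(mat, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

#' Structure-tensor coherence map of an image
#'
#' Computes per-pixel orientation coherence: the image is smoothed at
#' `gradient_scale`, differentiated by central differences, the gradient
#' outer-product tensor is smoothed componentwise at `integration_scale`,
#' and coherence is the normalized eigenvalue gap
#' `((l1 - l2) / (l1 + l2 + eps))^exponent`. Coherence is near 1 on oriented
#' ridges and edges (such as a rumble's frequency contour) and near 0 on
#' isotropic texture such as broadband noise.
#'
#' @param mat numeric matrix (image).
#' @param params an [enhancement_params()].
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
coherence_map <- function(mat, params = enhancement_params()) {
  stopifnot(is.matrix(mat), all(is.finite(mat)))
  sm <- gaussian_smooth(mat, params$gradient_scale)
  nr <- nrow(sm); nc <- ncol(sm)
  # central differences, replicated edges
  gy <- (sm[c(2:nr, nr), ] - sm[c(1, 1:(nr - 1)), ]) / 2  # along freq
  gx <- (sm[, c(2:nc, nc)] - sm[, c(1, 1:(nc - 1))]) / 2  # along time
  j11 <- gaussian_smooth(gx * gx, params$integration_scale)
  j22 <- gaussian_smooth(gy * gy, params$integration_scale)
  j12 <- gaussian_smooth(gx * gy, params$integration_scale)
  gap <- sqrt((j11 - j22)^2 + 4 * j12^2)   # l1 - l2
  tr <- j11 + j22                          # l1 + l2 >= 0
  coh <- (gap / (tr + 1e-12))^params$coherence_exponent
  pmin(pmax(coh, 0), 1)
}

#' Enhance a spectrogram by structure-tensor coherence weighting
#'
#' Multiplies each magnitude pixel by `max(coherence, floor)`, where the
#' coherence map is computed on the log-compressed image (`log1p`), so that
#' the weighting responds to contour shape rather than absolute loudness.
#' Sharp rising/falling frequency contours (rumbles) are preserved while
#' isotropic noise and broadband bursts are attenuated towards `floor`.
#'
#' @param s a [compute_spectrogram()] result.
#' @param params an [enhancement_params()].
#' @return A `spectrogram` with identical axes and weighted magnitudes.
#' @export
enhance_spectrogram <- function(s, params = enhancement_params()) {
  stopifnot(inherits(s, "spectrogram"))
  if (any(!is.finite(s$mag))) stop("spectrogram magnitudes must be finite")
  coh <- coherence_map(log1p(s$mag), params)
  s$mag <- s$mag * pmax(coh, params$floor)
  s
}

#' Write a spectrogram to a portable text container
#'
#' The magnitude matrix goes to `<path>.txt` (whitespace-separated, one row
#' per frequency bin) and the axes plus metadata to a `<path>.json` sidecar.
#'
#' @param s a `spectrogram`.
#' @param path output path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(s, path) {
  stopifnot(inherits(s, "spectrogram"))
  utils::write.table(s$mag, paste0(path, ".txt"),
                     row.names = FALSE, col.names = FALSE)
  meta <- list(freq_hz = s$freq, time_s = s$time, dt_s = s$dt,
               start_time = s$start_time, station_id = s$station_id,
               modality = s$modality)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectrogram written by [write_spectrogram()]
#'
#' @param path the path stem used when writing.
#' @return A `spectrogram`.
#' @export
read_spectrogram <- function(path) {
  mag <- as.matrix(utils::read.table(paste0(path, ".txt")))
  dimnames(mag) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(mag = mag, freq = meta$freq_hz, time = meta$time_s, dt = meta$dt_s,
         start_time = meta$start_time, station_id = meta$station_id,
         modality = meta$modality),
    class = "spectrogram")
}
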