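#' Specification of a synthetic rumble call
#'
#' Describes the source-time function of a rumble: 3-5 s duration with a
#' fundamental that first rises then falls between 20 and 40 Hz, plus
#' harmonics (the airborne component carries several; the ground-borne one
#' effectively only the fundamental after propagation).
#'
#' @param duration call length in seconds, within `[3, 5]`.
#' @param f_start,f_peak,f_end fundamental at onset, apex and offset (Hz);
#'   the contour is piecewise linear and must stay inside `[20, 40]`.
#' @param peak_frac fraction of the duration at which the apex occurs.
#' @param n_harmonics_acoustic number of harmonics synthesized (>= 1; the
#'   fundamental counts as the first).
#' @param harmonic_decay amplitude ratio between successive harmonics.
#' @param source_amplitude peak amplitude of the fundamental at the source.
#' @return A `rumble_spec` list.
#' @export
rumble_spec <- function(duration = 4, f_start = 24, f_peak = 38, f_end = 26,
                        peak_frac = 0.4, n_harmonics_acoustic = 3,
                        harmonic_decay = 0.5, source_amplitude = 1) {
  stopifnot(duration >= 3, duration <= 5,
            f_start >= 20, f_start <= 40, f_peak >= 20, f_peak <= 40,
            f_end >= 20, f_end <= 40, f_peak >= f_start, f_peak >= f_end,
            peak_frac > 0, peak_frac < 1, n_harmonics_acoustic >= 1,
            harmonic_decay > 0, source_amplitude > 0)
  structure(list(duration = duration, f_start = f_start, f_peak = f_peak,
                 f_end = f_end, peak_frac = peak_frac,
                 n_harmonics_acoustic = n_harmonics_acoustic,
                 harmonic_decay = harmonic_decay,
                 source_amplitude = source_amplitude),
            class = "rumble_spec")
}

# fundamental frequency contour, Hz, at times tt in [0, duration]
f0_contour <- function(spec, tt) {
  tp <- spec$peak_frac * spec$duration
  ifelse(tt <= tp,
         spec$f_start + (spec$f_peak - spec$f_start) * tt / tp,
         spec$f_peak + (spec$f_end - spec$f_peak) *
           (tt - tp) / (spec$duration - tp))
}

#' Synthesize a rumble waveform at the source
#'
#' Sums `n_harmonics` phase-continuous harmonics of the rising-then-falling
#' fundamental contour (phase is the integral of the instantaneous
#' frequency), with amplitudes decaying geometrically per harmonic, and a
#' 5% raised-cosine taper at both ends.
#'
#' @param spec a [rumble_spec()].
#' @param rate sampling rate in Hz.
#' @param n_harmonics harmonics to include; defaults to the spec's acoustic
#'   count. The highest harmonic must stay below Nyquist.
#' @return A single-channel [waveform()] (modality `"acoustic"` by
#'   convention; [propagate()] sets the receiving modality).
#' @export
synthesize_call <- function(spec, rate, n_harmonics = spec$n_harmonics_acoustic) {
  stopifnot(inherits(spec, "rumble_spec"), rate > 0, n_harmonics >= 1)
  if (n_harmonics * spec$f_peak >= rate / 2)
    stop("harmonic ", n_harmonics, " of the contour apex (",
         n_harmonics * spec$f_peak, " Hz) reaches the Nyquist frequency")
  n <- round(spec$duration * rate)
  tt <- (seq_len(n) - 0.5) / rate
  phase <- 2 * pi * cumsum(f0_contour(spec, tt)) / rate
  x <- numeric(n)
  for (k in seq_len(n_harmonics))
    x <- x + spec$harmonic_decay^(k - 1) * sin(k * phase)
  # 5% raised-cosine edges
  n_tap <- max(1L, round(0.05 * n))
  ramp <- 0.5 * (1 - cos(pi * seq_len(n_tap) / n_tap))
  x[seq_len(n_tap)] <- x[seq_len(n_tap)] * ramp
  x[(n - n_tap + 1):n] <- x[(n - n_tap + 1):n] * rev(ramp)
  waveform(spec$source_amplitude * x, rate = rate, start_time = 0,
           station_id = "source", modality = "acoustic")
}

# microphone low-frequency roll-off, gain in dB at given frequencies
# (flat above 100 Hz; published response points at 20/40/50 Hz)
mic_rolloff_db <- function(freq) {
  pts_f <- c(0, 20, 40, 50, 100)
  pts_db <- c(-16, -10, -4, -2, 0)
  g <- stats::approx(pts_f, pts_db, xout = pmin(freq, 100), rule = 2)$y
  g
}

apply_gain_curve <- function(x, rate, gain_db_fn) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  g <- 10^(gain_db_fn(abs(freqs)) / 20)
  Re(stats::fft(X * g, inverse = TRUE)) / n
}

#' Propagate a source waveform to a receiver
#'
#' Single-path constant-wavespeed propagation: the signal is delayed by
#' `distance / v` (sub-sample accurate via linear interpolation), scaled by
#' geometric spreading `1 / max(distance, 1)`, and filtered according to
#' the receiving modality. The ground acts as a low-pass filter, so the
#' seismic arrival retains essentially only the fundamental (4th-order
#' zero-phase Butterworth low-pass, default cutoff 45 Hz). The acoustic
#' arrival keeps its harmonics but passes through the microphone's
#' low-frequency roll-off (-2 dB at 50 Hz, -4 dB at 40 Hz, -10 dB at
#' 20 Hz, interpolated in dB over frequency).
#'
#' @param call source [waveform()] (single channel).
#' @param distance source-receiver distance in metres.
#' @param v wavespeed in m/s (> 0).
#' @param modality `"seismic"` or `"acoustic"`.
#' @param seismic_cutoff seismic low-pass corner in Hz.
#' @param pad_to total output duration in seconds (default: delay plus the
#'   call length plus 1 s).
#' @return A [waveform()] starting at time 0 with the arrival embedded at
#'   `distance / v`.
#' @export
propagate <- function(call, distance, v, modality = c("seismic", "acoustic"),
                      seismic_cutoff = 45, pad_to = NULL) {
  modality <- match.arg(modality)
  stopifnot(inherits(call, "waveform"), distance >= 0)
  if (v <= 0) stop("wavespeed must be positive")
  rate <- call$rate
  delay <- distance / v
  x <- as.vector(call$samples) / max(distance, 1)
  if (modality == "seismic") {
    bf <- signal::butter(4, min(0.99, seismic_cutoff / (rate / 2)),
                         type = "low")
    x <- signal::filtfilt(bf, x)
  } else {
    x <- apply_gain_curve(x, rate, mic_rolloff_db)
  }
  total <- if (is.null(pad_to)) delay + length(x) / rate + 1 else pad_to
  n_out <- round(total * rate)
  t_out <- (seq_len(n_out) - 1) / rate
  # sub-sample delay by linear interpolation of the source series
  y <- stats::approx(x = delay + (seq_along(x) - 1) / rate, y = x,
                     xout = t_out, yleft = 0, yright = 0)$y
  waveform(y, rate = rate, start_time = call$start_time,
           station_id = call$station_id, modality = modality)
}

#' Default synthetic four-station geometry
#'
#' Four stations ringing a central source region with an aperture under
#' 360 m, mirroring the scale of the field deployment. The coordinates are
#' synthetic: the field geometry was never published.
#'
#' @return A station geometry data.frame (`id`, `x_m`, `y_m`, `modality`).
#' @export
synthetic_stations <- function() {
  read_stations(system.file("extdata", "stations_synthetic.csv",
                            package = "rumbleloc", mustWork = TRUE))
}

#' Generate a synthetic seismo-acoustic scene
#'
#' Builds ground-truth multi-station recordings of one rumble: the source
#' waveform is synthesized once per modality (all harmonics for acoustic,
#' which are then shaped by the microphone roll-off; the full call is also
#' propagated seismically, where the ground low-pass leaves the
#' fundamental), propagated to every station at the modality's wavespeed,
#' and buried in additive white Gaussian noise whose level is set by the
#' target amplitude signal-to-noise ratio at the nearest station
#' (`snr = Inf` gives noiseless records).
#'
#' @param stations station geometry; default [synthetic_stations()].
#' @param spec a [rumble_spec()].
#' @param source true source position (m), length 2; default: a fixed point
#'   inside the array.
#' @param v_acoustic,v_seismic propagation speeds (m/s); defaults 350 and
#'   400, the field-estimated values.
#' @param snr amplitude SNR (signal RMS over noise RMS) at the station
#'   nearest the source; the same noise s.d. is used at every station.
#' @param seed RNG seed; scenes are bit-reproducible given the seed.
#' @param seismic_rate,acoustic_rate sampling rates (Hz). Seismic matches
#'   the field instruments (200 Hz); the acoustic default of 4000 Hz keeps
#'   synthetic scenes light while staying far above the rumble band.
#' @param onset source emission time in seconds after record start.
#' @return A `synthetic_scene`: list with `stations`, `true_source`,
#'   `v_acoustic`, `v_seismic`, `snr`, `seed`, `onset`, `spec`, and
#'   `waveforms` (a list with `seismic` and `acoustic` named lists of
#'   [waveform()]s, one per station).
#' @export
generate_scene <- function(stations = synthetic_stations(),
                           spec = rumble_spec(),
                           source = NULL,
                           v_acoustic = 350, v_seismic = 400,
                           snr = Inf, seed = 1L,
                           seismic_rate = 200, acoustic_rate = 4000,
                           onset = 2) {
  stopifnot(v_acoustic > 0, v_seismic > 0)
  if (is.null(source))
    source <- c(mean(stations$x_m), mean(stations$y_m)) + c(20, -15)
  dists <- sqrt((stations$x_m - source[1])^2 + (stations$y_m - source[2])^2)
  max_delay <- max(dists) / min(v_acoustic, v_seismic)
  total <- onset + max_delay + spec$duration + 2
  set.seed(seed)
  make_records <- function(modality, rate, v) {
    # harmonics above Nyquist cannot be represented at this rate (and the
    # seismic low-pass removes them regardless)
    n_h <- max(1L, min(spec$n_harmonics_acoustic,
                       floor(0.98 * (rate / 2) / spec$f_peak)))
    call <- synthesize_call(spec, rate, n_harmonics = n_h)
    call$start_time <- onset
    recs <- lapply(seq_len(nrow(stations)), function(i) {
      w <- propagate(call, dists[i], v, modality = modality,
                     pad_to = total - onset)
      # shift onto the scene clock: records all start at t = 0
      n_pre <- round(onset * rate)
      w$samples <- matrix(c(numeric(n_pre), as.vector(w$samples)), ncol = 1)
      w$start_time <- 0
      w$station_id <- stations$id[i]
      w
    })
    names(recs) <- stations$id
    if (is.finite(snr)) {
      nearest <- which.min(dists)
      sig_rms <- sqrt(mean(as.vector(recs[[nearest]]$samples)^2))
      sd_noise <- sig_rms / snr
      recs <- lapply(recs, function(w) {
        w$samples <- w$samples + stats::rnorm(nrow(w$samples), 0, sd_noise)
        w
      })
    }
    recs
  }
  structure(
    list(stations = stations, true_source = source,
         v_acoustic = v_acoustic, v_seismic = v_seismic,
         snr = snr, seed = seed, onset = onset, spec = spec,
         waveforms = list(
           seismic = make_records("seismic", seismic_rate, v_seismic),
           acoustic = make_records("acoustic", acoustic_rate, v_acoustic))),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d stations, source (%.1f, %.1f) m, v_a=%g v_s=%g m/s, snr=%g, seed=%d\n",
              nrow(x$stations), x$true_source[1], x$true_source[2],
              x$v_acoustic, x$v_seismic, x$snr, x$seed))
  invisible(x)
}

#' Write a synthetic scene to a directory
#'
#' Seismic records go to per-station CSVs, acoustic records to WAV (plus a
#' CSV carrying the metadata WAV cannot), the geometry to `stations.csv`
#' and the ground truth to `truth.json`.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(scene$waveforms$seismic))
    write_waveform_csv(scene$waveforms$seismic[[id]],
                       file.path(dir, paste0(id, "_seismic.csv")))
  for (id in names(scene$waveforms$acoustic)) {
    w <- scene$waveforms$acoustic[[id]]
    write_wav(w, file.path(dir, paste0(id, "_acoustic.wav")))
    write_waveform_csv(w, file.path(dir, paste0(id, "_acoustic.csv")))
  }
  utils::write.csv(scene$stations, file.path(dir, "stations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(true_source = scene$true_source, v_acoustic = scene$v_acoustic,
         v_seismic = scene$v_seismic, snr = scene$snr, seed = scene$seed,
         onset = scene$onset),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
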