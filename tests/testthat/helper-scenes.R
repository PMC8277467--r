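# Shared fixtures, all built in code at test time.

test_stations <- function() {
  data.frame(id = c("ETA", "NTA", "STA", "WTA"),
             x_m = c(155, -10, 20, -150),
             y_m = c(10, 150, -145, -20),
             modality = "both", stringsAsFactors = FALSE)
}

# a random point inside the station convex hull (Dirichlet weights)
random_hull_point <- function(stations) {
  w <- stats::rexp(nrow(stations))
  w <- w / sum(w)
  c(sum(stations$x_m * w), sum(stations$y_m * w))
}

# lag-level scene: exact geometric TDOAs plus optional Gaussian noise
make_lag_scene <- function(stations, source, v, modality = "seismic",
                           reference = "ETA", sigma = 0, dt = 0.05) {
  lags <- predict_tdoas(source, stations, reference, v)
  if (sigma > 0) lags <- lags + stats::rnorm(length(lags), 0, sigma)
  tdoa_set(reference, names(lags), lags, modality = modality, dt = dt)
}

# spectrogram of a 20->40->20 Hz chirp ridge as a clean test image;
# returns the enhanced-ready magnitude spectrogram of one record
chirp_spectrogram <- function(duration = 4, rate = 200, noise_sd = 0,
                              seed = NULL, station_id = "sta") {
  if (!is.null(seed)) set.seed(seed)
  spec <- rumble_spec(duration = duration, f_start = 20, f_peak = 40,
                      f_end = 20, peak_frac = 0.5, n_harmonics_acoustic = 1)
  w <- synthesize_call(spec, rate, n_harmonics = 1)
  if (noise_sd > 0)
    w$samples <- w$samples + stats::rnorm(nrow(w$samples), 0, noise_sd)
  w$station_id <- station_id
  w$modality <- "seismic"
  compute_spectrogram(w)
}

# brute-force reference for the spectrogram correlation curve:
# plain double loop over lags and rows, cosine-normalized overlap
brute_force_correlation <- function(a, b, bins) {
  n1 <- ncol(a); n2 <- ncol(b)
  vapply(bins, function(l) {
    num <- 0; sa <- 0; sb <- 0
    for (j in seq_len(n1)) {
      k <- j + l
      if (k < 1 || k > n2) next
      for (r in seq_len(nrow(a))) {
        num <- num + a[r, j] * b[r, k]
        sa <- sa + a[r, j]^2
        sb <- sb + b[r, k]^2
      }
    }
    den <- sqrt(sa) * sqrt(sb)
    if (den == 0) 0 else num / den
  }, 0)
}

# small solver config to keep sampler-based tests quick
quick_solver <- function(...) {
  solver_config(n_samples = 1500, burn_in = 500, rng_seed = 42L, ...)
}
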