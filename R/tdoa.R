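#' Select the reference station for TDOA measurement
#'
#' The reference station is the one at which the call is most pronounced,
#' measured as the total magnitude of its (enhanced) spectrogram within the
#' event window. Ties are broken by lexicographic station id so the choice
#' is deterministic.
#'
#' @param specs named list of [compute_spectrogram()] objects, one per
#'   station; names are station ids.
#' @return The chosen station id (character scalar).
#' @export
select_reference_station <- function(specs) {
  if (length(specs) < 2) stop("need at least two stations to pick a reference")
  ids <- names(specs)
  if (is.null(ids) || any(!nzchar(ids))) stop("spectrogram list must be named")
  totals <- vapply(specs, function(s) sum(s$mag), 0)
  ord <- order(-totals, ids)
  ids[ord[1]]
}

#' Cross-correlate two spectrograms along the time axis
#'
#' Slides `other` against `ref` by whole time bins and scores each lag by
#' the cosine similarity of the overlapping sub-images (sum over all
#' frequency rows of the elementwise product, divided by the product of the
#' Frobenius norms of the two overlaps). Scores are therefore in `[0, 1]`
#' for non-negative images and invariant to amplitude scaling of either
#' spectrogram. The peak lag is refined to sub-bin resolution by parabolic
#' interpolation of the three samples around the maximum.
#'
#' Sign convention: a positive `peak_lag` means the signal arrives at
#' `other` later than at `ref`. Differences between the two windows'
#' absolute start times are folded into the reported lags, so stations need
#' not share an identical window.
#'
#' @param ref,other `spectrogram` objects with identical frequency axes and
#'   time-bin spacing.
#' @param max_lag largest |lag| searched, in seconds (default: the full
#'   overlap range). Bounding the search by the array's maximum possible
#'   travel-time difference suppresses spurious side peaks.
#' @return A `correlation_curve`: list with `lags` (s), `values`,
#'   `peak_lag` (s, refined), `peak_prominence`.
#' @export
correlate_pair <- function(ref, other, max_lag = Inf) {
  stopifnot(inherits(ref, "spectrogram"), inherits(other, "spectrogram"))
  if (length(ref$freq) != length(other$freq) ||
      max(abs(ref$freq - other$freq)) > 1e-9)
    stop("spectrograms have mismatched frequency axes")
  if (abs(ref$dt - other$dt) > 1e-12)
    stop("spectrograms have mismatched time-bin spacing")
  dt <- ref$dt
  offset <- other$time[1] - ref$time[1]
  n1 <- ncol(ref$mag); n2 <- ncol(other$mag)
  l_max <- min(n2 - 1L, floor((max_lag - offset) / dt))
  l_min <- max(-(n1 - 1L), ceiling((-max_lag - offset) / dt))
  if (l_max < l_min) stop("max_lag excludes every candidate lag")
  bins <- l_min:l_max
  vals <- vapply(bins, function(l) {
    # compare ref column j with other column j + l
    j1 <- max(1L, 1L - l); j2 <- min(n1, n2 - l)
    if (j2 < j1) return(0)
    a <- ref$mag[, j1:j2, drop = FALSE]
    b <- other$mag[, (j1 + l):(j2 + l), drop = FALSE]
    den <- sqrt(sum(a * a)) * sqrt(sum(b * b))
    if (den == 0) 0 else sum(a * b) / den
  }, 0)
  ipk <- which.max(vals)
  delta <- 0
  if (ipk > 1 && ipk < length(vals)) {
    s0 <- vals[ipk]; sm <- vals[ipk - 1]; sp <- vals[ipk + 1]
    den <- sm - 2 * s0 + sp
    if (den < 0) delta <- 0.5 * (sm - sp) / den
  }
  structure(
    list(lags = offset + bins * dt, values = vals,
         peak_lag = offset + (bins[ipk] + delta) * dt,
         peak_bin_lag = bins[ipk],
         peak_prominence = peak_prominence_at(vals, ipk)),
    class = "correlation_curve")
}

# Topographic prominence of the local maximum at index i: descend on each
# side until a strictly higher value is met (or the end of the curve); the
# peak's base is the higher of the two minima found, and the prominence is
# the height above that base.
peak_prominence_at <- function(values, i) {
  n <- length(values)
  h <- values[i]
  left_min <- h
  if (i > 1) for (j in (i - 1):1) {
    if (values[j] > h) break
    left_min <- min(left_min, values[j])
  }
  right_min <- h
  if (i < n) for (j in (i + 1):n) {
    if (values[j] > h) break
    right_min <- min(right_min, values[j])
  }
  h - max(left_min, right_min)
}

#' Peak prominence of a correlation curve
#'
#' Topographic prominence of the curve's global maximum: its height above
#' the lowest contour line that encloses it alone (for the global maximum,
#' the height above the higher of the two outer minima flanking it). Event
#' quality is gated on this prominence rather than on the raw correlation
#' value, which is sensitive to noise level.
#'
#' @param curve a `correlation_curve` from [correlate_pair()], or a plain
#'   numeric vector of correlation values.
#' @return Prominence (same units as the correlation values); 0 for a flat
#'   curve.
#' @export
peak_prominence <- function(curve) {
  values <- if (inherits(curve, "correlation_curve")) curve$values else curve
  if (length(values) == 0) stop("empty correlation curve")
  peak_prominence_at(values, which.max(values))
}

#' Prominences of all local maxima of a curve
#'
#' @param values numeric vector.
#' @return data.frame with `index`, `height`, `prominence`, one row per
#'   (strict) local maximum; the curve ends count as boundaries, not peaks.
#' @export
peak_prominences <- function(values) {
  n <- length(values)
  if (n < 3) return(data.frame(index = integer(), height = numeric(),
                               prominence = numeric()))
  is_peak <- vapply(2:(n - 1), function(i)
    values[i] > values[i - 1] && values[i] >= values[i + 1], TRUE)
  idx <- (2:(n - 1))[is_peak]
  data.frame(index = idx, height = values[idx],
             prominence = vapply(idx, function(i)
               peak_prominence_at(values, i), 0))
}

#' Build a TDOA set for one event
#'
#' Picks the reference station (strongest enhanced spectrogram), correlates
#' it against every other station, and converts peak lags from time bins to
#' seconds (window start-time offsets included). The event is accepted only
#' if every pair's correlation peak prominence reaches `min_prominence`;
#' otherwise the event is rejected with the failing pair named. This
#' reproduces the quality gate used in event selection: a low-prominence
#' correlation peak means the lag cannot be trusted, whatever the absolute
#' correlation value.
#'
#' @param specs named list of enhanced `spectrogram`s, one per station.
#' @param max_lag search bound in seconds (see [correlate_pair()]).
#' @param min_prominence minimum acceptable peak prominence (default 0.1 on
#'   the cosine-similarity scale).
#' @param reference optional station id to force as reference; default:
#'   [select_reference_station()].
#' @return A `tdoa_set`: list with `reference`, `pairs` (data.frame of
#'   `station`, `lag_s`, `prominence`), `modality`, `dt`, and the retained
#'   `curves`.
#' @export
build_tdoa_set <- function(specs, max_lag = Inf, min_prominence = 0.1,
                           reference = NULL) {
  if (length(specs) < 2) stop("need at least two stations")
  if (is.null(reference)) reference <- select_reference_station(specs)
  if (!reference %in% names(specs))
    stop("reference station '", reference, "' not among the windows")
  others <- setdiff(names(specs), reference)
  curves <- lapply(others, function(id)
    correlate_pair(specs[[reference]], specs[[id]], max_lag = max_lag))
  names(curves) <- others
  prom <- vapply(curves, `[[`, 0, "peak_prominence")
  bad <- prom < min_prominence
  if (any(bad))
    stop("event rejected: correlation prominence ", signif(min(prom[bad]), 3),
         " below ", min_prominence, " for pair ", reference, "/",
         others[which(bad)[1]])
  structure(
    list(reference = reference,
         pairs = data.frame(station = others,
                            lag_s = vapply(curves, `[[`, 0, "peak_lag"),
                            prominence = prom, row.names = NULL),
         modality = specs[[reference]]$modality,
         dt = specs[[reference]]$dt,
         curves = curves),
    class = "tdoa_set")
}

#' Construct a TDOA set directly from lags
#'
#' Useful for solver studies where arrival-time differences are produced by
#' a forward model rather than by spectrogram correlation.
#'
#' @param reference reference station id.
#' @param station ids of the non-reference stations.
#' @param lag_s arrival-time differences (station minus reference), seconds.
#' @param modality `"seismic"` or `"acoustic"`.
#' @param dt nominal lag resolution in seconds (used for default TDOA
#'   uncertainty); default 0.05.
#' @param prominence optional per-pair prominences.
#' @return A `tdoa_set`.
#' @export
tdoa_set <- function(reference, station, lag_s,
                     modality = c("seismic", "acoustic"), dt = 0.05,
                     prominence = NULL) {
  modality <- match.arg(modality)
  if (is.null(prominence) || length(prominence) == 0)
    prominence <- rep(NA_real_, length(station))
  stopifnot(length(station) == length(lag_s), all(is.finite(lag_s)),
            !reference %in% station)
  structure(
    list(reference = reference,
         pairs = data.frame(station = as.character(station),
                            lag_s = as.numeric(lag_s),
                            prominence = prominence, row.names = NULL),
         modality = modality, dt = dt, curves = NULL),
    class = "tdoa_set")
}

#' @export
print.tdoa_set <- function(x, ...) {
  cat(sprintf("<tdoa_set> [%s] reference %s, %d pairs\n",
              x$modality, x$reference, nrow(x$pairs)))
  print(x$pairs)
  invisible(x)
}

#' Write a TDOA set to JSON
#'
#' @param t a `tdoa_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tdoa_json <- function(t, path) {
  stopifnot(inherits(t, "tdoa_set"))
  jsonlite::write_json(
    list(reference = t$reference, modality = t$modality, dt = t$dt,
         pairs = t$pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TDOA set from JSON
#'
#' @param path file written by [write_tdoa_json()].
#' @return A `tdoa_set`.
#' @export
read_tdoa_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tdoa_set(x$reference, x$pairs$station, x$pairs$lag_s,
           modality = x$modality, dt = x$dt, prominence = x$pairs$prominence)
}

#' Default lag search bound from array geometry
#'
#' No physical arrival-time difference can exceed the inter-station travel
#' time, so the lag search is bounded at 1.5 times the array diameter
#' divided by the slowest plausible wavespeed.
#'
#' @param stations a station geometry (see [read_stations()]).
#' @param v_min slowest wavespeed considered, m/s (default 200).
#' @return Bound in seconds.
#' @export
default_max_lag <- function(stations, v_min = 200) {
  d <- as.matrix(stats::dist(stations[, c("x_m", "y_m")]))
  1.5 * max(d) / v_min
}
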