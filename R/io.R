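#' Read a station geometry table
#'
#' @param path CSV with columns `id`, `x_m`, `y_m` and optionally
#'   `modality` (`seismic`, `acoustic` or `both`); positions are planar
#'   coordinates in metres in a local metric frame.
#' @return A validated data.frame of class `station_geometry`.
#' @export
read_stations <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(x) == 0) stop("no stations in '", path, "'")
  need <- c("id", "x_m", "y_m")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0)
    stop("stations file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(x$x_m) || !is.numeric(x$y_m) ||
      any(!is.finite(x$x_m)) || any(!is.finite(x$y_m)))
    stop("station coordinates must be finite numbers")
  if (anyDuplicated(x$id))
    stop("duplicate station id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  if (is.null(x$modality)) x$modality <- "both"
  x$id <- as.character(x$id)
  class(x) <- c("station_geometry", "data.frame")
  x
}

#' Read an event catalogue
#'
#' Candidate event windows are supplied by the user (detection is manual):
#' a CSV with `event_id`, `start_s`, `end_s` giving each candidate window
#' on the common (GPS-synchronized) scene clock, in seconds.
#'
#' @param path CSV path.
#' @return data.frame with one row per candidate event.
#' @export
read_catalogue <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("event_id", "start_s", "end_s")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0)
    stop("catalogue is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(x$end_s <= x$start_s)) stop("catalogue windows must have end > start")
  x
}

default_config <- function() {
  list(
    seed = 1L,
    signal = list(window_length_s = 0.5, overlap = 0.9, f_max_hz = 100,
                  analysis_rate_hz = 400,
                  enhancement = list(gradient_scale = 1, integration_scale = 3,
                                     exponent = 1, floor = 0.05)),
    tdoa = list(min_prominence = 0.1, v_min = 200),
    locate = list(methods = c("det", "prob"), modalities = c("seismic", "acoustic"),
                  joint = TRUE, tdoa_sigma = NULL, prior_pad = 200,
                  n_samples = 4000, burn_in = 1000))
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("unknown configuration key: '", full, "'")
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration key '", full, "' must be a mapping")
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Read a pipeline configuration
#'
#' YAML file overriding any subset of the defaults (STFT settings,
#' enhancement parameters, prominence gate, solver settings, seed).
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML path, or `NULL` for the defaults.
#' @return A `run_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                  paste0(...)))
}

load_scene_waveforms <- function(dir, stations, modality) {
  recs <- list()
  for (id in stations$id) {
    csv <- file.path(dir, paste0(id, "_", modality, ".csv"))
    wav <- file.path(dir, paste0(id, "_", modality, ".wav"))
    if (file.exists(csv)) recs[[id]] <- read_waveform_csv(csv)
    else if (file.exists(wav))
      recs[[id]] <- read_wav(wav, station_id = id, modality = modality)
  }
  recs
}

event_spectrograms <- function(recs, start_s, end_s, cfg) {
  sp <- cfg$signal
  ep <- enhancement_params(sp$enhancement$gradient_scale,
                           sp$enhancement$integration_scale,
                           sp$enhancement$exponent, sp$enhancement$floor)
  out <- lapply(recs, function(w) {
    if (w$modality == "acoustic" && w$rate > sp$analysis_rate_hz)
      w <- decimate_waveform(w, sp$analysis_rate_hz)
    if (n_channels(w) > 1) w <- stack_channels(w)
    w <- window_waveform(w, start_s, end_s)
    s <- compute_spectrogram(w, sp$window_length_s, sp$overlap, sp$f_max_hz)
    enhance_spectrogram(s, ep)
  })
  names(out) <- names(recs)
  out
}

rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[, cols]
  }))
}

#' Run the full localization pipeline on a scene directory
#'
#' For every catalogue event: load the waveforms, stack acoustic channels,
#' decimate the acoustic records to the analysis rate, compute and enhance
#' spectrograms, measure TDOAs with the prominence gate, and localize with
#' the requested methods (deterministic and/or probabilistic per modality,
#' plus the joint bimodal posterior). An event failing any stage (for
#' example the prominence gate) is logged and skipped; it does not abort
#' the run.
#'
#' @param scene_dir directory holding `stations.csv`, per-station waveform
#'   files (`<id>_seismic.csv`, `<id>_acoustic.wav` or `.csv`) and
#'   `catalogue.csv` (or pass `catalogue`).
#' @param config a `run_config` from [read_config()].
#' @param catalogue optional catalogue data.frame overriding
#'   `catalogue.csv`.
#' @param out_dir where to write `estimates.csv` and per-event TDOA JSON;
#'   `NULL` writes nothing.
#' @return List with `estimates` (data.frame: one row per event, method and
#'   modality) and `rejected` (data.frame of skipped events with reasons).
#' @export
run_pipeline <- function(scene_dir, config = read_config(), catalogue = NULL,
                         out_dir = NULL) {
  stations <- read_stations(file.path(scene_dir, "stations.csv"))
  if (is.null(catalogue))
    catalogue <- read_catalogue(file.path(scene_dir, "catalogue.csv"))
  lcfg <- config$locate
  solver <- solver_config(
    tdoa_sigma = lcfg$tdoa_sigma, prior_pad = lcfg$prior_pad,
    n_samples = lcfg$n_samples, burn_in = lcfg$burn_in,
    rng_seed = config$seed)
  max_lag <- default_max_lag(stations, config$tdoa$v_min)
  recs <- list(seismic = load_scene_waveforms(scene_dir, stations, "seismic"),
               acoustic = load_scene_waveforms(scene_dir, stations, "acoustic"))
  estimates <- list(); rejected <- list()
  for (ev in seq_len(nrow(catalogue))) {
    eid <- catalogue$event_id[ev]
    rows <- list()
    tsets <- list()
    ok <- TRUE
    for (mod in lcfg$modalities) {
      if (length(recs[[mod]]) < nrow(stations)) {
        log_msg("INFO", "event ", eid, ": missing ", mod, " records; skipped")
        rejected[[length(rejected) + 1]] <-
          data.frame(event_id = eid, reason = paste0("missing ", mod, " data"))
        ok <- FALSE
        break
      }
      res <- try({
        specs <- event_spectrograms(recs[[mod]], catalogue$start_s[ev],
                                    catalogue$end_s[ev], config)
        tset <- build_tdoa_set(specs, max_lag = max_lag,
                               min_prominence = config$tdoa$min_prominence)
        tsets[[mod]] <- tset
        for (pi in seq_len(nrow(tset$pairs)))
          log_msg("DEBUG", "event ", eid, " [", mod, "] ", tset$reference,
                  "/", tset$pairs$station[pi],
                  sprintf(": lag %.4f s, prominence %.3f",
                          tset$pairs$lag_s[pi], tset$pairs$prominence[pi]))
        if ("det" %in% lcfg$methods) {
          det <- localize_deterministic(tset, stations, solver)
          rows[[length(rows) + 1]] <- cbind(event_id = eid,
                                            best_estimate(det))
        }
        if ("prob" %in% lcfg$methods) {
          ps <- localize_probabilistic(tset, stations, solver)
          rows[[length(rows) + 1]] <- cbind(event_id = eid,
                                            best_estimate(ps, tset, stations))
        }
        if (!is.null(out_dir)) {
          dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
          write_tdoa_json(tset, file.path(out_dir,
                                          paste0("tdoa_", eid, "_", mod, ".json")))
        }
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        log_msg("INFO", "event ", eid, " [", mod, "] rejected: ",
                conditionMessage(attr(res, "condition")))
        rejected[[length(rejected) + 1]] <- data.frame(
          event_id = eid,
          reason = conditionMessage(attr(res, "condition")))
        ok <- FALSE
        break
      }
    }
    if (ok && isTRUE(lcfg$joint) && "prob" %in% lcfg$methods &&
        !is.null(tsets$seismic) && !is.null(tsets$acoustic)) {
      ps <- localize_joint(tsets$seismic, tsets$acoustic, stations, solver)
      rows[[length(rows) + 1]] <- cbind(
        event_id = eid,
        best_estimate(ps, list(seismic = tsets$seismic,
                               acoustic = tsets$acoustic), stations))
    }
    if (ok && length(rows) > 0) {
      estimates[[length(estimates) + 1]] <- rbind_fill(rows)
      log_msg("INFO", "event ", eid, ": ", length(rows), " estimate(s)")
    }
  }
  estimates <- if (length(estimates)) rbind_fill(estimates) else
    data.frame(event_id = character(), method = character(),
               modality = character(), x_m = numeric(), y_m = numeric(),
               v = numeric(), residual = numeric())
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(event_id = character(), reason = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
  }
  list(estimates = estimates, rejected = rejected)
}
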