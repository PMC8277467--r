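#' Read a per-event residual table
#'
#' Expects a CSV with one row per localized event and the five residual
#' columns `det_acoustic`, `det_seismic`, `prob_acoustic`, `prob_seismic`,
#' `prob_joint` (metres), plus optional metadata columns such as `event`,
#' `day`, `time`.
#'
#' @param path CSV path.
#' @return A data.frame of class `residual_table`.
#' @export
read_residual_table <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_residual_table(x)
}

residual_cols <- c("det_acoustic", "det_seismic", "prob_acoustic",
                   "prob_seismic", "prob_joint")

#' Validate a residual table
#'
#' @param x data.frame containing the five residual columns.
#' @return `x` with class `residual_table`.
#' @export
as_residual_table <- function(x) {
  missing_cols <- setdiff(residual_cols, names(x))
  if (length(missing_cols) > 0)
    stop("residual table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cc in residual_cols) {
    if (!is.numeric(x[[cc]]) || any(x[[cc]] < 0, na.rm = TRUE))
      stop("column '", cc, "' must be non-negative numeric residuals")
  }
  class(x) <- c("residual_table", "data.frame")
  x
}

#' Per-event localization residuals from the original field deployment
#'
#' The nine elephant rumbles localized from the 2019 Kenyan four-station
#' seismo-acoustic deployment, with the minimum residual (m) reached by
#' each method/modality combination, as published. Bundled so that the
#' comparative summary statistics can be recomputed exactly.
#'
#' @return A `residual_table` with nine rows.
#' @export
field_residual_table <- function() {
  read_residual_table(system.file("extdata", "field_event_residuals.csv",
                                  package = "rumbleloc", mustWork = TRUE))
}

#' Comparative summary of a residual table
#'
#' Computes, per method/modality column, the sample mean and standard
#' deviation (n-1 denominator); the Pearson correlations between the
#' deterministic and probabilistic residuals within each modality and
#' between the joint and each unimodal probabilistic column; and the
#' number of events where the seismic residual beats the acoustic one in
#' both frameworks simultaneously.
#'
#' @param table a `residual_table` with at least 2 rows.
#' @return A `residual_summary` list: `n_events`, `mean`, `sd` (named by
#'   column), `pearson` (named vector with entries
#'   `det_acoustic~prob_acoustic`, `det_seismic~prob_seismic`,
#'   `prob_joint~prob_seismic`, `prob_joint~prob_acoustic`),
#'   `seismic_win_count`.
#' @export
summarize_residuals <- function(table) {
  table <- as_residual_table(table)
  if (nrow(table) < 2) stop("need at least 2 events to summarize")
  m <- as.matrix(table[, residual_cols])
  pearson <- c(
    "det_acoustic~prob_acoustic" = stats::cor(m[, "det_acoustic"],
                                              m[, "prob_acoustic"]),
    "det_seismic~prob_seismic"   = stats::cor(m[, "det_seismic"],
                                              m[, "prob_seismic"]),
    "prob_joint~prob_seismic"    = stats::cor(m[, "prob_joint"],
                                              m[, "prob_seismic"]),
    "prob_joint~prob_acoustic"   = stats::cor(m[, "prob_joint"],
                                              m[, "prob_acoustic"]))
  structure(
    list(n_events = nrow(table),
         mean = colMeans(m),
         sd = apply(m, 2, stats::sd),
         pearson = pearson,
         seismic_win_count = sum(m[, "det_seismic"] < m[, "det_acoustic"] &
                                   m[, "prob_seismic"] < m[, "prob_acoustic"])),
    class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat(sprintf("<residual_summary> %d events\n", x$n_events))
  tab <- rbind(mean = round(x$mean, 2), sd = round(x$sd, 2))
  print(tab)
  cat("Pearson correlations:\n")
  print(round(x$pearson, 4))
  cat(sprintf("events with seismic < acoustic in both frameworks: %d/%d\n",
              x$seismic_win_count, x$n_events))
  invisible(x)
}

#' Write a residual summary as JSON and a plain-text table
#'
#' @param x a `residual_summary`.
#' @param path_json,path_txt output paths; either may be `NULL` to skip.
#' @return `x`, invisibly.
#' @export
write_residual_summary <- function(x, path_json = NULL, path_txt = NULL) {
  stopifnot(inherits(x, "residual_summary"))
  if (!is.null(path_json))
    jsonlite::write_json(unclass(x), path_json, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w")
    on.exit(close(con))
    sink(con); print(x); sink()
  }
  invisible(x)
}

#' Worst-case interaural time difference
#'
#' The arrival-time difference between two receivers a distance `separation`
#' apart (an elephant's two ears, about 1 m) for a wave of speed `v`
#' arriving along the line joining them: `separation / v`. This is the
#' azimuth cue magnitude an animal could exploit for either the acoustic or
#' the seismic component of a rumble.
#'
#' @param separation receiver separation in metres (> 0).
#' @param v wavespeed in m/s (> 0).
#' @return Delay in seconds.
#' @export
interaural_delay <- function(separation, v) {
  stopifnot(separation >= 0, v > 0)
  separation / v
}
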