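#' Solver configuration for localization
#'
#' @param wavespeed_grid named list of wavespeed grids (m/s) for the
#'   deterministic sweep. Defaults: acoustic 320-380 m/s in steps of 5
#'   (near-surface air, around the 350 m/s estimate), seismic 200-1500 m/s
#'   in steps of 25 (near-surface ground speeds vary widely).
#' @param tdoa_sigma Gaussian TDOA measurement uncertainty in seconds.
#'   `NULL` (default) uses one spectrogram time bin of the TDOA set at
#'   hand: lag quantization is the dominant known error.
#' @param position_prior bounding box `list(x = c(lo, hi), y = c(lo, hi))`
#'   in metres; `NULL` pads the station bounding box by `prior_pad` m.
#' @param prior_pad padding (m) used when `position_prior` is `NULL`.
#' @param wavespeed_prior named list of `(low, high)` m/s per modality for
#'   the Bayesian solver.
#' @param n_samples posterior samples kept after burn-in (default 4000).
#' @param burn_in discarded initial samples (default 1000).
#' @param n_starts_side multi-start grid is `n_starts_side^2` points over
#'   the position prior box (default 3, i.e. 9 starts).
#' @param rng_seed seed for the sampler.
#' @return A `solver_config` list.
#' @export
solver_config <- function(wavespeed_grid = list(acoustic = seq(320, 380, by = 5),
                                                seismic = seq(200, 1500, by = 25)),
                          tdoa_sigma = NULL,
                          position_prior = NULL,
                          prior_pad = 200,
                          wavespeed_prior = list(acoustic = c(300, 400),
                                                 seismic = c(150, 1600)),
                          n_samples = 4000,
                          burn_in = 1000,
                          n_starts_side = 3,
                          rng_seed = 1L) {
  stopifnot(length(wavespeed_grid) > 0, all(lengths(wavespeed_grid) > 0),
            n_samples > 0, burn_in >= 0, n_starts_side >= 1)
  structure(list(wavespeed_grid = wavespeed_grid, tdoa_sigma = tdoa_sigma,
                 position_prior = position_prior, prior_pad = prior_pad,
                 wavespeed_prior = wavespeed_prior, n_samples = n_samples,
                 burn_in = burn_in, n_starts_side = n_starts_side,
                 rng_seed = rng_seed),
            class = "solver_config")
}

station_pos <- function(stations, ids) {
  i <- match(ids, stations$id)
  if (anyNA(i)) stop("unknown station id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  cbind(stations$x_m[i], stations$y_m[i])
}

prior_box <- function(stations, cfg) {
  if (!is.null(cfg$position_prior)) return(cfg$position_prior)
  list(x = range(stations$x_m) + c(-1, 1) * cfg$prior_pad,
       y = range(stations$y_m) + c(-1, 1) * cfg$prior_pad)
}

#' Predict arrival-time differences from a candidate source
#'
#' For a source at planar position `x` and a constant wavespeed `v`, the
#' arrival-time difference between station `i` and the reference station is
#' `(||x - p_i|| - ||x - p_0||) / v`. All stations are treated as lying in
#' one horizontal plane.
#'
#' @param x numeric length-2 position (easting, northing) in metres.
#' @param stations station geometry data.frame (`id`, `x_m`, `y_m`).
#' @param reference reference station id.
#' @param v wavespeed in m/s (> 0).
#' @param targets ids of the non-reference stations; default: all others,
#'   in table order.
#' @return Named numeric vector of lags in seconds.
#' @export
predict_tdoas <- function(x, stations, reference, v,
                          targets = setdiff(stations$id, reference)) {
  stopifnot(v > 0, length(x) == 2)
  if (!reference %in% stations$id)
    stop("reference station '", reference, "' not in the geometry")
  p0 <- station_pos(stations, reference)
  pi_ <- station_pos(stations, targets)
  d0 <- sqrt(sum((x - p0)^2))
  di <- sqrt((x[1] - pi_[, 1])^2 + (x[2] - pi_[, 2])^2)
  stats::setNames((di - d0) / v, targets)
}

#' Localization residual in metres
#'
#' The mean absolute mismatch between the measured arrival-time differences
#' and the ones predicted from a candidate position and wavespeed,
#' expressed as a distance via the wavespeed estimate:
#' `v * mean(|observed - predicted|)`. Zero when the candidate explains the
#' measurements exactly; used as the accuracy proxy for every localization
#' method.
#'
#' @param x candidate position (m), length 2.
#' @param v wavespeed (m/s).
#' @param t a `tdoa_set`.
#' @param stations station geometry.
#' @return Residual in metres (>= 0).
#' @export
compute_residual <- function(x, v, t, stations) {
  stopifnot(inherits(t, "tdoa_set"), v > 0)
  pred <- predict_tdoas(x, stations, t$reference, v,
                        targets = t$pairs$station)
  v * mean(abs(t$pairs$lag_s - pred))
}

# residual pooling both modalities: each pair's time mismatch is converted
# to metres with its own modality's wavespeed, then averaged over all pairs
compute_residual_joint <- function(x, v_seis, v_acou, t_seis, t_acou,
                                   stations) {
  ps <- predict_tdoas(x, stations, t_seis$reference, v_seis,
                      targets = t_seis$pairs$station)
  pa <- predict_tdoas(x, stations, t_acou$reference, v_acou,
                      targets = t_acou$pairs$station)
  mean(c(v_seis * abs(t_seis$pairs$lag_s - ps),
         v_acou * abs(t_acou$pairs$lag_s - pa)))
}

multi_starts <- function(box, k) {
  qs <- seq(0, 1, length.out = k + 2)[2:(k + 1)]
  as.matrix(expand.grid(x = box$x[1] + qs * diff(box$x),
                        y = box$y[1] + qs * diff(box$y)))
}

# least-squares position fit at fixed wavespeed, multi-start Levenberg-
# Marquardt; returns list(x, objective, converged)
fit_position <- function(obs, targets, reference, stations, v, box, k_side) {
  resid_fn <- function(par) {
    obs - predict_tdoas(par, stations, reference, v, targets = targets)
  }
  best <- NULL
  for (s in seq_len(nrow(starts <- multi_starts(box, k_side)))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[s, ], fn = resid_fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                           maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$objective)
      best <- list(x = unname(fit$par), objective = obj,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best)) list(x = c(NA_real_, NA_real_), objective = NA_real_,
                          converged = FALSE)
  else best
}

#' Deterministic wavespeed-grid localization
#'
#' For each wavespeed in the grid for the set's modality, finds the planar
#' position minimizing the sum of squared differences between measured and
#' predicted arrival-time differences (multi-start Levenberg-Marquardt
#' least squares; hyperbola intersections are non-convex, so several
#' starting points over the prior box are tried and the best objective
#' wins). One candidate is returned per grid wavespeed, scored by
#' [compute_residual()]; non-converged grid points are kept but flagged.
#'
#' @param t a `tdoa_set` with at least 3 pairs (4 stations).
#' @param stations station geometry.
#' @param cfg a [solver_config()].
#' @return A data.frame of class `location_estimates` with one row per grid
#'   wavespeed: `method`, `modality`, `v`, `x_m`, `y_m`, `residual`,
#'   `objective`, `converged`, in grid order.
#' @export
localize_deterministic <- function(t, stations, cfg = solver_config()) {
  stopifnot(inherits(t, "tdoa_set"))
  if (nrow(t$pairs) < 3)
    stop("need at least 3 station pairs (4 stations) for a unique position")
  grid <- cfg$wavespeed_grid[[t$modality]]
  if (is.null(grid)) stop("no wavespeed grid for modality '", t$modality, "'")
  box <- prior_box(stations, cfg)
  rows <- lapply(grid, function(v) {
    fit <- fit_position(t$pairs$lag_s, t$pairs$station, t$reference,
                        stations, v, box, cfg$n_starts_side)
    res <- if (anyNA(fit$x)) NA_real_ else
      compute_residual(fit$x, v, t, stations)
    data.frame(method = "det", modality = t$modality, v = v,
               x_m = fit$x[1], y_m = fit$x[2], residual = res,
               objective = fit$objective, converged = fit$converged)
  })
  structure(do.call(rbind, rows), class = c("location_estimates",
                                            "data.frame"))
}

# ---- Bayesian solvers -------------------------------------------------------

# log posterior factory; theta = (x, y, v) or (x, y, v_seis, v_acou)
make_log_post <- function(sets, stations, box, v_priors, sigmas) {
  function(theta) {
    x <- theta[1:2]
    vs <- theta[-(1:2)]
    if (x[1] < box$x[1] || x[1] > box$x[2] ||
        x[2] < box$y[1] || x[2] > box$y[2]) return(-Inf)
    lp <- 0
    for (m in seq_along(sets)) {
      v <- vs[m]
      if (v < v_priors[[m]][1] || v > v_priors[[m]][2]) return(-Inf)
      t <- sets[[m]]
      pred <- predict_tdoas(x, stations, t$reference, v,
                            targets = t$pairs$station)
      lp <- lp + sum(stats::dnorm(t$pairs$lag_s, pred, sigmas[m], log = TRUE))
    }
    lp
  }
}

# MAP by multi-start box-constrained quasi-Newton, then a random-walk
# Metropolis chain with Laplace-scaled proposals
sample_posterior <- function(sets, stations, cfg, method_tag, modality_tag) {
  box <- prior_box(stations, cfg)
  mods <- vapply(sets, `[[`, "", "modality")
  v_priors <- cfg$wavespeed_prior[mods]
  sigmas <- vapply(seq_along(sets), function(m) {
    if (!is.null(cfg$tdoa_sigma)) cfg$tdoa_sigma else sets[[m]]$dt
  }, 0)
  log_post <- make_log_post(sets, stations, box, v_priors, sigmas)
  d <- 2 + length(sets)
  lower <- c(box$x[1], box$y[1], vapply(v_priors, `[`, 0, 1))
  upper <- c(box$x[2], box$y[2], vapply(v_priors, `[`, 0, 2))

  # MAP search: with flat priors the posterior mode is the weighted
  # least-squares optimum over (x, v...), which Levenberg-Marquardt finds
  # far more reliably than a generic optimizer on a razor-sharp likelihood
  wres_fn <- function(theta) {
    x <- theta[1:2]
    unlist(lapply(seq_along(sets), function(m) {
      t <- sets[[m]]
      pred <- predict_tdoas(x, stations, t$reference,
                            max(theta[2 + m], 1e-6),
                            targets = t$pairs$station)
      (t$pairs$lag_s - pred) / sigmas[m]
    }))
  }
  # the objective has a long shallow valley in (x, v) dotted with local
  # minima, so the search profiles over wavespeed first: for each grid
  # wavespeed the position is fit alone (a well-behaved 2-parameter
  # problem), then the full parameter vector is polished from there.
  # candidates are ranked by the weighted least-squares objective rather
  # than the log posterior: inside the flat-prior box the orderings are
  # identical, but the objective still separates fits whose likelihoods
  # agree to within double-precision rounding
  vq <- if (length(sets) == 1) seq(0.02, 0.98, length.out = 25)
        else seq(0.1, 0.9, length.out = 7)
  v_starts <- lapply(v_priors, function(p) p[1] + vq * diff(p))
  v_grid <- as.matrix(do.call(expand.grid, v_starts))
  map <- NULL; map_obj <- Inf
  for (j in seq_len(nrow(v_grid))) {
    vs <- v_grid[j, ]
    pos_res <- function(par) wres_fn(c(par, vs))
    pos <- NULL; pos_obj <- Inf
    for (i in seq_len(nrow(starts <- multi_starts(box, cfg$n_starts_side)))) {
      pf <- try(minpack.lm::nls.lm(
        par = starts[i, ], fn = pos_res,
        control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                             maxiter = 200)), silent = TRUE)
      if (inherits(pf, "try-error")) next
      o <- sum(pf$fvec^2)
      if (o < pos_obj) { pos <- unname(pf$par); pos_obj <- o }
    }
    if (is.null(pos)) next
    fit <- try(minpack.lm::nls.lm(
      par = c(pos, vs), fn = wres_fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                           maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    th <- pmin(pmax(unname(fit$par), lower + 1e-9), upper - 1e-9)
    obj <- sum(wres_fn(th)^2)
    if (is.finite(log_post(th)) && obj < map_obj) { map <- th; map_obj <- obj }
  }
  if (is.null(map))
    stop("posterior has no support inside the prior box; ",
         "widen position_prior or wavespeed_prior")

  # proposal scales from the local curvature (Laplace approximation);
  # fall back to prior-scale steps where the likelihood is flat
  fallback <- (upper - lower) / 10
  H <- try(stats::optimHess(map, function(th) -log_post(th)), silent = TRUE)
  step <- fallback
  if (!inherits(H, "try-error")) {
    hd <- diag(as.matrix(H))
    ok <- is.finite(hd) & hd > 0
    step[ok] <- pmin(2.4 / sqrt(d) / sqrt(hd[ok]), fallback[ok])
  }

  # seed the chain reproducibly without clobbering the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$rng_seed)
  n_tot <- cfg$burn_in + cfg$n_samples
  chain <- matrix(NA_real_, n_tot, d)
  ld <- numeric(n_tot)
  cur <- map; cur_lp <- log_post(cur)
  for (i in seq_len(n_tot)) {
    prop <- cur + stats::rnorm(d, 0, step)
    prop_lp <- log_post(prop)
    if (is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp) {
      cur <- prop; cur_lp <- prop_lp
    }
    chain[i, ] <- cur; ld[i] <- cur_lp
  }
  keep <- (cfg$burn_in + 1):n_tot
  # the MAP point is retained as an explicit sample so downstream
  # best-residual selection always sees the posterior mode
  samples <- rbind(map, chain[keep, , drop = FALSE])
  ld <- c(log_post(map), ld[keep])
  cn <- if (length(sets) == 1) c("x_m", "y_m", "v")
        else c("x_m", "y_m", paste0("v_", mods))
  colnames(samples) <- cn
  structure(
    list(samples = as.data.frame(samples), log_density = ld,
         map = stats::setNames(map, cn), method = method_tag,
         modality = modality_tag, rng_seed = cfg$rng_seed,
         tdoa_sigma = stats::setNames(sigmas, mods)),
    class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> [%s/%s] %d samples, seed %d\n",
              x$method, x$modality, nrow(x$samples), x$rng_seed))
  print(utils::head(x$samples, 3))
  invisible(x)
}

#' Bayesian localization from one TDOA set
#'
#' Samples the posterior over source position and wavespeed,
#' `p(x, v | lags) ~ prior(x) prior(v) prod_i N(lag_i | pred_i(x, v),
#' sigma^2)`, with uniform priors over the position box and the wavespeed
#' interval, using a random-walk Metropolis chain started at the
#' maximum-a-posteriori point (found by multi-start quasi-Newton) with
#' Laplace-scaled proposals. Reproducible given `cfg$rng_seed`; the MAP
#' point is included in the returned samples.
#'
#' @param t a `tdoa_set` (>= 3 pairs).
#' @param stations station geometry.
#' @param cfg a [solver_config()].
#' @return A `posterior_samples` object: `samples` (data.frame `x_m`,
#'   `y_m`, `v`), `log_density`, `map`, `rng_seed`.
#' @export
localize_probabilistic <- function(t, stations, cfg = solver_config()) {
  stopifnot(inherits(t, "tdoa_set"))
  if (nrow(t$pairs) < 3)
    stop("need at least 3 station pairs (4 stations) for a unique position")
  sample_posterior(list(t), stations, cfg, "prob", t$modality)
}

#' Joint bimodal Bayesian localization
#'
#' A single posterior over one shared source position with independent
#' seismic and acoustic wavespeeds; the likelihood is the product of the
#' two modalities' Gaussian TDOA terms. Both TDOA sets must describe the
#' same event.
#'
#' @param t_seis,t_acou seismic and acoustic `tdoa_set`s.
#' @param stations station geometry.
#' @param cfg a [solver_config()].
#' @return A `posterior_samples` object with columns `x_m`, `y_m`,
#'   `v_seismic`, `v_acoustic`.
#' @export
localize_joint <- function(t_seis, t_acou, stations, cfg = solver_config()) {
  stopifnot(inherits(t_seis, "tdoa_set"), inherits(t_acou, "tdoa_set"))
  if (t_seis$modality != "seismic" || t_acou$modality != "acoustic")
    stop("localize_joint expects one seismic and one acoustic tdoa_set")
  if (nrow(t_seis$pairs) < 3 || nrow(t_acou$pairs) < 3)
    stop("need at least 3 station pairs per modality")
  sample_posterior(list(t_seis, t_acou), stations, cfg, "prob", "both")
}

#' Residuals for every posterior sample
#'
#' @param ps a `posterior_samples` object.
#' @param t a `tdoa_set` (unimodal) or `list(seismic =, acoustic =)` for
#'   joint posteriors.
#' @param stations station geometry.
#' @return Numeric vector of residuals (m), one per sample.
#' @export
sample_residuals <- function(ps, t, stations) {
  stopifnot(inherits(ps, "posterior_samples"))
  s <- ps$samples
  if (ps$modality == "both") {
    vapply(seq_len(nrow(s)), function(i)
      compute_residual_joint(c(s$x_m[i], s$y_m[i]), s$v_seismic[i],
                             s$v_acoustic[i], t$seismic, t$acoustic,
                             stations), 0)
  } else {
    vapply(seq_len(nrow(s)), function(i)
      compute_residual(c(s$x_m[i], s$y_m[i]), s$v[i], t, stations), 0)
  }
}

#' Best location estimate by smallest residual
#'
#' Selects, over all candidates proposed by a localization method (grid
#' points of the deterministic sweep, or posterior samples), the one with
#' the smallest residual; ties go to the first occurrence.
#'
#' @param candidates a `location_estimates` data.frame
#'   ([localize_deterministic()]) or a `posterior_samples` object (in which
#'   case `t` and `stations` are required to score the samples).
#' @param t,stations needed to score posterior samples; `t` is a
#'   `tdoa_set`, or `list(seismic =, acoustic =)` for joint posteriors.
#' @return One-row data.frame: `method`, `modality`, `x_m`, `y_m`,
#'   wavespeed column(s) and `residual`.
#' @export
best_estimate <- function(candidates, t = NULL, stations = NULL) {
  if (inherits(candidates, "posterior_samples")) {
    if (is.null(t) || is.null(stations))
      stop("scoring posterior samples requires `t` and `stations`")
    res <- sample_residuals(candidates, t, stations)
    i <- which.min(res)
    out <- cbind(data.frame(method = candidates$method,
                            modality = candidates$modality),
                 candidates$samples[i, , drop = FALSE],
                 data.frame(residual = res[i]))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0) stop("no candidates to choose from")
  ok <- which(is.finite(candidates$residual))
  if (length(ok) == 0) stop("no candidate has a finite residual")
  i <- ok[which.min(candidates$residual[ok])]
  out <- candidates[i, c("method", "modality", "x_m", "y_m", "v", "residual")]
  rownames(out) <- NULL
  out
}
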