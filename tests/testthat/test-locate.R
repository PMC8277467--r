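test_that("predicted TDOAs follow hyperbola geometry", {
  st <- test_stations()
  # equidistant from ETA and NTA: lag for NTA is zero
  mid <- (c(155, 10) + c(-10, 150)) / 2
  lag <- predict_tdoas(mid, st, "ETA", 400)
  expect_equal(unname(lag["NTA"]), 0, tolerance = 1e-12)

  st2 <- data.frame(id = c("A", "B"), x_m = c(0, 100), y_m = c(0, 0))
  expect_equal(unname(predict_tdoas(c(100, 0), st2, "A", 400)), -0.25)
})

test_that("interaural geometry gives the published worst-case delays", {
  ears <- data.frame(id = c("L", "R"), x_m = c(0, 1), y_m = c(0, 0))
  src <- c(-50, 0)    # end-on incidence beyond the left ear
  expect_equal(abs(unname(predict_tdoas(src, ears, "L", 350))),
               2.86e-3, tolerance = 0.005)
  expect_equal(abs(unname(predict_tdoas(src, ears, "L", 400))),
               2.50e-3, tolerance = 0.005)
  expect_equal(signif(interaural_delay(1, 350), 3), 2.86e-3)
  expect_equal(interaural_delay(1, 400), 2.50e-3)
  expect_equal(interaural_delay(0, 350), 0)
})

test_that("the residual metric is mean absolute mismatch in metres", {
  st <- test_stations()
  src <- c(40, -20)
  lags <- predict_tdoas(src, st, "ETA", 400)
  ts <- tdoa_set("ETA", names(lags), lags, "seismic")
  expect_equal(compute_residual(src, 400, ts, st), 0, tolerance = 1e-12)

  off <- lags + c(0.01, 0, 0)
  t2 <- tdoa_set("ETA", names(off), off, "seismic")
  expect_equal(compute_residual(src, 400, t2, st), 0.01 * 400 / 3,
               tolerance = 1e-12)
})

test_that("the deterministic sweep inverts a noiseless forward model", {
  st <- test_stations()
  src <- c(55, -35)
  ts <- make_lag_scene(st, src, v = 400, modality = "seismic")
  est <- localize_deterministic(ts, st, solver_config())
  expect_equal(nrow(est), length(solver_config()$wavespeed_grid$seismic))
  best <- best_estimate(est)
  expect_equal(best$v, 400)
  expect_lt(sqrt(sum((c(best$x_m, best$y_m) - src)^2)), 0.5)
  expect_lt(best$residual, 0.01)

  expect_error(localize_deterministic(
    tdoa_set("A", c("B", "C"), c(0.1, 0.2), "seismic"),
    data.frame(id = c("A", "B", "C"), x_m = c(0, 100, 0),
               y_m = c(0, 0, 100))), "at least 3")
})

test_that("zero lags on a symmetric square array give the centroid", {
  sq <- data.frame(id = c("A", "B", "C", "D"),
                   x_m = c(-100, 100, 100, -100),
                   y_m = c(-100, -100, 100, 100))
  ts <- tdoa_set("A", c("B", "C", "D"), c(0, 0, 0), "seismic")
  best <- best_estimate(localize_deterministic(ts, sq, solver_config()))
  expect_lt(sqrt(best$x_m^2 + best$y_m^2), 1e-3)
})

test_that("one-bin lag perturbations move the estimate boundedly", {
  st <- test_stations()
  src <- c(10, 25)
  lags <- predict_tdoas(src, st, "ETA", 400)
  set.seed(17)
  for (k in 1:3) {
    pert <- lags + sample(c(-0.05, 0.05), 3, replace = TRUE)
    tp <- tdoa_set("ETA", names(pert), pert, "seismic")
    best <- best_estimate(localize_deterministic(tp, st, solver_config()))
    expect_gt(best$residual, 0)
    shift <- sqrt(sum((c(best$x_m, best$y_m) - src)^2))
    expect_lt(shift, 10 * max(best$residual, 0.05 * 400 / 3))
  }
})

test_that("the posterior concentrates on the truth as sigma shrinks", {
  st <- test_stations()
  src <- c(40, 30)
  ts <- make_lag_scene(st, src, v = 400, modality = "seismic")
  ps <- localize_probabilistic(ts, st, quick_solver(tdoa_sigma = 1e-5))
  m <- colMeans(ps$samples)
  expect_lt(sqrt((m["x_m"] - src[1])^2 + (m["y_m"] - src[2])^2), 1)
  expect_lt(sd(ps$samples$x_m), 1)
  expect_lt(sd(ps$samples$y_m), 1)
})

test_that("with an uninformative likelihood the posterior is the prior", {
  st <- test_stations()
  ts <- make_lag_scene(st, c(0, 0), v = 400, modality = "seismic")
  cfg <- solver_config(tdoa_sigma = 100, n_samples = 8000, burn_in = 1000,
                       rng_seed = 4)
  ps <- localize_probabilistic(ts, st, cfg)
  bx <- range(st$x_m) + c(-200, 200)
  by <- range(st$y_m) + c(-200, 200)
  ks_x <- suppressWarnings(ks.test(ps$samples$x_m, "punif", bx[1], bx[2]))
  ks_y <- suppressWarnings(ks.test(ps$samples$y_m, "punif", by[1], by[2]))
  expect_lt(unname(ks_x$statistic), 0.1)
  expect_lt(unname(ks_y$statistic), 0.1)
})

test_that("deterministic best and probabilistic MAP agree", {
  st <- test_stations()
  # a generic source: for some positions a ghost (x, v) pair fits the
  # three TDOAs exactly as well as the truth and the two methods may
  # legitimately pick different members of the tie (see the vignette)
  src <- c(40, 30)
  ts <- make_lag_scene(st, src, v = 400, modality = "seismic")
  det <- best_estimate(localize_deterministic(ts, st, solver_config()))
  ps <- localize_probabilistic(ts, st, quick_solver())
  expect_lt(sqrt((ps$map["x_m"] - det$x_m)^2 + (ps$map["y_m"] - det$y_m)^2),
            2)
})

test_that("the joint posterior pools both modalities", {
  st <- test_stations()
  src <- c(30, -40)
  set.seed(8)
  ts <- make_lag_scene(st, src, v = 400, modality = "seismic")
  ta <- make_lag_scene(st, src, v = 350, modality = "acoustic")
  cfg <- quick_solver(tdoa_sigma = 1e-4)
  pj <- localize_joint(ts, ta, st, cfg)
  m <- colMeans(pj$samples)
  expect_lt(sqrt((m["x_m"] - src[1])^2 + (m["y_m"] - src[2])^2), 1)
  expect_named(pj$samples, c("x_m", "y_m", "v_seismic", "v_acoustic"))

  # one modality 10x noisier: joint spread sits between the unimodal ones
  set.seed(9)
  ta_noisy <- make_lag_scene(st, src, v = 350, modality = "acoustic",
                             sigma = 0.01)
  cfg2 <- quick_solver(tdoa_sigma = 0.001)
  cfg2a <- quick_solver(tdoa_sigma = 0.01)
  sd_seis <- sd(localize_probabilistic(ts, st, cfg2)$samples$x_m)
  sd_acou <- sd(localize_probabilistic(ta_noisy, st, cfg2a)$samples$x_m)
  cfg_j <- quick_solver(tdoa_sigma = NULL)
  ts$dt <- 0.001; ta_noisy$dt <- 0.01   # per-modality sigma via dt default
  sd_joint <- sd(localize_joint(ts, ta_noisy, st, cfg_j)$samples$x_m)
  expect_lt(sd_joint, max(sd_seis, sd_acou) * 1.2)
  expect_gt(sd_joint, min(sd_seis, sd_acou) * 0.5)
})

test_that("a duplicated modality leaves the joint MAP at the unimodal MAP", {
  st <- test_stations()
  src <- c(70, 10)
  ts <- make_lag_scene(st, src, v = 400, modality = "seismic")
  ta <- ts; ta$modality <- "acoustic"
  cfg <- quick_solver(
    tdoa_sigma = 0.002,
    wavespeed_prior = list(acoustic = c(150, 1600), seismic = c(150, 1600)))
  p1 <- localize_probabilistic(ts, st, cfg)
  pj <- localize_joint(ts, ta, st, cfg)
  expect_lt(sqrt((pj$map["x_m"] - p1$map["x_m"])^2 +
                   (pj$map["y_m"] - p1$map["y_m"])^2), 1)
})

test_that("best_estimate minimizes the residual with first-occurrence ties", {
  cand <- data.frame(method = "det", modality = "seismic",
                     v = c(300, 400, 500), x_m = 1:3, y_m = 4:6,
                     residual = c(3.1, 0.4, 2.2))
  expect_equal(best_estimate(cand)$v, 400)
  cand$residual <- c(1, 1, 1)
  expect_equal(best_estimate(cand)$v, 300)
  expect_error(best_estimate(cand[0, ]), "no candidates")
})

test_that("the best posterior sample is near the deterministic optimum", {
  st <- test_stations()
  src <- c(15, -55)
  ts <- make_lag_scene(st, src, v = 400, modality = "seismic")
  det <- best_estimate(localize_deterministic(ts, st, solver_config()))
  ps <- localize_probabilistic(ts, st, quick_solver(tdoa_sigma = 1e-4))
  bp <- best_estimate(ps, ts, st)
  expect_lt(bp$residual, det$residual + 0.5)
})

test_that("estimates are equivariant under rigid motions of the frame", {
  st <- test_stations()
  src <- c(45, -10)
  ts <- make_lag_scene(st, src, v = 400, modality = "seismic")
  best <- best_estimate(localize_deterministic(ts, st, solver_config()))

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(1000, -500)
  P2 <- t(R %*% t(cbind(st$x_m, st$y_m))) +
    matrix(shift, nrow(st), 2, byrow = TRUE)
  st2 <- st; st2$x_m <- P2[, 1]; st2$y_m <- P2[, 2]
  best2 <- best_estimate(localize_deterministic(ts, st2, solver_config()))
  expected <- as.vector(R %*% src + shift)
  expect_lt(sqrt((best2$x_m - expected[1])^2 + (best2$y_m - expected[2])^2),
            1e-3)
})

test_that("scaling all lags rescales the best-fit wavespeed inversely", {
  st <- test_stations()
  src <- c(-30, 20)
  lags <- predict_tdoas(src, st, "ETA", 400)
  t2 <- tdoa_set("ETA", names(lags), 2 * lags, "seismic")
  best <- best_estimate(localize_deterministic(t2, st, solver_config()))
  expect_equal(best$v, 200, tolerance = 0.1)
})

test_that("the numerical solver matches exhaustive grid minimization", {
  st <- test_stations()
  src <- c(60, 40)
  set.seed(33)
  ts <- make_lag_scene(st, src, v = 400, modality = "seismic", sigma = 0.02)
  speeds <- seq(250, 700, length.out = 10)
  xs <- seq(-350, 350, length.out = 50)
  ys <- seq(-350, 350, length.out = 50)
  brute <- Inf
  for (v in speeds) for (x in xs) {
    for (y in ys) {
      pred <- predict_tdoas(c(x, y), st, ts$reference, v,
                            targets = ts$pairs$station)
      brute <- min(brute, sum((ts$pairs$lag_s - pred)^2))
    }
  }
  cfg <- solver_config(wavespeed_grid = list(seismic = speeds))
  est <- localize_deterministic(ts, st, cfg)
  expect_lte(min(est$objective), brute * 1.01)
})
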