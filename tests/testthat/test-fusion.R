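test_that("fusion MSE matches a hand-expanded sum and its endpoints", {
  d <- random_fusion_dataset(n = 10, seed = 3)
  # endpoints reduce to single-source MSE
  expect_equal(fusion_mse(0, d), mean(rowSums((d$V - d$D)^2)))
  expect_equal(fusion_mse(1, d), mean(rowSums((d$U - d$D)^2)))
  # exact data: zero for every h
  exact <- d
  exact$U <- exact$V <- exact$D
  class(exact) <- "fusion_dataset"
  for (h in c(0, 0.3, 1)) expect_equal(fusion_mse(h, exact), 0)

  # 1-joint, 2-frame instance expanded by hand:
  # U = (1,0,0),(0,1,0); V = (0,0,0),(0,0,0); D = (0.5,0,0),(0,0,0); h = 0.5
  # L = (0.5,0,0),(0,0.5,0); residuals: 0 and (0,0.5,0) -> mse = 0.25 / 2
  cat1 <- joint_catalog()$joint[1]
  mk <- function(m, src) keypoint_sequence(array(as.vector(m), c(2, 1, 3)),
                                           c(0, 1 / 30), cat1, source = src)
  dd <- fusion_dataset(mk(rbind(c(1, 0, 0), c(0, 1, 0)), "rgb_detector"),
                       mk(rbind(c(0, 0, 0), c(0, 0, 0)), "aligned"),
                       mk(rbind(c(0.5, 0, 0), c(0, 0, 0)), "reference"))
  expect_equal(fusion_mse(0.5, dd), 0.125)
})

test_that("closed-form weight recovers designed blends and endpoints", {
  # D constructed as the exact mid-blend
  d <- random_fusion_dataset(n = 50, seed = 9, w = 0.5, noise = 0)
  expect_equal(closed_form_weight(d), 0.5, tolerance = 1e-12)
  # one source perfect
  d1 <- random_fusion_dataset(n = 50, seed = 10, w = 1, noise = 0)
  expect_equal(closed_form_weight(d1), 1, tolerance = 1e-12)
  # degenerate U = V: constant objective, defined fallback with warning
  dg <- d
  dg$V <- dg$U
  class(dg) <- "fusion_dataset"
  expect_warning(h <- closed_form_weight(dg), "constant")
  expect_equal(h, 0.5)
})

test_that("closed-form weight agrees with a fine grid search", {
  for (seed in 1:5) {
    d <- random_fusion_dataset(n = 60, seed = seed)
    expect_lt(abs(closed_form_weight(d) - oracle_grid_weight(d)), 5e-4)
  }
})

test_that("L-BFGS weight solve agrees with the quadratic closed form", {
  for (seed in 1:10) {
    d <- random_fusion_dataset(n = 80, seed = 100 + seed)
    res <- optimize_weight(d)
    expect_lt(abs(res$h - closed_form_weight(d)), 1e-6)
    expect_gte(res$h, 0)
    expect_lte(res$h, 1)
  }
  # perfect source endpoints
  d1 <- random_fusion_dataset(n = 50, seed = 21, w = 1, noise = 0)
  expect_lt(abs(optimize_weight(d1)$h - 1), 1e-6)
  d5 <- random_fusion_dataset(n = 50, seed = 22, w = 0.5, noise = 0)
  expect_lt(abs(optimize_weight(d5)$h - 0.5), 1e-6)
})

test_that("fused MSE at the solved weight never exceeds either source", {
  for (seed in c(2, 7, 13)) {
    d <- random_fusion_dataset(n = 60, seed = seed)
    h <- optimize_weight(d)$h
    expect_lte(fusion_mse(h, d),
               min(fusion_mse(0, d), fusion_mse(1, d)) + 1e-12)
  }
})

test_that("sigmoid fit recovers noiseless generating parameters", {
  xbar <- seq(0.05, 0.95, by = 0.05)
  h <- 1 / (1 + exp(-8 * xbar + 4))
  m <- fit_sigmoid(cbind(xbar, h))
  expect_lt(abs(m$a_est - 8), 1e-3)
  expect_lt(abs(m$b_est - 4), 1e-3)
})

test_that("sigmoid fit of constant weights collapses to the flat model", {
  xbar <- seq(0.1, 0.9, by = 0.1)
  m <- fit_sigmoid(cbind(xbar, rep(0.5, length(xbar))))
  expect_lt(attr(m, "objective"), 1e-12)
  expect_equal(predict_weight(0.5, m), 0.5, tolerance = 1e-5)
})

test_that("sigmoid fit tolerates noise and beats a coarse grid oracle", {
  xbar <- seq(0.05, 0.95, by = 0.05)
  set.seed(31)
  h <- 1 / (1 + exp(-8 * xbar + 4)) + stats::rnorm(length(xbar), 0, 0.02)
  h <- pmin(pmax(h, 1e-3), 1 - 1e-3)
  m <- fit_sigmoid(cbind(xbar, h))
  expect_lt(abs(m$a_est - 8) / 8, 0.10)
  expect_lt(abs(m$b_est - 4) / 4, 0.10)
  # objective at optimum must not exceed the best of a coarse grid
  obj <- function(a, b) sum((1 / (1 + exp(-a * xbar + b)) - h)^2)
  grid <- expand.grid(a = seq(4, 12, by = 0.25), b = seq(2, 6, by = 0.25))
  grid_best <- min(mapply(obj, grid$a, grid$b))
  expect_lte(attr(m, "objective"), grid_best + 1e-4)
})

test_that("sigmoid fit enforces its preconditions", {
  expect_error(fit_sigmoid(cbind(c(0.2, 0.8), c(0.3, 0.7))), "at least 3")
  expect_error(fit_sigmoid(cbind(rep(0.5, 5), seq(0.1, 0.5, 0.1))), "identical")
})

test_that("predict_weight evaluates the logistic law", {
  m <- sigmoid_weight_model(8, 4)
  expect_equal(predict_weight(0.5, m), 0.5)          # a xbar = b -> midpoint
  expect_equal(predict_weight(1, m), 1 / (1 + exp(-4)))
  flat <- sigmoid_weight_model(0, 0)
  for (x in c(0, 0.3, 1)) expect_equal(predict_weight(x, flat), 0.5)
  # strictly monotone in brightness when a > 0
  xs <- seq(0, 1, 0.1)
  expect_true(all(diff(predict_weight(xs, m)) > 0))
})

test_that("fuse_sequences blends coordinatewise and tracks validity", {
  u <- toy_sequence(n = 4, seed = 1, source = "rgb_detector")
  v <- toy_sequence(n = 4, seed = 2, source = "aligned")
  expect_equal(fuse_sequences(u, v, 1)$coords, u$coords)
  expect_equal(fuse_sequences(u, v, 0)$coords, v$coords)
  q <- fuse_sequences(u, v, 0.25)
  expect_equal(q$coords, 0.25 * u$coords + 0.75 * v$coords)
  expect_identical(q$source, "fused")
  # validity: fused sample valid only where both inputs are
  u2 <- u
  u2$valid[2, 3] <- FALSE
  f <- fuse_sequences(u2, v, 0.5)
  expect_false(f$valid[2, 3])
  expect_true(all(is.na(f$coords[2, 3, ])))
  expect_error(fuse_sequences(u, v, 1.5), "\\[0, 1\\]")
})

test_that("calibration across gain levels yields a rising weight model", {
  # bright conditions favor the rgb stream, dark conditions the depth stream
  truth <- generate_truth(scene_spec(n_frames = 80, seed = 5))
  spec <- scene_spec(n_frames = 80, seed = 5)
  v <- simulate_depth_stream(truth, spec)
  gains <- c(1, 0.75, 0.55, 0.4, 0.3)
  scenes <- lapply(gains, function(g) {
    u <- simulate_rgb_stream(truth, g, spec)
    list(gain = g, data = fusion_dataset(u, v, truth),
         image = simulate_illumination(make_test_image("gradient"),
                                       illumination_params(g)))
  })
  cal <- calibrate_light_adaptation(scenes)
  expect_gt(cal$model$a_est, 0)
  # in-sample prediction quality at the calibration points
  pred <- predict_weight(cal$table$xbar, cal$model)
  expect_true(all(abs(pred - cal$table$h_best) < 0.1))
  expect_error(calibrate_light_adaptation(scenes[1]), "at least 3")
})
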