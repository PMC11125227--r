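test_that("trajectory metrics match their hand-derived examples", {
  expect_equal(mse(c(1, 2), c(0, 0)), 2.5)
  expect_equal(mse(c(1, 1), c(1, 1)), 0)
  expect_equal(mse(c(3, 3), c(1, 1)), 4)  # constant shift c -> c^2

  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(2, 3), c(2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")

  expect_equal(r_squared(c(0, 1, 2), c(0, 2, 4)), 0.375)  # 1 - 5/8
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  d <- c(1, 2, 3)
  expect_equal(r_squared(rep(mean(d), 3), d), 0)
  expect_error(r_squared(c(1, 2), c(5, 5)), "zero variance")

  expect_equal(percentage_difference(3, 1), 100)
  expect_equal(percentage_difference(c(2, 2), c(2, 2)), 0)
  expect_error(percentage_difference(0, 0), "zero mean-pair")

  expect_equal(coefficient_of_variation(c(1, 3)), sd(c(1, 3)) / 2 * 100)
  expect_equal(coefficient_of_variation(rep(4, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3) * 10),
               coefficient_of_variation(c(1, 3)))  # scale invariance
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("metric symmetries and asymmetries hold", {
  set.seed(12)
  F <- stats::rnorm(40, 5, 1); D <- stats::rnorm(40, 5, 1)
  expect_equal(mse(F, D), mse(D, F))
  expect_equal(percentage_difference(F, D), percentage_difference(D, F))
  expect_false(isTRUE(all.equal(r_squared(F, D), r_squared(D, F))))
})

test_that("joint accuracy counts threshold hits and is monotone", {
  # 12 samples: 9 at distance 5, 3 at distance 20
  F <- cbind(c(rep(5, 9), rep(20, 3)), 0)
  D <- cbind(rep(0, 12), 0)
  expect_equal(joint_accuracy(F, D, 8), 0.75)
  expect_equal(joint_accuracy(F, D, 4), 0)
  expect_equal(joint_accuracy(F, F, 6), 1)
  set.seed(77)
  for (i in 1:20) {
    A <- matrix(stats::rnorm(24, 0, 6), 12, 2)
    B <- matrix(stats::rnorm(24, 0, 6), 12, 2)
    expect_gte(joint_accuracy(A, B, 8), joint_accuracy(A, B, 6))
  }
})

test_that("every metric agrees with its naive-loop oracle on random input", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    d <- sample(1:3, 1)
    F <- matrix(stats::rnorm(n * d, 2, 1), n, d)
    D <- matrix(stats::rnorm(n * d, 2, 1), n, d)
    th <- stats::runif(1, 0.5, 4)
    expect_equal(mse(F, D), oracle_mse(F, D), tolerance = 1e-10)
    expect_equal(cosine_similarity(F, D), oracle_cosine(F, D), tolerance = 1e-10)
    expect_equal(r_squared(F, D), oracle_r_squared(F, D), tolerance = 1e-10)
    expect_equal(percentage_difference(abs(F), abs(D)),
                 oracle_percentage(abs(F), abs(D)), tolerance = 1e-10)
    if (d >= 2) {
      expect_equal(joint_accuracy(F[, 1:2], D[, 1:2], th),
                   oracle_joint_accuracy(F[, 1:2], D[, 1:2], th),
                   tolerance = 1e-10)
    }
    v <- stats::rnorm(8, 10, 2)
    expect_equal(coefficient_of_variation(v), oracle_cv(v), tolerance = 1e-10)
  }
})

test_that("global SSIM follows the closed form for constant images", {
  mkimg <- function(v) image_buffer(array(v, c(8, 8, 3)), "srgb")
  a <- 0.3; b <- 0.7
  C1 <- 0.01^2; C2 <- 0.03^2
  expected <- ((2 * a * b + C1) / (a^2 + b^2 + C1)) * (C2 / C2)
  expect_equal(ssim(mkimg(a), mkimg(b)), expected)
  expect_equal(ssim(mkimg(a), mkimg(a)), 1)
})

test_that("SSIM and PSNR match oracles and behave under noise", {
  set.seed(55)
  for (i in 1:40) {
    p <- matrix(stats::runif(64), 8, 8)
    q <- matrix(stats::runif(64), 8, 8)
    expect_equal(ssim(p, q), oracle_ssim(p, q), tolerance = 1e-6)
    expect_equal(ssim(p, q), ssim(q, p), tolerance = 1e-12)
    expect_equal(psnr(p, q), oracle_psnr(p, q), tolerance = 1e-6)
  }
  img <- make_test_image("gradient", size = 32)
  expect_equal(ssim(img, img), 1)
  expect_equal(psnr(img, img), Inf)
  # psnr decreases as noise amplitude increases
  set.seed(8)
  noise <- array(stats::rnorm(length(img)), dim(img))
  ps <- vapply(c(0.01, 0.05, 0.1, 0.2), function(s) {
    psnr(img, image_buffer(unclass(img) + s * noise, "srgb"))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # 8-bit arithmetic identity: MSE 6.5025 at MAX 255 -> 40 dB
  expect_equal(10 * log10(255^2 / 6.5025), 40)
  p8 <- matrix(0, 2, 2); q8 <- matrix(sqrt(6.5025), 2, 2)
  expect_equal(psnr(p8, q8, data_range = 255), 40)
})

test_that("SSIM of an image with its unit-gain relit self is 1", {
  img <- make_test_image("checker", size = 32)
  relit <- simulate_illumination(img, illumination_params(1))
  expect_equal(ssim(img, relit), 1, tolerance = 1e-6)
})

test_that("metric_report summarizes a stream pair coherently", {
  spec <- scene_spec(n_frames = 60, seed = 14)
  truth <- generate_truth(spec)
  noisy <- simulate_depth_stream(truth, spec)
  rep <- metric_report(noisy, truth, spec$calib)
  expect_s3_class(rep, "metric_report")
  expect_gt(rep$mse, 0)
  expect_lte(rep$r_squared, 1)
  expect_gte(rep$joint_accuracy[["8"]], rep$joint_accuracy[["6"]])
  expect_equal(nrow(rep$per_joint), 12)
  perfect <- metric_report(truth, truth, spec$calib)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r_squared, 1)
  expect_equal(unname(perfect$joint_accuracy), c(1, 1))
})
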