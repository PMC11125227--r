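# Shared fixture builders and independent naive-loop oracles.

# Small sequence with arbitrary smooth coordinates for the 12-joint catalog.
toy_sequence <- function(n = 5, rate = 30, source = "reference", unit = "m",
                         seed = 1) {
  catalog <- joint_catalog()
  set.seed(seed)
  coords <- array(stats::rnorm(n * 12 * 3, mean = 1, sd = 0.3), c(n, 12, 3))
  coords[, , 3] <- abs(coords[, , 3]) + 1.5  # keep depth positive
  keypoint_sequence(coords, (seq_len(n) - 1) / rate, catalog$joint,
                    rate = rate, source = source, unit = unit)
}

# Random fusion dataset: D is a noisy w-blend of U and V, so the optimal
# weight is interior and seed-reproducible.
random_fusion_dataset <- function(n = 100, seed = 1, w = NULL, noise = 0.05) {
  catalog <- joint_catalog()
  set.seed(seed)
  if (is.null(w)) w <- stats::runif(1, 0.2, 0.8)
  t <- (seq_len(n) - 1) / 30
  U <- array(stats::rnorm(n * 12 * 3), c(n, 12, 3))
  V <- array(stats::rnorm(n * 12 * 3), c(n, 12, 3))
  D <- w * U + (1 - w) * V + array(stats::rnorm(n * 12 * 3, 0, noise), c(n, 12, 3))
  mk <- function(a, src) keypoint_sequence(a, t, catalog$joint, rate = 30,
                                           source = src, unit = "m")
  fusion_dataset(mk(U, "rgb_detector"), mk(V, "aligned"), mk(D, "reference"))
}

# --- naive-loop metric oracles (independent of the vectorized paths) ------

oracle_mse <- function(F, D) {
  F <- as.matrix(F); D <- as.matrix(D)
  tot <- 0
  for (i in seq_len(nrow(F))) for (j in seq_len(ncol(F))) {
    tot <- tot + (F[i, j] - D[i, j])^2
  }
  tot / nrow(F)
}

oracle_cosine <- function(F, D) {
  f <- as.numeric(F); d <- as.numeric(D)
  num <- 0; nf <- 0; nd <- 0
  for (i in seq_along(f)) {
    num <- num + f[i] * d[i]; nf <- nf + f[i]^2; nd <- nd + d[i]^2
  }
  num / (sqrt(nf) * sqrt(nd))
}

oracle_r_squared <- function(F, D) {
  f <- as.numeric(F); d <- as.numeric(D)
  m <- sum(d) / length(d)
  ss_res <- 0; ss_tot <- 0
  for (i in seq_along(f)) {
    ss_res <- ss_res + (f[i] - d[i])^2
    ss_tot <- ss_tot + (d[i] - m)^2
  }
  1 - ss_res / ss_tot
}

oracle_percentage <- function(F, D) {
  f <- abs(as.numeric(F)); d <- abs(as.numeric(D))
  acc <- 0
  for (i in seq_along(f)) acc <- acc + abs(f[i] - d[i]) / ((f[i] + d[i]) / 2)
  acc / length(f) * 100
}

oracle_joint_accuracy <- function(F, D, th) {
  F <- as.matrix(F); D <- as.matrix(D)
  hits <- 0
  for (i in seq_len(nrow(F))) {
    dist <- sqrt(sum((F[i, ] - D[i, ])^2))
    if (dist <= th) hits <- hits + 1
  }
  hits / nrow(F)
}

oracle_cv <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  ss <- 0
  for (x in v) ss <- ss + (x - m)^2
  sqrt(ss / (n - 1)) / m * 100
}

oracle_ssim <- function(gp, gq, L = 1) {
  np <- length(gp)
  mu_p <- sum(gp) / np; mu_q <- sum(gq) / np
  vp <- 0; vq <- 0; cpq <- 0
  for (i in seq_along(gp)) {
    vp <- vp + (gp[i] - mu_p)^2
    vq <- vq + (gq[i] - mu_q)^2
    cpq <- cpq + (gp[i] - mu_p) * (gq[i] - mu_q)
  }
  vp <- vp / np; vq <- vq / np; cpq <- cpq / np
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  ((2 * mu_p * mu_q + C1) * (2 * cpq + C2)) /
    ((mu_p^2 + mu_q^2 + C1) * (vp + vq + C2))
}

oracle_psnr <- function(p, q, L = 1) {
  e <- 0
  for (i in seq_along(p)) e <- e + (p[i] - q[i])^2
  e <- e / length(p)
  if (e == 0) Inf else 10 * log10(L^2 / e)
}

# Grid search oracle for the optimal fusion weight (0.001 step).
oracle_grid_weight <- function(data, step = 0.001) {
  grid <- seq(0, 1, by = step)
  vals <- vapply(grid, function(h) fusion_mse(h, data), numeric(1))
  grid[which.min(vals)]
}
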