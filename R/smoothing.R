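#' Kalman filter configuration
#'
#' Constant-velocity filter with process noise `Q = q I6` and observation
#' noise `R = r I3`. Defaults follow the trajectory-smoothing setup used
#' for fused keypoint streams: `q = 0.08`, `r = 0.2`, 30 fps frame
#' interval, and a 30-frame window to initialize per-joint velocity. Noise
#' scales are expressed in the unit of the filtered data (pixels for 2-D
#' runs, meters for 3-D) and are config-overridable.
#'
#' @param dt Frame interval in seconds (default 1/30).
#' @param q Process-noise scale (default 0.08).
#' @param r Observation-noise scale (default 0.2).
#' @param init_window Frames used to initialize velocity (default 30).
#' @return An object of class `kalman_config`.
#' @export
kalman_config <- function(dt = 1 / 30, q = 0.08, r = 0.2, init_window = 30) {
  if (dt <= 0) stop("dt must be positive")
  if (q <= 0 || r <= 0) stop("noise scales q and r must be positive")
  if (init_window < 2) stop("init_window must be >= 2")
  structure(list(dt = dt, q = q, r = r, init_window = as.integer(init_window)),
            class = "kalman_config")
}

#' Kalman filter state
#'
#' @param x 6-vector: position (3) then velocity (3).
#' @param P 6x6 covariance, symmetric positive semi-definite.
#' @return An object of class `kalman_state`.
#' @export
kalman_state <- function(x, P = diag(6)) {
  x <- as.numeric(x)
  P <- as.matrix(P)
  if (length(x) != 6L || !all(dim(P) == c(6L, 6L))) {
    stop("state is a 6-vector with a 6x6 covariance")
  }
  if (max(abs(P - t(P))) > 1e-9) stop("covariance must be symmetric")
  if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
    stop("covariance must be positive semi-definite")
  }
  structure(list(x = x, P = (P + t(P)) / 2), class = "kalman_state")
}

# Constant-velocity transition matrix: position += dt * velocity.
kalman_A <- function(dt) {
  A <- diag(6)
  A[1:3, 4:6] <- dt * diag(3)
  A
}

#' Kalman prediction step
#'
#' Propagates the state through the constant-velocity model:
#' `x- = A x`, `P- = A P A^T + Q` with `Q = q I6`.
#'
#' @param state A [kalman_state()].
#' @param cfg A [kalman_config()].
#' @return The prior [kalman_state()].
#' @export
kalman_predict <- function(state, cfg = kalman_config()) {
  stopifnot(inherits(state, "kalman_state"), inherits(cfg, "kalman_config"))
  A <- kalman_A(cfg$dt)
  kalman_state(A %*% state$x, A %*% state$P %*% t(A) + cfg$q * diag(6))
}

#' Kalman measurement update
#'
#' Position-only observation `H = [I3 | 0]`: the gain is
#' `K = P- H^T (H P- H^T + r I3)^-1`, the posterior mean
#' `x = x- + K (z - H x-)`, the posterior covariance `(I - K H) P-`,
#' re-symmetrized.
#'
#' @param prior A prior [kalman_state()] (output of [kalman_predict()]).
#' @param z Length-3 position measurement.
#' @param cfg A [kalman_config()].
#' @return The posterior [kalman_state()].
#' @export
kalman_update <- function(prior, z, cfg = kalman_config()) {
  stopifnot(inherits(prior, "kalman_state"), inherits(cfg, "kalman_config"))
  z <- as.numeric(z)
  if (length(z) != 3L || any(!is.finite(z))) stop("z must be a finite 3-vector")
  H <- cbind(diag(3), matrix(0, 3, 3))
  S <- H %*% prior$P %*% t(H) + cfg$r * diag(3)
  K <- prior$P %*% t(H) %*% solve(S)
  x <- prior$x + K %*% (z - H %*% prior$x)
  P <- (diag(6) - K %*% H) %*% prior$P
  kalman_state(x, (P + t(P)) / 2)
}

#' Smooth a keypoint sequence with a per-joint Kalman filter
#'
#' Runs an independent constant-velocity filter over each joint's
#' trajectory. Initialization uses the first valid frame as the starting
#' position and the mean finite-difference velocity over the first
#' `init_window` frames; `P0 = I6`. From the second frame on, each frame is
#' a predict step followed by an update with that frame's measured
#' position; frames with an invalid measurement are predict-only. Output
#' positions are the posterior means; validity flags are copied from the
#' input. The filter is causal: the output at frame k depends only on
#' frames up to k.
#'
#' @param seq A [keypoint_sequence()] with at least `init_window` frames.
#' @param cfg A [kalman_config()]; `dt` defaults to the sequence's frame
#'   interval when `cfg` is omitted.
#' @return The smoothed [keypoint_sequence()].
#' @export
smooth_sequence <- function(seq, cfg = NULL) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  if (is.null(cfg)) cfg <- kalman_config(dt = 1 / seq$rate)
  n <- n_frames(seq)
  if (n < cfg$init_window) {
    stop("sequence has ", n, " frames; smoothing needs at least init_window = ",
         cfg$init_window)
  }
  out <- seq$coords
  for (j in seq_along(seq$joints)) {
    pos <- seq$coords[, j, , drop = TRUE]          # n x 3
    ok <- seq$valid[, j] & !apply(is.na(pos), 1, any)
    if (!any(ok)) next
    first <- which(ok)[1]
    # velocity from mean finite difference over the initialization window
    w <- seq_len(min(cfg$init_window, n))
    vel <- c(0, 0, 0)
    dok <- which(ok[w][-length(w)] & ok[w][-1])
    if (length(dok) > 0) {
      d <- (pos[w[dok + 1L], , drop = FALSE] - pos[w[dok], , drop = FALSE]) / cfg$dt
      vel <- colMeans(d)
    }
    st <- kalman_state(c(pos[first, ], vel), diag(6))
    out[first, j, ] <- st$x[1:3]
    if (first < n) for (k in (first + 1L):n) {
      st <- kalman_predict(st, cfg)
      if (ok[k]) st <- kalman_update(st, pos[k, ], cfg)
      out[k, j, ] <- st$x[1:3]
    }
  }
  keypoint_sequence(out, seq$time, seq$joints, seq$valid,
                    rate = seq$rate, source = seq$source, unit = seq$unit,
                    frames = seq$frames)
}
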