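#' Assemble a fusion calibration dataset
#'
#' Bundles the three streams the weight solve needs: the RGB-detector
#' stream `U'` (possibly captured under simulated illumination), the
#' depth-camera stream `V'` after [transform_to_reference()], and the
#' motion-capture reference `D`. Only samples where all three streams are
#' valid enter the objective.
#'
#' @param u_prime,v_prime,d [keypoint_sequence()]s on a shared frame grid
#'   with identical joint sets.
#' @return An object of class `fusion_dataset` with jointly-valid sample
#'   matrices `U`, `V`, `D` (n x 3) and the sample count `n`.
#' @export
fusion_dataset <- function(u_prime, v_prime, d) {
  check_same_grid(u_prime, v_prime)
  check_same_grid(u_prime, d)
  jv <- jointly_valid(list(u_prime, v_prime, d))
  n <- nrow(jv$mats[[1]])
  if (n < 1L) stop("no jointly valid (frame, joint) samples")
  structure(list(U = jv$mats[[1]], V = jv$mats[[2]], D = jv$mats[[3]],
                 n = n, u_prime = u_prime, v_prime = v_prime, d = d),
            class = "fusion_dataset")
}

#' Fused mean squared error objective
#'
#' The calibration objective: for fused stream `L = h U' + (1 - h) V'`,
#' the mean over jointly valid samples of the squared Euclidean distance
#' `||L_i - D_i||^2` to the reference.
#'
#' @param h Scalar fusion weight.
#' @param data A [fusion_dataset()].
#' @return Non-negative scalar MSE.
#' @export
fusion_mse <- function(h, data) {
  stopifnot(inherits(data, "fusion_dataset"))
  resid <- h * data$U + (1 - h) * data$V - data$D
  mean(rowSums(resid^2))
}

# Analytic gradient of fusion_mse in h: (2/n) sum <U - V, L - D>.
fusion_mse_grad <- function(h, data) {
  diffUV <- data$U - data$V
  resid <- h * data$U + (1 - h) * data$V - data$D
  2 * mean(rowSums(diffUV * resid))
}

#' Closed-form optimal fusion weight
#'
#' The fused-MSE objective is an exact quadratic in the scalar weight, so
#' its unconstrained minimizer has the closed form
#' `h* = sum <U'_i - V'_i, D_i - V'_i> / sum ||U'_i - V'_i||^2`,
#' clamped to `[0, 1]`. Serves as the independent oracle for the iterative
#' solver.
#'
#' @param data A [fusion_dataset()].
#' @return Scalar weight in `[0, 1]`. If `U' = V'` everywhere the objective
#'   is constant; 0.5 is returned with a warning.
#' @export
closed_form_weight <- function(data) {
  stopifnot(inherits(data, "fusion_dataset"))
  diffUV <- data$U - data$V
  denom <- sum(diffUV^2)
  if (denom <= 0) {
    warning("U' and V' coincide on all valid samples; objective is constant in h")
    return(0.5)
  }
  h <- sum(diffUV * (data$D - data$V)) / denom
  min(max(h, 0), 1)
}

#' Solve for the optimal fusion weight by L-BFGS
#'
#' Minimizes [fusion_mse()] over the scalar weight with the two-loop
#' recursion quasi-Newton engine, starting from `cfg$h0` and stopping at
#' gradient threshold `cfg$epsilon`. The returned weight is clamped to
#' `[0, 1]` (with a warning if the unconstrained minimizer fell outside),
#' since it is interpreted as a convex-combination coefficient.
#'
#' @param data A [fusion_dataset()].
#' @param cfg An [lbfgs_config()].
#' @return A `fusion_result`: list with weight `h`, fused sequence `L`,
#'   final `objective` and `iterations`.
#' @export
optimize_weight <- function(data, cfg = lbfgs_config()) {
  stopifnot(inherits(data, "fusion_dataset"))
  res <- lbfgs_minimize(function(h) fusion_mse(h, data),
                        function(h) fusion_mse_grad(h, data),
                        cfg$h0, cfg)
  h <- res$par
  if (h < 0 || h > 1) {
    warning("unconstrained optimal weight ", format(h), " clamped to [0, 1]")
    h <- min(max(h, 0), 1)
  }
  structure(list(h = h, L = fuse_sequences(data$u_prime, data$v_prime, h),
                 objective = fusion_mse(h, data), iterations = res$iterations),
            class = "fusion_result")
}

#' Logistic brightness-to-weight model
#'
#' @param a_est Slope parameter.
#' @param b_est Offset parameter.
#' @return An object of class `sigmoid_weight_model`.
#' @export
sigmoid_weight_model <- function(a_est, b_est) {
  if (!all(is.finite(c(a_est, b_est)))) stop("model parameters must be finite")
  structure(list(a_est = a_est, b_est = b_est), class = "sigmoid_weight_model")
}

#' Predict the fusion weight from scene brightness
#'
#' Evaluates the fitted logistic law `h = 1 / (1 + exp(-a_est * xbar + b_est))`.
#' Output is always in the open interval (0, 1).
#'
#' @param xbar Mean scene brightness (see [mean_brightness()]).
#' @param model A [sigmoid_weight_model()].
#' @return Predicted weight in (0, 1).
#' @export
predict_weight <- function(xbar, model) {
  stopifnot(inherits(model, "sigmoid_weight_model"))
  1 / (1 + exp(-model$a_est * xbar + model$b_est))
}

#' Fit the sigmoid brightness-to-weight model
#'
#' Least-squares fit of `(a_est, b_est)` to calibration pairs
#' `(xbar_i, h_best_i)`, minimizing
#' `sum_i (1 / (1 + exp(-a xbar_i + b)) - h_best_i)^2` with the same L-BFGS
#' engine used for the weight solve, run in 2 dimensions. Logistic least
#' squares is non-convex, so the solver is multi-started over a fixed grid
#' of initial values (`a` in {-20, -10, -5, 0, 5, 10, 20}, `b` in
#' {-10, -5, 0, 5, 10}) and the best final objective is kept.
#'
#' @param samples A 2-column matrix or data frame: column 1 brightness
#'   `xbar` in `[0, 1]`, column 2 optimal weight `h_best` in `[0, 1]`. At
#'   least 3 rows; `xbar` values must not all coincide.
#' @param cfg An [lbfgs_config()]; the fit defaults to a tighter gradient
#'   threshold (1e-10) and a higher iteration cap than the weight solve
#'   because parameter accuracy — not objective accuracy — is what matters
#'   here.
#' @return A [sigmoid_weight_model()] with attribute `objective`.
#' @export
fit_sigmoid <- function(samples, cfg = lbfgs_config(epsilon = 1e-10, max_iter = 500)) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 3L) stop("need at least 3 (xbar, h_best) samples")
  xbar <- as.numeric(samples[, 1])
  hb <- as.numeric(samples[, 2])
  if (diff(range(xbar)) == 0) stop("all xbar values identical; slope unidentifiable")

  fn <- function(p) {
    s <- 1 / (1 + exp(-p[1] * xbar + p[2]))
    sum((s - hb)^2)
  }
  gr <- function(p) {
    s <- 1 / (1 + exp(-p[1] * xbar + p[2]))
    e <- s - hb
    w <- 2 * e * s * (1 - s)
    c(sum(w * xbar), -sum(w))
  }
  starts <- expand.grid(a = c(-20, -10, -5, 0, 5, 10, 20),
                        b = c(-10, -5, 0, 5, 10))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- lbfgs_minimize(fn, gr, c(starts$a[i], starts$b[i]), cfg)
    if (is.null(best) || res$value < best$value) best <- res
  }
  out <- sigmoid_weight_model(best$par[1], best$par[2])
  attr(out, "objective") <- best$value
  out
}

#' Blend two keypoint streams with a fixed weight
#'
#' The fused stream `L' = h U' + (1 - h) V'`, computed per (frame, joint);
#' a fused sample is valid only where both inputs are valid.
#'
#' @param u_prime,v_prime [keypoint_sequence()]s on a shared grid.
#' @param h Fusion weight in `[0, 1]`.
#' @return A [keypoint_sequence()] labeled `source = "fused"`.
#' @export
fuse_sequences <- function(u_prime, v_prime, h) {
  check_same_grid(u_prime, v_prime)
  if (!is.finite(h) || h < 0 || h > 1) stop("fusion weight h must lie in [0, 1]")
  coords <- h * u_prime$coords + (1 - h) * v_prime$coords
  valid <- u_prime$valid & v_prime$valid
  coords[!rep(valid, 3)] <- NA_real_
  keypoint_sequence(coords, u_prime$time, u_prime$joints, valid,
                    rate = u_prime$rate, source = "fused",
                    unit = u_prime$unit, frames = u_prime$frames)
}

#' Calibrate the light-adaptive weight model from a gain sweep
#'
#' For each illumination condition (one inverse gain level) the optimal
#' fusion weight is solved by [optimize_weight()] against the reference
#' stream, its scene brightness `xbar` is measured (from a supplied image
#' via [mean_brightness()], or taken directly from the scene entry), and
#' the sigmoid weight model is then fitted to the resulting
#' `(xbar, h_best)` table.
#'
#' @param scenes A list with one entry per illumination condition; each
#'   entry is a list with elements `data` (a [fusion_dataset()]), plus
#'   either `xbar` (scalar brightness) or `image` (an sRGB
#'   [image_buffer()]), and optionally `gain` (recorded in the table).
#' @param cfg An [lbfgs_config()] for the per-scene weight solves.
#' @return A `light_calibration`: list with `model`
#'   (a [sigmoid_weight_model()]) and `table` (data frame of gain, xbar,
#'   h_best, objective per condition).
#' @export
calibrate_light_adaptation <- function(scenes, cfg = lbfgs_config()) {
  if (length(scenes) < 3L) stop("need at least 3 illumination conditions to calibrate")
  rows <- lapply(scenes, function(sc) {
    xbar <- if (!is.null(sc$xbar)) sc$xbar else if (!is.null(sc$image)) {
      mean_brightness(sc$image)
    } else stop("each scene needs either 'xbar' or 'image'")
    fit <- optimize_weight(sc$data, cfg)
    data.frame(gain = if (is.null(sc$gain)) NA_real_ else sc$gain,
               xbar = xbar, h_best = fit$h, objective = fit$objective)
  })
  tab <- do.call(rbind, rows)
  model <- fit_sigmoid(tab[, c("xbar", "h_best")])
  structure(list(model = model, table = tab), class = "light_calibration")
}

#' @export
print.light_calibration <- function(x, ...) {
  cat(sprintf("<light_calibration> a_est = %.4f, b_est = %.4f over %d conditions\n",
              x$model$a_est, x$model$b_est, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
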