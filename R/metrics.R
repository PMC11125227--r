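# Coerce metric inputs to an n x d sample matrix. Accepts numeric vectors
# (d = 1), matrices, or keypoint sequences (jointly valid samples only when
# paired via metric_samples).
as_sample_matrix <- function(x) {
  if (inherits(x, "keypoint_sequence")) {
    stop("pass keypoint sequences through metric_report(), or extract ",
         "jointly valid samples first")
  }
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
}

check_shapes <- function(F, D) {
  if (!all(dim(F) == dim(D))) stop("inputs must have identical shapes")
  if (nrow(F) < 1L) stop("need at least one sample")
  invisible(TRUE)
}

#' Mean squared error
#'
#' Mean over samples of the squared Euclidean deviation `||F_i - D_i||^2`.
#' For scalar samples this is the usual MSE.
#'
#' @param F,D Numeric vectors or n x d matrices of equal shape (predicted
#'   and reference samples).
#' @return Non-negative scalar.
#' @export
mse <- function(F, D) {
  F <- as_sample_matrix(F); D <- as_sample_matrix(D)
  check_shapes(F, D)
  mean(rowSums((F - D)^2))
}

#' Cosine similarity
#'
#' Inner product of the flattened coordinate vectors over the product of
#' their norms; 1 means directionally identical, 0 orthogonal.
#'
#' @inheritParams mse
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(F, D) {
  f <- as.numeric(as_sample_matrix(F)); d <- as.numeric(as_sample_matrix(D))
  if (length(f) != length(d)) stop("inputs must have identical shapes")
  nf <- sqrt(sum(f^2)); nd <- sqrt(sum(d^2))
  if (nf == 0 || nd == 0) stop("cosine similarity undefined for zero-norm input")
  sum(f * d) / (nf * nd)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSres / SStot` with residuals taken against the reference
#' `D` and total variation about `mean(D)`, both over the flattened
#' samples. Not symmetric in its arguments.
#'
#' @inheritParams mse
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(F, D) {
  f <- as.numeric(as_sample_matrix(F)); d <- as.numeric(as_sample_matrix(D))
  if (length(f) != length(d)) stop("inputs must have identical shapes")
  ss_tot <- sum((d - mean(d))^2)
  if (ss_tot == 0) stop("reference has zero variance; R^2 undefined")
  1 - sum((f - d)^2) / ss_tot
}

#' Percentage difference
#'
#' Mean of `|F_i - D_i| / ((F_i + D_i) / 2) * 100`. Raw signed coordinates
#' can make the mean-pair denominator vanish or flip sign, so the default
#' (`on = "magnitude"`) feeds coordinate magnitudes into the formula; the
#' `"norm"` variant feeds per-sample Euclidean norms instead.
#'
#' @inheritParams mse
#' @param on `"magnitude"` (per-coordinate absolute values, default) or
#'   `"norm"` (per-sample Euclidean norms).
#' @return Non-negative percentage; symmetric in `F` and `D`.
#' @export
percentage_difference <- function(F, D, on = c("magnitude", "norm")) {
  on <- match.arg(on)
  F <- as_sample_matrix(F); D <- as_sample_matrix(D)
  check_shapes(F, D)
  if (on == "magnitude") {
    f <- abs(as.numeric(F)); d <- abs(as.numeric(D))
  } else {
    f <- sqrt(rowSums(F^2)); d <- sqrt(rowSums(D^2))
  }
  denom <- (f + d) / 2
  if (any(denom == 0)) stop("zero mean-pair denominator in percentage difference")
  mean(abs(f - d) / denom) * 100
}

#' Joint accuracy at a pixel threshold
#'
#' PCK-style score: the fraction of (frame, joint) samples whose Euclidean
#' pixel distance between prediction and reference is at most `threshold`.
#' Operates on 2-D pixel data (sequences projected via
#' [project_to_image()], or plain n x 2 matrices).
#'
#' @param F,D 2-D pixel [keypoint_sequence()]s on a shared grid, or n x 2
#'   numeric matrices.
#' @param threshold Distance threshold in pixels (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
joint_accuracy <- function(F, D, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  if (inherits(F, "keypoint_sequence")) {
    check_same_grid(F, D)
    if (F$unit != "px" || D$unit != "px") {
      stop("joint accuracy is defined on pixel-unit sequences")
    }
    jv <- jointly_valid(list(F, D))
    Fm <- jv$mats[[1]][, 1:2, drop = FALSE]
    Dm <- jv$mats[[2]][, 1:2, drop = FALSE]
  } else {
    Fm <- as_sample_matrix(F); Dm <- as_sample_matrix(D)
    check_shapes(Fm, Dm)
  }
  if (nrow(Fm) == 0L) stop("no valid samples for joint accuracy")
  d <- sqrt(rowSums((Fm - Dm)^2))
  mean(d <= threshold)
}

#' Coefficient of variation
#'
#' Relative stability of repeated measurements: sample standard deviation
#' over mean, in percent. Uses the n-1 (sample) standard deviation
#' convention.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return Non-negative percentage.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  stats::sd(values) / m * 100
}

# Luminance plane of an image buffer (Rec. 709 weights on stored values).
img_gray <- function(img) {
  p <- unclass(img)
  0.2126 * p[, , 1] + 0.7152 * p[, , 2] + 0.0722 * p[, , 3]
}

#' Structural similarity index (global)
#'
#' Whole-image SSIM on the luminance plane using single global means,
#' variances and covariance (no sliding window):
#' `(2 mu_p mu_q + C1)(2 cov + C2) / ((mu_p^2 + mu_q^2 + C1)(var_p + var_q + C2))`
#' with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` and `L` the dynamic range.
#' A windowed mean-SSIM variant (8x8 blocks) is available behind
#' `windowed = TRUE` for comparison but the global form is the primary
#' definition.
#'
#' @param p,q [image_buffer()]s of identical dimensions (any matching
#'   space), or numeric matrices.
#' @param data_range Dynamic range `L` (default 1 for `[0, 1]` buffers).
#' @param windowed Use 8x8 tiled mean-SSIM instead of global statistics.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(p, q, data_range = 1, windowed = FALSE) {
  gp <- if (inherits(p, "image_buffer")) img_gray(p) else as.matrix(p)
  gq <- if (inherits(q, "image_buffer")) img_gray(q) else as.matrix(q)
  if (!all(dim(gp) == dim(gq))) stop("images must have identical dimensions")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  ssim_stat <- function(a, b) {
    mu_a <- mean(a); mu_b <- mean(b)
    va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
    cov <- mean((a - mu_a) * (b - mu_b))
    ((2 * mu_a * mu_b + C1) * (2 * cov + C2)) /
      ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  }
  if (!windowed) return(ssim_stat(gp, gq))
  h <- nrow(gp); w <- ncol(gp)
  bi <- split(seq_len(h), ceiling(seq_len(h) / 8))
  bj <- split(seq_len(w), ceiling(seq_len(w) / 8))
  vals <- unlist(lapply(bi, function(ri) {
    vapply(bj, function(cj) ssim_stat(gp[ri, cj], gq[ri, cj]), numeric(1))
  }))
  mean(vals)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(MAX^2 / MSE)` in decibels, with per-pixel MSE over all
#' channels and `MAX` the dynamic-range maximum (1 for `[0, 1]` buffers;
#' pass `data_range = 255` for 8-bit convention). Identical images return
#' `Inf` as a documented sentinel. Set `observed_max = TRUE` to use the
#' observed maximum of `p` instead of the range maximum.
#'
#' @inheritParams ssim
#' @param observed_max Use `max(p)` as MAX instead of `data_range`.
#' @return PSNR in dB, or `Inf` for identical images.
#' @export
psnr <- function(p, q, data_range = 1, observed_max = FALSE) {
  ap <- if (inherits(p, "image_buffer")) unclass(p) else as.array(p)
  aq <- if (inherits(q, "image_buffer")) unclass(q) else as.array(q)
  if (!all(dim(ap) == dim(aq))) stop("images must have identical dimensions")
  err <- mean((ap - aq)^2)
  mx <- if (observed_max) max(ap) else data_range
  if (err == 0) return(Inf)
  10 * log10(mx^2 / err)
}

#' Full evaluation report for a predicted stream
#'
#' Computes the trajectory metric suite of a predicted keypoint stream
#' against a reference: 3-D MSE, R-squared, cosine similarity and
#' percentage difference on the jointly valid samples, plus pixel-threshold
#' joint accuracy after projection through the camera model, overall and
#' per joint.
#'
#' @param pred,ref Metric 3-D [keypoint_sequence()]s on a shared grid.
#' @param calib A [camera_calibration()] used to project both streams to
#'   pixels for joint accuracy.
#' @param thresholds Pixel thresholds for joint accuracy (default `c(6, 8)`).
#' @return A list of class `metric_report`.
#' @export
metric_report <- function(pred, ref, calib, thresholds = c(6, 8)) {
  check_same_grid(pred, ref)
  jv <- jointly_valid(list(pred, ref))
  Fm <- jv$mats[[1]]; Dm <- jv$mats[[2]]
  pred_px <- project_to_image(pred, calib)
  ref_px <- project_to_image(ref, calib)
  acc <- vapply(thresholds, function(th) joint_accuracy(pred_px, ref_px, th),
                numeric(1))
  names(acc) <- as.character(thresholds)

  per_joint <- lapply(seq_along(pred$joints), function(j) {
    ok <- jv$mask[, j]
    if (!any(ok)) return(NULL)
    Fj <- pred$coords[ok, j, , drop = TRUE]; Dj <- ref$coords[ok, j, , drop = TRUE]
    if (is.null(dim(Fj))) { Fj <- matrix(Fj, 1); Dj <- matrix(Dj, 1) }
    Fpx <- cbind(pred_px$coords[ok, j, 1], pred_px$coords[ok, j, 2])
    Dpx <- cbind(ref_px$coords[ok, j, 1], ref_px$coords[ok, j, 2])
    a <- vapply(thresholds, function(th) joint_accuracy(Fpx, Dpx, th), numeric(1))
    data.frame(joint = pred$joints[j], mse = mse(Fj, Dj),
               diff_percent = percentage_difference(Fj, Dj, on = "norm"),
               t(stats::setNames(a, paste0("acc_", thresholds))))
  })
  structure(list(
    mse = mse(Fm, Dm),
    r_squared = r_squared(Fm, Dm),
    cosine = cosine_similarity(Fm, Dm),
    diff_percent = percentage_difference(Fm, Dm, on = "norm"),
    joint_accuracy = acc,
    n_samples = nrow(Fm),
    per_joint = do.call(rbind, per_joint)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  MSE          %.6g\n", x$mse))
  cat(sprintf("  R^2          %.4f\n", x$r_squared))
  cat(sprintf("  cosine       %.4f\n", x$cosine))
  cat(sprintf("  diff%%        %.2f\n", x$diff_percent))
  for (th in names(x$joint_accuracy)) {
    cat(sprintf("  accuracy@%spx  %.1f%%\n", th, 100 * x$joint_accuracy[[th]]))
  }
  invisible(x)
}
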