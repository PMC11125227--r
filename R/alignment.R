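#' Camera calibration parameters
#'
#' Intrinsics (focal lengths `fx`, `fy`; optical center `dx`, `dy`; scale
#' factor `s`) and extrinsics (rotation `R`, translation `T`) of the depth
#' camera relative to the reference coordinate system. The rotation must be
#' orthonormal with determinant +1; calibration values are consumed from a
#' config file — estimating them (e.g. by checkerboard calibration) is out
#' of scope.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param dx,dy Optical center in pixels.
#' @param s Dimensionless scale factor applied to 3-D points before
#'   projection (default 1).
#' @param R 3x3 rotation matrix.
#' @param T Length-3 translation vector, in the length unit of the
#'   keypoints.
#' @return An object of class `camera_calibration`.
#' @export
camera_calibration <- function(fx, fy, dx, dy, s = 1,
                               R = diag(3), T = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  T <- as.numeric(T)
  if (length(T) != 3L) stop("T must be a 3-vector")
  if (!all(is.finite(c(fx, fy, dx, dy, s, R, T)))) stop("non-finite calibration value")
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (s <= 0) stop("scale factor s must be positive")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    stop("R must be orthonormal with determinant +1")
  }
  structure(list(fx = fx, fy = fy, dx = dx, dy = dy, s = s, R = R, T = T),
            class = "camera_calibration")
}

#' Read a camera calibration block from a YAML config
#'
#' Expects keys `fx, fy, dx, dy, s, R, T` with `R` given as 9 numbers in
#' row-major order and `T` as 3 numbers. The block may be the whole file or
#' nested under `calibration:`.
#'
#' @param path Path to the YAML file.
#' @return A [camera_calibration()].
#' @export
read_calibration <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$calibration)) cfg <- cfg$calibration
  camera_calibration(
    fx = cfg$fx, fy = cfg$fy, dx = cfg$dx, dy = cfg$dy,
    s = if (is.null(cfg$s)) 1 else cfg$s,
    R = matrix(as.numeric(cfg$R), 3, 3, byrow = TRUE),
    T = as.numeric(cfg$T)
  )
}

#' Rigidly transform a 3-D stream into the reference coordinate system
#'
#' Maps every valid joint position `p` of the depth-camera stream to
#' `R p + T`, expressing it in the coordinate system of the RGB stream.
#' Being a rigid motion, the map preserves all inter-joint distances.
#'
#' @param seq A metric (`unit == "m"`) [keypoint_sequence()].
#' @param calib A [camera_calibration()].
#' @return The transformed sequence, labeled `source = "aligned"`.
#' @export
transform_to_reference <- function(seq, calib) {
  stopifnot(inherits(seq, "keypoint_sequence"), inherits(calib, "camera_calibration"))
  if (seq$unit != "m") stop("transform_to_reference expects a metric 3-D sequence")
  d <- dim(seq$coords)
  flat <- matrix(seq$coords, d[1] * d[2], 3)       # rows are (frame, joint) points
  flat <- sweep(flat %*% t(calib$R), 2, calib$T, `+`)
  keypoint_sequence(array(flat, d), seq$time, seq$joints, seq$valid,
                    rate = seq$rate, source = "aligned", unit = seq$unit,
                    frames = seq$frames)
}

#' Project a 3-D stream to 2-D pixel coordinates
#'
#' Pinhole projection `u = fx X / Z + dx`, `v = fy Y / Z + dy`, applied after
#' scaling points by the calibration scale factor `s`. Used so that joint
#' accuracy can be evaluated at pixel thresholds. The output sequence has
#' unit `"px"` and its Z column set to 0.
#'
#' @param seq A metric [keypoint_sequence()] expressed in the camera frame;
#'   every valid joint must have Z > 0.
#' @param calib A [camera_calibration()].
#' @return A 2-D pixel [keypoint_sequence()].
#' @export
project_to_image <- function(seq, calib) {
  stopifnot(inherits(seq, "keypoint_sequence"), inherits(calib, "camera_calibration"))
  if (seq$unit != "m") stop("project_to_image expects a metric 3-D sequence")
  Z <- seq$coords[, , 3] * calib$s
  bad <- seq$valid & !is.na(Z) & Z <= 0
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-positive depth at frame ", seq$frames[i[1]], ", joint '",
         seq$joints[i[2]], "': cannot project")
  }
  d <- dim(seq$coords)
  u <- calib$fx * seq$coords[, , 1] / seq$coords[, , 3] + calib$dx
  v <- calib$fy * seq$coords[, , 2] / seq$coords[, , 3] + calib$dy
  out <- array(0, d)
  out[, , 1] <- u
  out[, , 2] <- v
  keypoint_sequence(out, seq$time, seq$joints, seq$valid,
                    rate = seq$rate, source = seq$source, unit = "px",
                    frames = seq$frames)
}
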