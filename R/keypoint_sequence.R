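#' Construct a keypoint sequence
#'
#' A keypoint sequence is the package's central container: a time-ordered
#' set of frames, each holding one 3-D (or projected 2-D) coordinate per
#' canonical joint, with an explicit validity flag per (frame, joint).
#' Invalid joints carry `NA` coordinates — never silent zeros — and are
#' excluded from all downstream sums (fusion objectives, metric
#' denominators).
#'
#' @param coords Numeric array `n_frames x n_joints x 3`. Coordinates of
#'   invalid samples may be `NA`.
#' @param time Numeric vector of frame timestamps in seconds, strictly
#'   increasing.
#' @param joints Character vector of canonical joint names (one per coords
#'   column).
#' @param valid Logical matrix `n_frames x n_joints`; defaults to all valid.
#' @param rate Nominal frame rate in frames per second.
#' @param source One of `"rgb_detector"`, `"depth_camera"`, `"reference"`,
#'   `"fused"`, `"aligned"`.
#' @param unit `"m"` for metric 3-D streams, `"px"` for projected 2-D
#'   streams. Kept explicit so metric and pixel data are never mixed
#'   silently.
#' @param frames Integer frame indices, strictly increasing; defaults to
#'   `0:(n_frames-1)`.
#' @return An object of class `keypoint_sequence`.
#' @export
keypoint_sequence <- function(coords, time, joints, valid = NULL,
                              rate = 30, source = "reference", unit = "m",
                              frames = NULL) {
  sources <- c("rgb_detector", "depth_camera", "reference", "fused", "aligned")
  if (!source %in% sources) {
    stop("source must be one of: ", paste(sources, collapse = ", "))
  }
  if (!unit %in% c("m", "px")) stop("unit must be 'm' or 'px'")
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be an n_frames x n_joints x 3 array")
  }
  n <- dim(coords)[1]
  nj <- dim(coords)[2]
  if (n < 1L) stop("a keypoint sequence needs at least one frame")
  if (length(time) != n) stop("time must have one entry per frame")
  if (length(joints) != nj) stop("joints must name every coords column")
  if (anyDuplicated(joints)) stop("duplicate joint names")
  if (any(time < 0)) stop("timestamps must be non-negative")
  if (n > 1L && any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(frames)) frames <- seq_len(n) - 1L
  frames <- as.integer(frames)
  if (any(frames < 0L)) stop("frame indices must be non-negative")
  if (n > 1L && any(diff(frames) <= 0L)) stop("frame indices must be strictly increasing")
  if (is.null(valid)) valid <- matrix(TRUE, n, nj)
  valid <- matrix(as.logical(valid), n, nj)
  if (!is.finite(rate) || rate <= 0) stop("rate must be a positive frame rate")
  dimnames(coords) <- list(NULL, joints, c("x", "y", "z"))
  colnames(valid) <- joints
  structure(
    list(coords = coords, time = as.numeric(time), joints = as.character(joints),
         valid = valid, frames = frames, rate = as.numeric(rate),
         source = source, unit = unit),
    class = "keypoint_sequence"
  )
}

#' @export
print.keypoint_sequence <- function(x, ...) {
  cat(sprintf("<keypoint_sequence> %d frames x %d joints | %.6g fps | source=%s | unit=%s\n",
              n_frames(x), length(x$joints), x$rate, x$source, x$unit))
  cat(sprintf("  t = [%.4f, %.4f] s | %.1f%% valid\n",
              x$time[1], x$time[n_frames(x)], 100 * mean(x$valid)))
  invisible(x)
}

#' Number of frames in a keypoint sequence
#' @param seq A `keypoint_sequence`.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' @export
as.data.frame.keypoint_sequence <- function(x, ...) {
  n <- n_frames(x)
  nj <- length(x$joints)
  data.frame(
    frame = rep(x$frames, each = nj),
    time_s = rep(x$time, each = nj),
    joint = rep(x$joints, times = n),
    x = as.vector(t(x$coords[, , 1])),
    y = as.vector(t(x$coords[, , 2])),
    z = as.vector(t(x$coords[, , 3])),
    valid = as.vector(t(x$valid)),
    stringsAsFactors = FALSE
  )
}

# Shared-grid check used by fusion and metrics: same joints, same length,
# timestamps equal to within a microsecond.
check_same_grid <- function(a, b) {
  if (!identical(a$joints, b$joints)) stop("sequences have different joint sets")
  if (n_frames(a) != n_frames(b)) stop("sequences have different frame counts")
  if (max(abs(a$time - b$time)) > 1e-6) stop("sequences are not on the same time grid")
  invisible(TRUE)
}

# Matrix of jointly valid samples for two or three sequences: returns an
# n_samples x 3 coordinate matrix per sequence plus the (frame, joint) index.
jointly_valid <- function(seqs) {
  v <- Reduce(`&`, lapply(seqs, function(s) s$valid & !apply(is.na(s$coords), c(1, 2), any)))
  idx <- which(v, arr.ind = TRUE)
  mats <- lapply(seqs, function(s) {
    m <- cbind(s$coords[, , 1][v], s$coords[, , 2][v], s$coords[, , 3][v])
    colnames(m) <- c("x", "y", "z")
    m
  })
  list(mats = mats, index = idx, mask = v)
}
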