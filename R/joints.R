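#' The 12-joint limb catalog
#'
#' The canonical joint set tracked by the fusion pipeline: left/right
#' shoulder, elbow, wrist, hip, knee and ankle. Each canonical joint carries
#' its index in the depth-camera skeleton scheme and in the RGB-detector
#' landmark scheme, so that streams from the two detectors can be relabeled
#' onto a common vocabulary.
#'
#' @param path Path to a catalog CSV with columns `joint`, `depth_index`,
#'   `rgb_index`. Defaults to the catalog shipped with the package.
#' @return A data frame of class `joint_catalog` with 12 rows.
#' @export
#' @examples
#' cat <- joint_catalog()
#' cat[cat$joint == "Left Shoulder", ]
joint_catalog <- function(path = system.file("extdata", "joint_catalog.csv",
                                             package = "lightfuse")) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("joint", "depth_index", "rgb_index")
  if (!all(required %in% names(cat))) {
    stop("joint catalog must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(cat) != 12L) {
    stop("joint catalog must have exactly 12 entries, got ", nrow(cat))
  }
  if (anyDuplicated(cat$joint)) stop("duplicate canonical joint names in catalog")
  if (anyDuplicated(cat$depth_index)) stop("duplicate depth-scheme indices in catalog")
  if (anyDuplicated(cat$rgb_index)) stop("duplicate rgb-scheme indices in catalog")
  class(cat) <- c("joint_catalog", "data.frame")
  cat
}

#' Relabel raw detector keypoints onto the canonical joint vocabulary
#'
#' Detectors emit keypoints indexed by their own skeleton scheme (a depth
#' camera's numeric skeleton joints, or an RGB pose detector's landmark
#' indices). This maps those raw indices to canonical joint names and drops
#' every index that is not one of the 12 limb joints (face, hands, torso
#' midpoints and similar).
#'
#' @param raw A numeric matrix with one row per raw keypoint (3 columns,
#'   X/Y/Z) whose row names are the raw scheme indices, or a named list of
#'   3-vectors keyed by raw index.
#' @param scheme `"depth"` or `"rgb"` — which detector's index scheme the
#'   raw names use.
#' @param catalog A [joint_catalog()].
#' @return A numeric matrix (possibly 0-row) with canonical joint names as
#'   row names, rows in catalog order.
#' @export
harmonize_joints <- function(raw, scheme = c("depth", "rgb"),
                             catalog = joint_catalog()) {
  scheme <- match.arg(scheme)
  if (is.list(raw)) {
    raw <- do.call(rbind, lapply(raw, function(p) as.numeric(p)))
  }
  raw <- as.matrix(raw)
  if (ncol(raw) != 3L) stop("raw keypoints must be 3-vectors")
  idx_col <- if (scheme == "depth") catalog$depth_index else catalog$rgb_index
  raw_idx <- as.integer(rownames(raw))
  keep <- match(idx_col, raw_idx)
  present <- !is.na(keep)
  out <- raw[keep[present], , drop = FALSE]
  rownames(out) <- catalog$joint[present]
  colnames(out) <- c("x", "y", "z")
  out
}
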