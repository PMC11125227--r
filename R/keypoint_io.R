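#' Read a keypoint sequence from CSV
#'
#' The on-disk format is a UTF-8, LF-terminated CSV with header
#' `frame,time_s,joint,x,y,z,valid`, one row per (frame, joint), preceded by
#' comment lines recording the stream metadata:
#'
#' ```
#' # rate: 30
#' # source: reference
#' # unit: m
#' ```
#'
#' Every frame must contain exactly one row for each catalog joint; invalid
#' joints have `valid = FALSE` and `NA` coordinates.
#'
#' @param path Path to the CSV file.
#' @param catalog A [joint_catalog()] defining the expected joint set.
#' @return A [keypoint_sequence()].
#' @export
read_keypoint_csv <- function(path, catalog = joint_catalog()) {
  if (!file.exists(path)) stop("keypoint CSV not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list(rate = 30, source = "reference", unit = "m")
  for (ln in lines[meta_lines]) {
    m <- regmatches(ln, regexec("^#\\s*(rate|source|unit):\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  n_head <- length(meta_lines) + 1L  # comments + header line precede data
  df <- utils::read.csv(text = lines[-meta_lines], stringsAsFactors = FALSE)
  required <- c("frame", "time_s", "joint", "x", "y", "z", "valid")
  if (!identical(names(df), required)) {
    stop("malformed keypoint CSV header in ", path,
         ": expected columns ", paste(required, collapse = ","))
  }
  if (nrow(df) == 0L) stop("keypoint CSV has no data rows: ", path)

  unknown <- setdiff(unique(df$joint), catalog$joint)
  if (length(unknown)) {
    line <- n_head + which(df$joint %in% unknown)[1]
    stop("unknown joint label '", unknown[1], "' at line ", line, " of ", path)
  }
  dup <- duplicated(df[, c("frame", "joint")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate (frame, joint) pair (", df$frame[i], ", ", df$joint[i],
         ") at line ", n_head + i, " of ", path)
  }

  frames <- sort(unique(df$frame))
  n <- length(frames)
  nj <- nrow(catalog)
  for (k in seq_len(n)) {
    have <- df$joint[df$frame == frames[k]]
    missing <- setdiff(catalog$joint, have)
    if (length(missing)) {
      stop("frame ", frames[k], " is missing joint '", missing[1], "' in ", path)
    }
  }
  # one timestamp per frame, strictly increasing
  t_by_frame <- tapply(df$time_s, df$frame, function(t) {
    if (length(unique(t)) != 1L) stop("inconsistent timestamps within a frame in ", path)
    t[1]
  })
  time <- as.numeric(t_by_frame[as.character(frames)])
  if (n > 1L && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1]
    stop("non-monotone timestamps between frames ", frames[bad], " and ",
         frames[bad + 1L], " in ", path)
  }

  coords <- array(NA_real_, c(n, nj, 3))
  valid <- matrix(FALSE, n, nj)
  fi <- match(df$frame, frames)
  ji <- match(df$joint, catalog$joint)
  coords[cbind(fi, ji, 1L)] <- df$x
  coords[cbind(fi, ji, 2L)] <- df$y
  coords[cbind(fi, ji, 3L)] <- df$z
  valid[cbind(fi, ji)] <- as.logical(df$valid)
  if (any(valid & apply(is.na(coords), c(1, 2), any))) {
    stop("row marked valid but with missing coordinates in ", path)
  }
  keypoint_sequence(coords, time, catalog$joint, valid,
                    rate = as.numeric(meta$rate), source = meta$source,
                    unit = meta$unit, frames = as.integer(frames))
}

#' Write a keypoint sequence to CSV
#'
#' Inverse of [read_keypoint_csv()]: coordinates are serialized at full
#' double precision (`%.17g`) so the round trip is lossless, and the output
#' is byte-stable for a fixed input.
#'
#' @param seq A [keypoint_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_keypoint_csv <- function(seq, path) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  if (n_frames(seq) < 1L) stop("empty sequences are not serializable")
  df <- as.data.frame(seq)
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  rows <- sprintf("%d,%.17g,%s,%s,%s,%s,%s",
                  df$frame, df$time_s, df$joint,
                  num(df$x), num(df$y), num(df$z),
                  ifelse(df$valid, "TRUE", "FALSE"))
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(c(sprintf("# rate: %.17g", seq$rate),
               sprintf("# source: %s", seq$source),
               sprintf("# unit: %s", seq$unit),
               "frame,time_s,joint,x,y,z,valid",
               rows), con, sep = "\n")
  invisible(path)
}

#' Downsample a keypoint sequence to a target frame rate
#'
#' Used to synchronize a high-rate reference stream (e.g. a 100 Hz
#' motion-capture system) with 30 Hz camera streams. Output timestamps lie
#' on the grid `t0 + k / target_rate`; each output frame copies the input
#' frame whose timestamp is nearest to the grid point, with ties broken
#' toward the earlier frame. No interpolation is performed.
#'
#' @param seq A [keypoint_sequence()].
#' @param target_rate Target rate in fps; must not exceed `seq$rate`.
#' @return A [keypoint_sequence()] at `target_rate`.
#' @export
resample_to_rate <- function(seq, target_rate) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  if (!is.finite(target_rate) || target_rate <= 0) {
    stop("target_rate must be positive")
  }
  if (target_rate > seq$rate) {
    stop("upsampling unsupported: target_rate (", target_rate,
         ") exceeds source rate (", seq$rate, ")")
  }
  t0 <- seq$time[1]
  span <- seq$time[n_frames(seq)] - t0
  k_max <- floor(span * target_rate + 1e-9)
  grid <- t0 + (0:k_max) / target_rate
  # nearest input frame per grid point; ties toward the earlier frame
  pick <- vapply(grid, function(g) {
    d <- abs(seq$time - g)
    which(d <= min(d) + 1e-12)[1]
  }, integer(1))
  keypoint_sequence(seq$coords[pick, , , drop = FALSE], grid, seq$joints,
                    seq$valid[pick, , drop = FALSE], rate = target_rate,
                    source = seq$source, unit = seq$unit)
}
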