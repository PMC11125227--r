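# Run code with a temporary RNG seed, restoring the caller's RNG state, so
# generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic rehabilitation scene
#'
#' Describes the stated world every synthetic fixture is generated from: a
#' smooth 12-joint ground-truth trajectory mimicking a lower-limb
#' rehabilitation exercise, a depth-camera-like stream with spatial jitter
#' and heavy-tailed spikes on the knees and ankles, an RGB-detector-like
#' stream whose noise grows as the scene darkens, and a sweep of
#' illumination gains.
#'
#' Noise magnitudes are expressed in pixels at the nominal camera geometry
#' (they are converted to meters through the focal length and the subject's
#' nominal depth) and default to values that place single-source joint
#' accuracies at the 8 px threshold in the 60-95% band typical of
#' marker-free pose detectors: depth jitter sigma 2 px with 2% spike
#' probability at 15 px scale, RGB base noise 1 px growing by a darkness
#' factor k = 8 at full darkness.
#'
#' @param n_frames Number of frames (default 300, i.e. 10 s at 30 fps).
#' @param rate Frame rate in fps (default 30).
#' @param motion `"gait_balance"` (large periodic leg excursions) or
#'   `"gravity_shift"` (smaller weight-transfer sway).
#' @param depth_noise Named numeric: `sigma` (px), `spike_prob`,
#'   `spike_scale` (px).
#' @param rgb_noise Named numeric: `sigma` (px at full brightness), `k`
#'   (darkness growth factor).
#' @param gains Illumination gain sweep (default 5 levels from 1 to 0.3).
#' @param seed Integer RNG seed; a fixed seed makes every generated
#'   artifact identical.
#' @param calib A [camera_calibration()] giving the nominal camera
#'   geometry.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_frames = 300, rate = 30,
                       motion = c("gait_balance", "gravity_shift"),
                       depth_noise = c(sigma = 2, spike_prob = 0.02, spike_scale = 15),
                       rgb_noise = c(sigma = 1, k = 8),
                       gains = c(1, 0.8, 0.6, 0.45, 0.3),
                       seed = 1,
                       calib = camera_calibration(fx = 500, fy = 500,
                                                  dx = 320, dy = 240)) {
  motion <- match.arg(motion)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (any(depth_noise[c("sigma", "spike_scale")] < 0) || rgb_noise["sigma"] < 0) {
    stop("noise scales must be non-negative")
  }
  sp <- depth_noise["spike_prob"]
  if (sp < 0 || sp > 1) stop("spike_prob must lie in [0, 1]")
  if (any(gains <= 0 | gains > 1)) stop("gains must lie in (0, 1]")
  structure(list(n_frames = as.integer(n_frames), rate = rate, motion = motion,
                 depth_noise = depth_noise, rgb_noise = rgb_noise,
                 gains = gains, seed = as.integer(seed), calib = calib),
            class = "scene_spec")
}

# Pixel-to-meter conversion at the subject's nominal depth.
px_to_m <- function(spec, z_nominal = 2.2) z_nominal / spec$calib$fx

# Rotation about the camera x-axis (sagittal plane).
rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
}

#' Generate a smooth ground-truth keypoint trajectory
#'
#' Stands in for a marker-based motion-capture reference. The skeleton is a
#' kinematic chain: a pelvis that sways smoothly, rigid shoulder/hip
#' offsets, and limbs that rotate about their parent joints with
#' band-limited sinusoid joint angles (fundamental 0.5 Hz plus a second
#' harmonic, phases drawn once from the seed). Because limbs move by
#' rotation, bone lengths are constant over time by construction. The
#' `gait_balance` motif uses large hip/knee angle amplitudes (high leg
#' lifts); `gravity_shift` uses smaller amplitudes with more lateral sway.
#' Coordinates are meters in the camera frame, subject roughly 2.2 m from
#' the camera.
#'
#' @param spec A [scene_spec()].
#' @return A reference [keypoint_sequence()].
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$n_frames
  if (n < 2) stop("n_frames must be >= 2")
  t <- (seq_len(n) - 1) / spec$rate
  catalog <- joint_catalog()
  f0 <- 0.5  # exercise fundamental, Hz

  amp <- switch(spec$motion,
    gait_balance = list(hip = 0.55, knee = 0.85, shoulder = 0.45, elbow = 0.30,
                        sway = c(0.03, 0.02, 0.02)),
    gravity_shift = list(hip = 0.20, knee = 0.30, shoulder = 0.15, elbow = 0.10,
                         sway = c(0.08, 0.01, 0.03)))

  ph <- with_seed(spec$seed, stats::runif(8, 0, 2 * pi))

  # band-limited angle track: fundamental + second harmonic
  angle <- function(a, phase, lag = 0) {
    a * (sin(2 * pi * f0 * t + phase + lag) + 0.3 * sin(4 * pi * f0 * t + 2 * phase + lag))
  }

  pelvis <- cbind(amp$sway[1] * sin(2 * pi * 0.25 * t + ph[7]),
                  amp$sway[2] * sin(2 * pi * 0.35 * t + ph[8]),
                  2.2 + amp$sway[3] * sin(2 * pi * 0.3 * t))
  trunk <- c(0, -0.45, 0)  # camera y points down: shoulders above hips

  hip_off <- list(`Left Hip` = c(-0.10, 0, 0), `Right Hip` = c(0.10, 0, 0))
  sho_off <- list(`Left Shoulder` = c(-0.18, 0, 0), `Right Shoulder` = c(0.18, 0, 0))
  L <- list(thigh = 0.40, shank = 0.40, upper = 0.28, fore = 0.25)
  down <- c(0, 1, 0)  # +y is down in the camera frame

  sides <- list(
    list(tag = "Left", lag = 0, ph_leg = ph[1], ph_arm = ph[3]),
    list(tag = "Right", lag = pi, ph_leg = ph[2], ph_arm = ph[4])
  )

  coords <- array(NA_real_, c(n, 12, 3))
  dimnames(coords) <- list(NULL, catalog$joint, c("x", "y", "z"))
  setj <- function(name, mat) coords[, name, ] <<- mat

  for (s in sides) {
    hip <- pelvis + matrix(hip_off[[paste(s$tag, "Hip")]], n, 3, byrow = TRUE)
    sho <- pelvis + matrix(trunk + sho_off[[paste(s$tag, "Shoulder")]], n, 3, byrow = TRUE)
    th_hip <- angle(amp$hip, s$ph_leg, s$lag)
    th_knee <- pmax(angle(amp$knee, s$ph_leg + 0.6, s$lag), 0)  # knees don't hyperextend
    th_sho <- angle(amp$shoulder, s$ph_arm, s$lag)
    th_elb <- angle(amp$elbow, s$ph_arm + 0.4, s$lag)
    knee <- hip + t(vapply(seq_len(n), function(i) L$thigh * rot_x(th_hip[i]) %*% down,
                           numeric(3)))
    ankle <- knee + t(vapply(seq_len(n), function(i)
      L$shank * rot_x(th_hip[i] + th_knee[i]) %*% down, numeric(3)))
    elb <- sho + t(vapply(seq_len(n), function(i) L$upper * rot_x(th_sho[i]) %*% down,
                          numeric(3)))
    wri <- elb + t(vapply(seq_len(n), function(i)
      L$fore * rot_x(th_sho[i] + th_elb[i]) %*% down, numeric(3)))
    setj(paste(s$tag, "Hip"), hip)
    setj(paste(s$tag, "Shoulder"), sho)
    setj(paste(s$tag, "Knee"), knee)
    setj(paste(s$tag, "Ankle"), ankle)
    setj(paste(s$tag, "Elbow"), elb)
    setj(paste(s$tag, "Wrist"), wri)
  }
  keypoint_sequence(coords, t, catalog$joint, rate = spec$rate,
                    source = "reference", unit = "m")
}

#' Simulate a depth-camera-like keypoint stream
#'
#' Adds the characteristic depth-detector degradation to the ground truth:
#' i.i.d. Gaussian jitter on every coordinate plus heavy-tailed Bernoulli
#' spikes concentrated on the knees and ankles — the joints where
#' skeletal-tracking depth cameras visibly jump during leg motion. The
#' noise is independent of illumination.
#'
#' @param truth A reference [keypoint_sequence()] from [generate_truth()].
#' @param spec The [scene_spec()] that produced it.
#' @return A [keypoint_sequence()] labeled `depth_camera`.
#' @export
simulate_depth_stream <- function(truth, spec) {
  stopifnot(inherits(truth, "keypoint_sequence"), inherits(spec, "scene_spec"))
  n <- n_frames(truth)
  nj <- length(truth$joints)
  scale <- px_to_m(spec)
  sigma <- spec$depth_noise[["sigma"]] * scale
  spike_scale <- spec$depth_noise[["spike_scale"]] * scale
  spike_prob <- spec$depth_noise[["spike_prob"]]
  lower_limb <- truth$joints %in% c("Left Knee", "Right Knee",
                                    "Left Ankle", "Right Ankle")
  coords <- with_seed(spec$seed + 1L, {
    out <- truth$coords + array(stats::rnorm(n * nj * 3, 0, sigma), c(n, nj, 3))
    if (spike_prob > 0 && spike_scale > 0) {
      hit <- matrix(stats::runif(n * nj) < spike_prob, n, nj)
      hit[, !lower_limb] <- FALSE
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx) > 0) for (d in 1:3) {
        out[cbind(idx, d)] <- out[cbind(idx, d)] +
          stats::rnorm(nrow(idx), 0, spike_scale)
      }
    }
    out
  })
  keypoint_sequence(coords, truth$time, truth$joints, truth$valid,
                    rate = truth$rate, source = "depth_camera", unit = "m")
}

# Relative scene brightness of a gain level: brightness of the canonical
# gradient test image relit at that gain, normalized by its full-light
# brightness. Deterministic, monotone increasing in gain.
relative_brightness <- function(gain, t = 0.9) {
  img <- make_test_image("gradient")
  b1 <- mean_brightness(img)
  mean_brightness(simulate_illumination(img, illumination_params(gain, t))) / b1
}

#' Simulate an RGB-detector-like keypoint stream under a gain level
#'
#' The RGB detector is stable in good light but degrades as the scene
#' darkens: coordinates are the truth plus Gaussian noise with
#' `sigma = sigma_base * (1 + k * (1 - b(gain)))`, where `b(gain)` is the
#' relative scene brightness of the gain level (1 at full light). Under the
#' default spec this stream is less noisy than the depth stream at gain 1
#' and noisier at low gain — the crossover the adaptive weight model must
#' capture.
#'
#' @param truth A reference [keypoint_sequence()].
#' @param gain Illumination inverse gain in `(0, 1]`.
#' @param spec The [scene_spec()].
#' @return A [keypoint_sequence()] labeled `rgb_detector`.
#' @export
simulate_rgb_stream <- function(truth, gain, spec) {
  stopifnot(inherits(truth, "keypoint_sequence"), inherits(spec, "scene_spec"))
  if (gain <= 0 || gain > 1) stop("gain must lie in (0, 1]")
  n <- n_frames(truth)
  nj <- length(truth$joints)
  rel <- relative_brightness(gain)
  sigma <- spec$rgb_noise[["sigma"]] * (1 + spec$rgb_noise[["k"]] * (1 - rel)) *
    px_to_m(spec)
  coords <- with_seed(spec$seed + 2L + round(1000 * gain), {
    truth$coords + array(stats::rnorm(n * nj * 3, 0, sigma), c(n, nj, 3))
  })
  keypoint_sequence(coords, truth$time, truth$joints, truth$valid,
                    rate = truth$rate, source = "rgb_detector", unit = "m")
}

#' Deterministic synthetic test images
#'
#' Small sRGB patterns used by the illumination and image-metric tests:
#' a horizontal `gradient` spanning 0 to 1, an 8 px `checker` of two tones,
#' or a uniform `gray`.
#'
#' @param kind `"gradient"`, `"checker"` or `"gray"`.
#' @param size Height/width in pixels, length-2 or scalar (default 64).
#' @param level Gray level for `kind = "gray"` (default 0.5).
#' @param tones The two checker tones (default 0.25 and 0.75).
#' @return An sRGB [image_buffer()].
#' @export
make_test_image <- function(kind = c("gradient", "checker", "gray"),
                            size = 64, level = 0.5, tones = c(0.25, 0.75)) {
  kind <- match.arg(kind)
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 1)) stop("size must be positive")
  h <- size[1]; w <- size[2]
  plane <- switch(kind,
    gradient = matrix(rep(seq(0, 1, length.out = w), each = h), h, w),
    checker = {
      tile <- outer(ceiling(seq_len(h) / 8), ceiling(seq_len(w) / 8), `+`) %% 2
      matrix(tones[tile + 1], h, w)
    },
    gray = matrix(level, h, w))
  image_buffer(plane, "srgb")
}

#' Generate a complete synthetic scene bundle on disk
#'
#' Writes everything one illumination-adaptation experiment needs: the
#' ground-truth CSV, the depth-stream CSV, one RGB-stream CSV and one
#' relit PNG per gain level, and a YAML manifest recording files, gains,
#' seed and parameters. Fully reproducible from the spec's seed.
#'
#' @param spec A [scene_spec()].
#' @param dir Output directory (created if needed).
#' @return The manifest as a list, invisibly; side effect: files in `dir`.
#' @export
make_scene <- function(spec, dir) {
  stopifnot(inherits(spec, "scene_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_truth(spec)
  depth <- simulate_depth_stream(truth, spec)
  write_keypoint_csv(truth, file.path(dir, "truth.csv"))
  write_keypoint_csv(depth, file.path(dir, "depth.csv"))
  base_img <- make_test_image("gradient")
  files <- list(truth = "truth.csv", depth = "depth.csv", rgb = list(),
                images = list())
  for (g in spec$gains) {
    tag <- gsub("\\.", "_", sprintf("%.2f", g))
    rgb <- simulate_rgb_stream(truth, g, spec)
    rgb_file <- sprintf("rgb_gain%s.csv", tag)
    img_file <- sprintf("img_gain%s.png", tag)
    write_keypoint_csv(rgb, file.path(dir, rgb_file))
    write_image_png(simulate_illumination(base_img, illumination_params(g)),
                    file.path(dir, img_file))
    files$rgb[[sprintf("%.2f", g)]] <- rgb_file
    files$images[[sprintf("%.2f", g)]] <- img_file
  }
  manifest <- list(
    seed = spec$seed, rate = spec$rate, n_frames = spec$n_frames,
    motion = spec$motion, gains = as.numeric(spec$gains),
    depth_noise = as.list(spec$depth_noise), rgb_noise = as.list(spec$rgb_noise),
    calibration = list(fx = spec$calib$fx, fy = spec$calib$fy,
                       dx = spec$calib$dx, dy = spec$calib$dy, s = spec$calib$s,
                       R = as.numeric(t(spec$calib$R)), T = spec$calib$T),
    files = files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
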