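# Gamma-curve constants used throughout: piecewise linear below the
# breakpoint, power law above it. The linear-domain breakpoint is 0.0031,
# so the corresponding sRGB-domain breakpoint is 12.92 * 0.0031.
.GAMMA_LIN_BREAK <- 0.0031
.GAMMA_SRGB_BREAK <- 12.92 * 0.0031

#' Construct an image buffer
#'
#' A real-valued H x W x 3 pixel array in `[0, 1]`, tagged with the color
#' space its values live in (`"srgb"` display values or `"linear"` light).
#' Every operation checks the tag and refuses mismatched spaces, so linear
#' math is never applied to gamma-encoded values by accident.
#'
#' @param pixels Numeric array H x W x 3 (a single-channel H x W matrix is
#'   replicated to 3 channels). Values are clipped to `[0, 1]`.
#' @param space `"srgb"` or `"linear"`.
#' @return An object of class `image_buffer`.
#' @export
image_buffer <- function(pixels, space = c("srgb", "linear")) {
  space <- match.arg(space)
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be an H x W x 3 array")
  }
  if (any(!is.finite(pixels))) stop("non-finite pixel values")
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  structure(pixels, space = space, class = "image_buffer")
}

img_space <- function(img) attr(img, "space")

check_space <- function(img, expected) {
  if (!inherits(img, "image_buffer")) stop("expected an image_buffer")
  if (img_space(img) != expected) {
    stop("expected a ", expected, "-space image, got ", img_space(img))
  }
  invisible(TRUE)
}

#' @export
print.image_buffer <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_buffer> %d x %d x 3 [%s], range [%.4f, %.4f]\n",
              d[1], d[2], img_space(x), min(x), max(x)))
  invisible(x)
}

#' Convert sRGB display values to linear light
#'
#' Exact piecewise inverse of [linear_to_srgb()]: `C / 12.92` below the
#' sRGB-domain breakpoint `12.92 * 0.0031`, `((C + 0.055) / 1.055)^2.4`
#' above it.
#'
#' @param img An sRGB [image_buffer()].
#' @return A linear-space [image_buffer()].
#' @export
srgb_to_linear <- function(img) {
  check_space(img, "srgb")
  C <- unclass(img)
  f <- ifelse(C < .GAMMA_SRGB_BREAK, C / 12.92, ((C + 0.055) / 1.055)^2.4)
  image_buffer(f, "linear")
}

#' Convert linear light to sRGB display values
#'
#' Piecewise gamma encoding: `12.92 f` for `f < 0.0031`,
#' `1.055 f^(1/2.4) - 0.055` for `f >= 0.0031` (the upper branch evaluates
#' to exactly 1 at `f = 1`).
#'
#' @param img A linear-space [image_buffer()].
#' @return An sRGB [image_buffer()].
#' @export
linear_to_srgb <- function(img) {
  check_space(img, "linear")
  f <- unclass(img)
  C <- ifelse(f < .GAMMA_LIN_BREAK, 12.92 * f, 1.055 * f^(1 / 2.4) - 0.055)
  image_buffer(C, "srgb")
}

#' Illumination simulator parameters
#'
#' @param x Inverse gain in `(0, 1]`; 1 leaves the image unchanged, smaller
#'   values darken it.
#' @param t Highlight threshold in `(0, 1)`: gains above `t` engage the
#'   highlight-preserving blend (default 0.9).
#' @return An object of class `illumination_params`.
#' @export
illumination_params <- function(x, t = 0.9) {
  if (!is.finite(x) || x <= 0 || x > 1) stop("inverse gain x must lie in (0, 1]")
  if (!is.finite(t) || t <= 0 || t >= 1) stop("highlight threshold t must lie in (0, 1)")
  structure(list(x = x, t = t), class = "illumination_params")
}

#' Highlight-preserving inverse gain in linear space
#'
#' Plain inverse gain multiplies every linear channel value `g` by `x`,
#' which dims highlights as aggressively as shadows. This operator instead
#' blends the plainly gained value with the original using a gain-dependent
#' blend weight `alpha = (max(x - t, 0) / (1 - t))^2`:
#'
#'   `f = max(x g, (1 - alpha) x g + alpha g)`
#'
#' For `x <= t` the blend weight is 0 and the map is exactly linear
#' (`f = x g`); as `x` approaches 1 the blend weight approaches 1 and the
#' image is left untouched, so bright detail survives mild darkening. The
#' output never falls below the plain gain `x g` and never exceeds
#' `max(x g, g)`, and is monotone non-decreasing in `g`.
#'
#' @param img A linear-space [image_buffer()].
#' @param params An [illumination_params()].
#' @return A linear-space [image_buffer()].
#' @export
safe_inverse_gain <- function(img, params) {
  check_space(img, "linear")
  stopifnot(inherits(params, "illumination_params"))
  g <- unclass(img)
  alpha <- (max(params$x - params$t, 0) / (1 - params$t))^2
  f <- pmax(params$x * g, (1 - alpha) * params$x * g + alpha * g)
  image_buffer(f, "linear")
}

#' Simulate an illumination change on an sRGB image
#'
#' Full relighting composition: decode sRGB to linear light, apply the
#' highlight-preserving inverse gain, re-encode to sRGB. With `x = 1` the
#' composition is the identity to within gamma round-trip error.
#'
#' @param img An sRGB [image_buffer()].
#' @param params An [illumination_params()].
#' @return A darkened sRGB [image_buffer()].
#' @export
simulate_illumination <- function(img, params) {
  linear_to_srgb(safe_inverse_gain(srgb_to_linear(img), params))
}

#' Mean scene brightness of an sRGB image
#'
#' The scalar lighting condition driving the sigmoid weight model: the
#' image is linearized and the Rec. 709 relative luminance
#' `0.2126 R + 0.7152 G + 0.0722 B` is averaged over all pixels.
#'
#' @param img An sRGB [image_buffer()].
#' @return Mean linear luminance in `[0, 1]`.
#' @export
mean_brightness <- function(img) {
  check_space(img, "srgb")
  if (length(img) == 0L) stop("empty image")
  f <- unclass(srgb_to_linear(img))
  mean(0.2126 * f[, , 1] + 0.7152 * f[, , 2] + 0.0722 * f[, , 3])
}

#' Read an 8-bit PNG into an sRGB image buffer
#' @param path PNG file path.
#' @return An sRGB [image_buffer()].
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  image_buffer(px, "srgb")
}

#' Write an sRGB image buffer to an 8-bit PNG
#' @param img An sRGB [image_buffer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  check_space(img, "srgb")
  px <- round(unclass(img) * 255) / 255  # quantize to the 8-bit grid
  png::writePNG(px, path)
  invisible(path)
}
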