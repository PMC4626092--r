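#' @useDynLib nvuquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# round half-up (deterministic across platforms, unlike base round's
# banker's rounding) and clamp to the 8-bit range
round_half_up <- function(x) floor(x + 0.5)
round_clamp8 <- function(x) pmin(pmax(round_half_up(x), 0), 255)

as_matrix_input <- function(img, channel = NULL) {
  m <- get_channel(img, channel)
  if (length(m) == 0L) stop("empty image")
  if (!all(is.finite(m))) stop("non-finite intensities")
  m
}

# In 8-bit mode every stage consumes and emits integers in [0, 255], the way
# an ImageJ macro running on an 8-bit image would.
prep8 <- function(m, eight_bit) if (eight_bit) round_clamp8(m) else m
post8 <- function(m, eight_bit) if (eight_bit) round_clamp8(m) else m

#' Filter-stack parameters
#'
#' Bundles the parameters of the vessel-segmentation filter stack:
#' Gaussian blur sigma, variance and median radii, the subtract constant
#' (`"auto"` = the standard deviation of the current image, the
#' conventional reading of a sigma-valued subtract stage), the multiply
#' factor, and whether to emulate 8-bit arithmetic (round half-up + clamp
#' to 0..255 after every stage).
#'
#' @param gaussian_sigma blur sigma in px (default 2).
#' @param variance_radius local-variance radius in px (default 5).
#' @param median_radius median radius in px (default 3).
#' @param subtract_constant `"auto"` or a non-negative intensity.
#' @param multiply_factor positive multiplier (default 255; with 8-bit
#'   integer inputs this binarizes the image).
#' @param eight_bit_mode logical; emulate 8-bit semantics (default TRUE).
#' @return a `filter_params` list.
#' @export
filter_params <- function(gaussian_sigma = 2, variance_radius = 5,
                          median_radius = 3, subtract_constant = "auto",
                          multiply_factor = 255, eight_bit_mode = TRUE) {
  stopifnot(gaussian_sigma > 0, variance_radius >= 1, median_radius >= 1,
            multiply_factor > 0)
  if (!identical(subtract_constant, "auto")) {
    if (!is.numeric(subtract_constant) || subtract_constant < 0)
      stop("'subtract_constant' must be \"auto\" or a non-negative number")
  }
  structure(list(gaussian_sigma = gaussian_sigma,
                 variance_radius = variance_radius,
                 median_radius = median_radius,
                 subtract_constant = subtract_constant,
                 multiply_factor = multiply_factor,
                 eight_bit_mode = isTRUE(eight_bit_mode)),
            class = "filter_params")
}

#' Rescale an image linearly to the 8-bit range
#'
#' Maps the minimum intensity to 0 and the maximum to 255 (linear in
#' between, rounded half-up). A constant image maps to all zeros.
#'
#' @param img micrograph channel or numeric matrix.
#' @param channel optional channel selector.
#' @return matrix of integers in 0..255 (same shape).
#' @export
normalize_to_8bit <- function(img, channel = NULL) {
  m <- as_matrix_input(img, channel)
  rng <- range(m)
  if (rng[1L] == rng[2L]) return(matrix(0, nrow(m), ncol(m)))
  round_half_up((m - rng[1L]) / (rng[2L] - rng[1L]) * 255)
}

#' Gaussian blur
#'
#' Discrete Gaussian convolution, kernel truncated at 3 sigma, replicate
#' edge padding.
#'
#' @param img matrix or micrograph channel.
#' @param sigma positive blur radius in px.
#' @param eight_bit round half-up and clamp to 0..255 (default TRUE).
#' @param channel optional channel selector.
#' @export
gaussian_blur <- function(img, sigma = 2, eight_bit = TRUE, channel = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  m <- prep8(as_matrix_input(img, channel), eight_bit)
  post8(cpp_gaussian_blur(m, sigma), eight_bit)
}

#' Sobel gradient magnitude ("Find edges")
#'
#' Per pixel sqrt(Gx^2 + Gy^2) with the standard 3x3 Sobel kernels and
#' replicate padding; clamped to 255 in 8-bit mode.
#'
#' @inheritParams gaussian_blur
#' @export
sobel_magnitude <- function(img, eight_bit = TRUE, channel = NULL) {
  m <- as_matrix_input(img, channel)
  if (nrow(m) < 3L || ncol(m) < 3L) stop("image must be at least 3x3")
  m <- prep8(m, eight_bit)
  post8(cpp_sobel_magnitude(m), eight_bit)
}

#' Local (neighbourhood) variance filter
#'
#' Population variance over the circular neighbourhood of offsets with
#' Euclidean distance <= radius, replicate padding.
#'
#' @inheritParams gaussian_blur
#' @param radius neighbourhood radius in px (>= 1).
#' @export
local_variance <- function(img, radius = 5, eight_bit = TRUE, channel = NULL) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("'radius' must be >= 1")
  m <- prep8(as_matrix_input(img, channel), eight_bit)
  post8(cpp_local_variance(m, radius), eight_bit)
}

#' Local median filter
#'
#' Median over the same circular neighbourhood as [local_variance()];
#' even-sized neighbourhoods take the mean of the two central order
#' statistics (rounded in 8-bit mode).
#'
#' @inheritParams local_variance
#' @export
local_median <- function(img, radius = 3, eight_bit = TRUE, channel = NULL) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("'radius' must be >= 1")
  m <- prep8(as_matrix_input(img, channel), eight_bit)
  post8(cpp_local_median(m, radius), eight_bit)
}

#' Saturating subtraction
#'
#' `max(v - c, 0)` per pixel. With `c = "auto"` the constant is the sample
#' standard deviation of the image's intensities, computed on the image as
#' passed in (after 8-bit rounding when in 8-bit mode).
#'
#' @inheritParams gaussian_blur
#' @param c non-negative constant, or `"auto"`.
#' @return for `"auto"`, the resolved constant is attached as attribute
#'   `"constant_used"`.
#' @export
subtract_saturate <- function(img, c = "auto", eight_bit = TRUE,
                              channel = NULL) {
  m <- prep8(as_matrix_input(img, channel), eight_bit)
  if (identical(c, "auto")) {
    c <- stats::sd(as.numeric(m))
    if (is.na(c)) c <- 0  # single-pixel image
  }
  if (!is.numeric(c) || length(c) != 1L || c < 0)
    stop("'c' must be \"auto\" or a non-negative scalar")
  out <- post8(pmax(m - c, 0), eight_bit)
  attr(out, "constant_used") <- c
  out
}

#' Saturating multiplication
#'
#' `min(v * factor, 255)` per pixel. With factor 255 on an 8-bit integer
#' image this binarizes: 0 stays 0, anything >= 1 saturates to 255.
#'
#' @inheritParams gaussian_blur
#' @param factor positive multiplier.
#' @export
multiply_saturate <- function(img, factor = 255, eight_bit = TRUE,
                              channel = NULL) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("'factor' must be a positive scalar")
  m <- prep8(as_matrix_input(img, channel), eight_bit)
  post8(pmin(m * factor, 255), eight_bit)
}

#' 8-bit inversion
#'
#' `255 - v` per pixel; input values must already lie in 0..255.
#'
#' @inheritParams gaussian_blur
#' @export
invert8 <- function(img, channel = NULL) {
  m <- as_matrix_input(img, channel)
  if (any(m < 0 | m > 255)) stop("invert8 requires values in [0, 255]")
  255 - m
}
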