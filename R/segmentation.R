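#' Connected-component particle analysis
#'
#' Labels 8-connected foreground components of a binary mask and tabulates
#' per-particle area, centroid and bounding box, discarding components
#' outside `[min_area, max_area]` (px^2). Mirrors ImageJ's "Analyze
#' Particles" defaults (8-connectivity, no circularity filter).
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param min_area minimum particle area in px^2 (default 0).
#' @param max_area maximum particle area in px^2 (default Inf).
#' @param pixel_size micrometres per pixel, used for the um^2 area column.
#' @return a `particle_table`: list with `particles` (data.frame: label,
#'   area_px2, area_um2, centroid_row, centroid_col, bbox_* columns),
#'   `particle_count`, `total_area` (px^2) and `percent_area` (0..100).
#' @export
analyze_particles <- function(mask, min_area = 0, max_area = Inf,
                              pixel_size = 1.0) {
  stopifnot(is.matrix(mask), min_area >= 0, max_area >= min_area)
  mask <- mask != 0
  lab <- cpp_label8(mask)
  npx <- length(mask)
  if (max(lab) == 0L) {
    pt <- data.frame(label = integer(), area_px2 = numeric(),
                     area_um2 = numeric(), centroid_row = numeric(),
                     centroid_col = numeric(), bbox_rmin = integer(),
                     bbox_rmax = integer(), bbox_cmin = integer(),
                     bbox_cmax = integer())
    return(structure(list(particles = pt, particle_count = 0L,
                          total_area = 0, percent_area = 0),
                     class = "particle_table"))
  }
  idx <- which(lab > 0L)
  lv <- lab[idx]
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  area <- tabulate(lv)
  keep <- which(area >= min_area & area <= max_area)
  pt <- data.frame(
    label = seq_along(keep),
    area_px2 = area[keep],
    area_um2 = area[keep] * pixel_size^2,
    centroid_row = vapply(keep, function(k) mean(rows[lv == k]), 0),
    centroid_col = vapply(keep, function(k) mean(cols[lv == k]), 0),
    bbox_rmin = vapply(keep, function(k) min(rows[lv == k]), 0L),
    bbox_rmax = vapply(keep, function(k) max(rows[lv == k]), 0L),
    bbox_cmin = vapply(keep, function(k) min(cols[lv == k]), 0L),
    bbox_cmax = vapply(keep, function(k) max(cols[lv == k]), 0L))
  total <- sum(pt$area_px2)
  structure(list(particles = pt, particle_count = nrow(pt),
                 total_area = total, percent_area = 100 * total / npx),
            class = "particle_table")
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("particle_table: %d particles, total area %g px^2 (%.3f%%)\n",
              x$particle_count, x$total_area, x$percent_area))
  invisible(x)
}

#' Automated vessel segmentation
#'
#' The in-house ImageJ-macro style pipeline for vessel area: rescale to
#' 8-bit, Gaussian blur (2 px), Sobel edge magnitude, local variance
#' (5 px), median (3 px), subtract the image's own standard deviation,
#' multiply by 255 (binarize by saturation), invert, and run particle
#' analysis. Foreground is the set of pixels equal to 0 after inversion
#' (255 before it).
#'
#' @param img micrograph or numeric matrix (single channel).
#' @param params a [filter_params()] object.
#' @param min_area minimum particle area retained, px^2 (default 25).
#' @param max_area maximum particle area retained (default Inf).
#' @param channel channel selector for multi-channel images.
#' @param pixel_size um/px; taken from the micrograph when available.
#' @param keep_stages if TRUE, all intermediate stage images are returned
#'   in `$stages` for debugging.
#' @return a `segmentation_result`: list with `mask` (logical matrix),
#'   `particles` (particle_table), `area_fraction` (retained area / image
#'   area, in 0..1) and `params_used` (including the resolved subtract
#'   constant `sigma_used`).
#' @export
segment_vessels <- function(img, params = filter_params(), min_area = 25,
                            max_area = Inf, channel = NULL, pixel_size = NULL,
                            keep_stages = FALSE) {
  if (inherits(img, "micrograph") && is.null(pixel_size))
    pixel_size <- img$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1.0
  m <- as_matrix_input(img, channel)
  eb <- params$eight_bit_mode

  stages <- list()
  x <- normalize_to_8bit(m)
  if (keep_stages) stages$normalized <- x
  x <- gaussian_blur(x, params$gaussian_sigma, eight_bit = eb)
  if (keep_stages) stages$blurred <- x
  x <- sobel_magnitude(x, eight_bit = eb)
  if (keep_stages) stages$edges <- x
  x <- local_variance(x, params$variance_radius, eight_bit = eb)
  if (keep_stages) stages$variance <- x
  x <- local_median(x, params$median_radius, eight_bit = eb)
  if (keep_stages) stages$median <- x
  x <- subtract_saturate(x, params$subtract_constant, eight_bit = eb)
  sigma_used <- attr(x, "constant_used")
  if (is.null(sigma_used)) sigma_used <- params$subtract_constant
  if (keep_stages) stages$subtracted <- x
  x <- multiply_saturate(x, params$multiply_factor, eight_bit = eb)
  if (keep_stages) stages$multiplied <- x
  if (!eb) x <- round_clamp8(x)  # inversion is defined on the 8-bit range
  inv <- invert8(x)
  if (keep_stages) stages$inverted <- inv

  mask <- inv == 0
  particles <- analyze_particles(mask, min_area = min_area,
                                 max_area = max_area,
                                 pixel_size = pixel_size)
  # retained mask: drop pixels of filtered-out components
  if (particles$particle_count > 0) {
    lab <- cpp_label8(mask)
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_area & areas <= max_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  } else {
    mask <- matrix(FALSE, nrow(mask), ncol(mask))
  }
  pu <- params
  pu$sigma_used <- sigma_used
  pu$min_area <- min_area
  pu$max_area <- max_area
  out <- list(mask = mask, particles = particles,
              area_fraction = particles$total_area / length(mask),
              params_used = pu)
  if (keep_stages) out$stages <- stages
  structure(out, class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation_result: %d particles, area fraction %.4f (sigma %.2f)\n",
    x$particles$particle_count, x$area_fraction, x$params_used$sigma_used))
  invisible(x)
}

#' Validate automated area fractions against a reference
#'
#' Ordinary least-squares regression of the automated measurements on the
#' reference (ground truth or manual tracing), the design used to validate
#' automated vessel segmentation against independent manual tracing.
#'
#' @param auto numeric vector of automated area fractions.
#' @param reference numeric vector of reference fractions (same length).
#' @return list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation) and `p_value` (two-sided, zero-slope null).
#' @export
validate_against_reference <- function(auto, reference) {
  stopifnot(length(auto) == length(reference), length(auto) >= 3)
  if (stats::sd(reference) == 0)
    stop("degenerate fit: reference values are constant")
  fit <- stats::lm(auto ~ reference)
  cf <- stats::coef(fit)
  sm <- summary(fit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2L, 4L]))
}
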