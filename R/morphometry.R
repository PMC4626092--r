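#' Percent area of a stain above a fixed threshold
#'
#' Fraction of pixels with intensity strictly greater than the threshold.
#' The same threshold must be applied to every image of an experiment;
#' use [pooled_otsu()] to derive one from the control group and freeze it.
#'
#' @param img micrograph channel or matrix, normalized to 8-bit.
#' @param threshold intensity threshold in `[0, 255]`.
#' @param channel optional channel selector.
#' @return proportion of above-threshold pixels, in `[0, 1]`.
#' @export
percent_area <- function(img, threshold, channel = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255)
    stop("'threshold' must be a single value in [0, 255]")
  m <- as_matrix_input(img, channel)
  mean(m > threshold)
}

#' Otsu threshold from pooled 8-bit intensities
#'
#' Computes Otsu's between-class-variance-maximizing threshold on the
#' pooled histogram of one or more images. Intended use: compute once on
#' the control group, then apply the frozen value to the whole experiment
#' ("same threshold criteria for all the pictures").
#'
#' @param imgs a matrix, micrograph, or list of them.
#' @param channel channel selector applied to each image.
#' @return an integer threshold in 0..254.
#' @export
pooled_otsu <- function(imgs, channel = NULL) {
  if (!is.list(imgs) || inherits(imgs, "micrograph")) imgs <- list(imgs)
  v <- unlist(lapply(imgs, function(x)
    as.numeric(round_clamp8(as_matrix_input(x, channel)))))
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  which.max(sb2[1:255]) - 1L
}

# Weighted step length of a 1-px skeleton: each 8-adjacent pixel pair
# counts once; orthogonal steps weigh 1, diagonal steps sqrt(2).
skeleton_step_length <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  ortho <- 0L; diag <- 0L
  if (nr > 1L) ortho <- ortho + sum(skel[-nr, ] & skel[-1L, ])
  if (nc > 1L) ortho <- ortho + sum(skel[, -nc] & skel[, -1L])
  if (nr > 1L && nc > 1L) {
    diag <- diag + sum(skel[-nr, -nc] & skel[-1L, -1L])
    diag <- diag + sum(skel[-nr, -1L] & skel[-1L, -nc])
  }
  ortho + sqrt(2) * diag
}

#' Skeleton-based curvilinear length
#'
#' Thins the mask to a 1-px skeleton (Zhang-Suen) and sums adjacency
#' steps: 1 px for orthogonal neighbours, sqrt(2) px for diagonal ones,
#' scaled by the pixel size. An automated surrogate for manual centerline
#' tracing (NeuronJ-style); an isolated skeleton pixel contributes 0.
#'
#' @param mask logical matrix.
#' @param pixel_size micrometres per pixel (default 1).
#' @return total length in micrometres.
#' @export
skeleton_length <- function(mask, pixel_size = 1.0) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  mask <- mask != 0
  if (!any(mask)) return(0)
  skeleton_step_length(cpp_thin(mask)) * pixel_size
}

#' Pericyte coverage of the vessel network
#'
#' The vessel centerline is the skeleton of `vessel_mask`; a centerline
#' pixel counts as covered when any pericyte-positive pixel lies within
#' `tolerance_radius` (Euclidean). Lengths use the same orthogonal/diagonal
#' step weighting as [skeleton_length()], with a step contributing to the
#' covered length only when both of its endpoints are covered.
#'
#' @param vessel_mask logical matrix of vessel-positive pixels.
#' @param pericyte_mask logical matrix, same shape.
#' @param tolerance_radius apposition tolerance in px (default 2).
#' @param pixel_size micrometres per pixel (default 1).
#' @return list with `vessel_length` (um), `covered_length` (um) and
#'   `coverage_fraction` in `[0, 1]`.
#' @export
pericyte_coverage <- function(vessel_mask, pericyte_mask,
                              tolerance_radius = 2, pixel_size = 1.0) {
  stopifnot(is.matrix(vessel_mask), is.matrix(pericyte_mask),
            tolerance_radius >= 0, pixel_size > 0)
  if (!identical(dim(vessel_mask), dim(pericyte_mask)))
    stop("masks must share dimensions")
  vessel_mask <- vessel_mask != 0
  pericyte_mask <- pericyte_mask != 0
  skel <- cpp_thin(vessel_mask)
  if (!any(skel))
    stop("empty vessel skeleton: coverage is undefined")
  near <- cpp_dilate_disk(pericyte_mask, tolerance_radius)
  vl <- skeleton_step_length(skel) * pixel_size
  cl <- skeleton_step_length(skel & near) * pixel_size
  list(vessel_length = vl, covered_length = cl,
       coverage_fraction = if (vl > 0) cl / vl else 0)
}
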