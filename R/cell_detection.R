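#' Blob-based cell detection
#'
#' Multi-scale Laplacian-of-Gaussian detection of soma-like bright blobs:
#' the image is rescaled to `[0, 1]`, convolved with Gaussians over a
#' geometric ladder of scales between `min_scale` and `max_scale`, and the
#' scale-normalized negative Laplacian response (`sigma^2 * -lap`) is
#' searched for 3x3 spatial local maxima that also dominate the adjacent
#' scales. Survivors above `score_threshold` go through greedy
#' non-maximum suppression (highest score first) enforcing `min_distance`
#' between accepted centres. An automated, reproducible surrogate for
#' manual click-counting of marker-positive cells.
#'
#' @param img micrograph channel or matrix.
#' @param min_scale smallest blob sigma in px (default 3).
#' @param max_scale largest blob sigma in px (default 8).
#' @param score_threshold minimum normalized LoG response (image rescaled
#'   to 0..1; default 0.05).
#' @param min_distance minimum centre-to-centre distance in px (default 6).
#' @param edge_ratio reject ridge-like (elongated) responses whose
#'   Hessian trace^2/determinant exceeds `(edge_ratio+1)^2/edge_ratio`
#'   (SIFT-style edge rejection; default 10; `Inf` disables). Keeps
#'   somata while suppressing responses along curvilinear structures
#'   such as vessels or pericyte processes.
#' @param channel optional channel selector.
#' @param pixel_size um/px used to report the field area; taken from the
#'   micrograph when available.
#' @return a `detection_set`: list with `points` (data.frame: row, col,
#'   scale, score), `channel`, and `image_area_mm2`.
#' @export
detect_cells <- function(img, min_scale = 3, max_scale = 8,
                         score_threshold = 0.05, min_distance = 6,
                         edge_ratio = 10, channel = NULL,
                         pixel_size = NULL) {
  stopifnot(min_scale > 0, max_scale >= min_scale, min_distance >= 0,
            edge_ratio > 0)
  if (inherits(img, "micrograph") && is.null(pixel_size))
    pixel_size <- img$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1.0
  m <- as_matrix_input(img, channel)
  f <- normalize_to_8bit(m) / 255

  n_scales <- max(3L, ceiling(log(max_scale / min_scale) / log(1.3)) + 1L)
  scales <- exp(seq(log(min_scale), log(max_scale), length.out = n_scales))
  smoothed <- lapply(scales, function(s) cpp_gaussian_blur_sep(f, s))
  resp <- lapply(seq_along(scales), function(k)
    scales[k]^2 * -discrete_laplacian(smoothed[[k]]))
  edge_thr <- (edge_ratio + 1)^2 / edge_ratio

  cand <- list()
  nr <- nrow(f); nc <- ncol(f)
  for (k in seq_along(scales)) {
    mx <- cpp_local_maxima(resp[[k]], score_threshold)
    if (nrow(mx) == 0L) next
    g <- smoothed[[k]]
    mrg <- ceiling(scales[k])  # border zone: padding artifacts, not blobs
    ok <- vapply(seq_len(nrow(mx)), function(t) {
      i <- mx[t, 1L]; j <- mx[t, 2L]; v <- mx[t, 3L]
      if (i <= mrg || i > nr - mrg || j <= mrg || j > nc - mrg)
        return(FALSE)
      if (k > 1L && resp[[k - 1L]][i, j] > v) return(FALSE)
      if (k < length(scales) && resp[[k + 1L]][i, j] > v) return(FALSE)
      if (is.infinite(edge_ratio)) return(TRUE)
      # Hessian curvature-ratio test against ridge-like responses
      im <- max(i - 1L, 1L); ip <- min(i + 1L, nr)
      jm <- max(j - 1L, 1L); jp <- min(j + 1L, nc)
      dxx <- g[i, jp] - 2 * g[i, j] + g[i, jm]
      dyy <- g[ip, j] - 2 * g[i, j] + g[im, j]
      dxy <- (g[ip, jp] - g[ip, jm] - g[im, jp] + g[im, jm]) / 4
      det <- dxx * dyy - dxy^2
      det > 0 && (dxx + dyy)^2 / det <= edge_thr
    }, TRUE)
    if (any(ok))
      cand[[length(cand) + 1L]] <- cbind(mx[ok, , drop = FALSE], scales[k])
  }
  pts <- if (length(cand)) do.call(rbind, cand) else matrix(0, 0L, 4L)

  # greedy NMS: best score first, deterministic tie-break by (row, col)
  if (nrow(pts) > 0L) {
    ord <- order(-pts[, 3L], pts[, 1L], pts[, 2L])
    pts <- pts[ord, , drop = FALSE]
    keep <- logical(nrow(pts))
    for (t in seq_len(nrow(pts))) {
      if (t == 1L) { keep[1L] <- TRUE; next }
      kept <- pts[keep, , drop = FALSE]
      d2 <- (kept[, 1L] - pts[t, 1L])^2 + (kept[, 2L] - pts[t, 2L])^2
      keep[t] <- all(d2 >= min_distance^2)
    }
    pts <- pts[keep, , drop = FALSE]
  }
  area_mm2 <- prod(dim(m)) * (pixel_size / 1000)^2
  structure(list(
    points = data.frame(row = pts[, 1L], col = pts[, 2L],
                        scale = if (nrow(pts)) pts[, 4L] else numeric(),
                        score = pts[, 3L]),
    channel = if (is.character(channel)) channel else NA_character_,
    image_area_mm2 = area_mm2,
    image_dim = dim(m)), class = "detection_set")
}

discrete_laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("detection_set: %d cells in %.4f mm^2 (%s)\n",
              nrow(x$points), x$image_area_mm2, x$channel))
  invisible(x)
}

#' Double-positive cell counting across two channels
#'
#' Pairs detections from two channels of the same field by greedy
#' one-to-one matching in ascending distance (deterministic tie-break by
#' distance, then row, then column); a pair counts when the centre
#' distance is at most `pairing_radius`. One-to-one matching prevents a
#' single cell in one channel from claiming several partners.
#'
#' @param a,b `detection_set`s from the same image frame.
#' @param pairing_radius maximum pairing distance in px (default 5).
#' @return list with `count_a`, `count_b`, `count_ab` and `pairs`
#'   (data.frame of matched indices and distances).
#' @export
double_positive <- function(a, b, pairing_radius = 5) {
  stopifnot(inherits(a, "detection_set"), inherits(b, "detection_set"),
            pairing_radius >= 0)
  if (!identical(a$image_dim, b$image_dim))
    stop("detection sets come from different image frames")
  na <- nrow(a$points); nb <- nrow(b$points)
  if (na == 0L || nb == 0L)
    return(list(count_a = na, count_b = nb, count_ab = 0L,
                pairs = data.frame(ia = integer(), ib = integer(),
                                   dist = numeric())))
  d <- outer(seq_len(na), seq_len(nb), function(i, j)
    sqrt((a$points$row[i] - b$points$row[j])^2 +
           (a$points$col[i] - b$points$col[j])^2))
  cand <- which(d <= pairing_radius, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(list(count_a = na, count_b = nb, count_ab = 0L,
                pairs = data.frame(ia = integer(), ib = integer(),
                                   dist = numeric())))
  dd <- d[cand]
  ord <- order(dd, a$points$row[cand[, 1L]], a$points$col[cand[, 1L]])
  cand <- cand[ord, , drop = FALSE]
  dd <- dd[ord]
  used_a <- logical(na); used_b <- logical(nb)
  ia <- integer(); ib <- integer(); dv <- numeric()
  for (t in seq_len(nrow(cand))) {
    i <- cand[t, 1L]; j <- cand[t, 2L]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    ia <- c(ia, i); ib <- c(ib, j); dv <- c(dv, dd[t])
  }
  list(count_a = na, count_b = nb, count_ab = length(ia),
       pairs = data.frame(ia = ia, ib = ib, dist = dv))
}

#' Cell density
#'
#' @param d a `detection_set`.
#' @return cells per mm^2.
#' @export
density_per_mm2 <- function(d) {
  stopifnot(inherits(d, "detection_set"))
  if (d$image_area_mm2 <= 0) stop("image area must be positive")
  nrow(d$points) / d$image_area_mm2
}
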