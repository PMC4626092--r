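#' Micrograph objects
#'
#' A `micrograph` is a list of named single-channel intensity matrices
#' (row-major orientation: `[row, col]`, origin top-left) plus pixel-size
#' metadata. All channels share dimensions; intensities are finite and
#' non-negative. Images are 8- or 16-bit on read and 8-bit (integers in
#' 0..255) after [normalize_to_8bit()].
#'
#' @param channels named list of numeric matrices, or a single matrix
#'   (wrapped as channel `"GRAY"`).
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param bit_depth nominal bit depth of the stored intensities (8 or 16).
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(channels, pixel_size = 1.0, bit_depth = 8L) {
  if (is.matrix(channels)) channels <- list(GRAY = channels)
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of matrices")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named")
  dims <- lapply(channels, dim)
  for (i in seq_along(channels)) {
    ch <- channels[[i]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop("channel '", names(channels)[i], "' is not a numeric matrix")
    if (length(ch) == 0L)
      stop("channel '", names(channels)[i], "' is empty")
    if (!all(is.finite(ch)) || any(ch < 0))
      stop("channel '", names(channels)[i],
           "' has non-finite or negative intensities")
    if (!identical(dims[[i]], dims[[1L]]))
      stop("all channels must share dimensions")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a positive scalar (um/px)")
  structure(list(channels = channels, pixel_size = as.numeric(pixel_size),
                 bit_depth = as.integer(bit_depth)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("micrograph: %d x %d px, %d channel(s) [%s], %g um/px, %d-bit\n",
              d[1L], d[2L], length(x$channels),
              paste(names(x$channels), collapse = ", "),
              x$pixel_size, x$bit_depth))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$channels[[1L]])

#' Extract a single channel matrix
#'
#' @param img a `micrograph` or a plain numeric matrix (returned as-is).
#' @param channel channel name; may be `NULL` when the image has exactly one
#'   channel.
#' @return a numeric intensity matrix.
#' @export
get_channel <- function(img, channel = NULL) {
  if (is.matrix(img)) return(img)
  if (!inherits(img, "micrograph")) stop("not a micrograph or matrix")
  if (is.null(channel)) {
    if (length(img$channels) != 1L)
      stop("multi-channel image: a channel selector is required")
    return(img$channels[[1L]])
  }
  if (!channel %in% names(img$channels))
    stop("channel '", channel, "' not present (have: ",
         paste(names(img$channels), collapse = ", "), ")")
  img$channels[[channel]]
}

#' Read a grayscale image file
#'
#' Supports PNG (8/16-bit, via the png package; RGB(A) collapsed to
#' luminance) and plain-text PGM (`P2`). Intensities are returned on the
#' native integer scale (0..255 or 0..65535).
#'
#' @param path file path; format inferred from the extension.
#' @param channel channel name to assign (default `"GRAY"`).
#' @param pixel_size micrometres per pixel to record (default 1).
#' @return a `micrograph` with one channel.
#' @export
read_micrograph <- function(path, channel = "GRAY", pixel_size = 1.0) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    bit <- 8L
    if (length(dim(a)) == 3L) a <- a[, , 1L]  # gray written as flat RGB
    m <- round(a * 255)
    return(micrograph(stats::setNames(list(m), channel),
                      pixel_size = pixel_size, bit_depth = bit))
  }
  if (ext %in% c("pgm", "pnm")) {
    m <- read_pgm(path)
    bit <- if (max(m) > 255) 16L else 8L
    return(micrograph(stats::setNames(list(m), channel),
                      pixel_size = pixel_size, bit_depth = bit))
  }
  stop("unsupported image format '.", ext, "' (supported: png, pgm)")
}

#' Write a channel as an 8-bit grayscale PNG
#'
#' @param img micrograph or matrix; values must be in 0..255 after rounding.
#' @param path output path.
#' @param channel channel to write for multi-channel images.
#' @export
write_micrograph <- function(img, path, channel = NULL) {
  m <- get_channel(img, channel)
  m <- round_clamp8(m)
  png::writePNG(m / 255, path)
  invisible(path)
}

# plain (ASCII, P2) PGM reader/writer: the text-format interchange used for
# fixtures; comment lines (#) allowed after the magic
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1L] != "P2") stop("not a plain (P2) PGM file: ", path)
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(m, path, maxval = 255L) {
  m <- round(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  apply(m, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Read an image manifest
#'
#' A manifest CSV links image files to experimental metadata. Required
#' columns: `file`, `animal_id`, `group`, `channel`.
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "animal_id", "group", "channel")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  m
}
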