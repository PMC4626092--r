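# Naive per-pixel brute-force references for the filter stack. These
# enumerate neighbourhoods directly and stay independent of the compiled
# implementations they check.

bf_pad_get <- function(m, i, j) {
  m[min(max(i, 1L), nrow(m)), min(max(j, 1L), ncol(m))]
}

bf_disk_offsets <- function(radius) {
  r <- floor(radius)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off[off$di^2 + off$dj^2 <= radius^2, ]
}

bf_gaussian <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * (-rad:rad)^2 / sigma^2)
  k <- k / sum(k)
  out <- m
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      acc <- 0
      for (di in -rad:rad)
        for (dj in -rad:rad)
          acc <- acc + k[di + rad + 1L] * k[dj + rad + 1L] *
            bf_pad_get(m, i + di, j + dj)
      out[i, j] <- acc
    }
  out
}

bf_sobel <- function(m) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)        # d/dcol
  ky <- t(kx)                                              # d/drow
  out <- m
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      gx <- 0; gy <- 0
      for (di in -1:1)
        for (dj in -1:1) {
          v <- bf_pad_get(m, i + di, j + dj)
          gx <- gx + kx[di + 2L, dj + 2L] * v
          gy <- gy + ky[di + 2L, dj + 2L] * v
        }
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  out
}

bf_neighbourhood <- function(m, i, j, off) {
  vapply(seq_len(nrow(off)), function(t)
    bf_pad_get(m, i + off$di[t], j + off$dj[t]), 0)
}

bf_variance <- function(m, radius) {
  off <- bf_disk_offsets(radius)
  out <- m
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      v <- bf_neighbourhood(m, i, j, off)
      out[i, j] <- mean((v - mean(v))^2)
    }
  out
}

bf_median <- function(m, radius) {
  off <- bf_disk_offsets(radius)
  out <- m
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      v <- sort(bf_neighbourhood(m, i, j, off))
      n <- length(v)
      out[i, j] <- if (n %% 2L == 1L) v[(n + 1L) / 2L]
                   else 0.5 * (v[n / 2L] + v[n / 2L + 1L])
    }
  out
}

bf_round8 <- function(m) pmin(pmax(floor(m + 0.5), 0), 255)

random_img8 <- function(nr = 16L, nc = 16L) {
  matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
}

# 4- vs 8-connectivity labelling by pixel-set flood fill (slow, direct)
bf_label <- function(mask, eight = TRUE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  offs <- if (eight) expand.grid(di = -1:1, dj = -1:1)
          else data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  for (j in seq_len(ncol(mask)))
    for (i in seq_len(nrow(mask))) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nxt <- nxt + 1L
      stack <- list(c(i, j)); lab[i, j] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (t in seq_len(nrow(offs))) {
          ii <- p[1L] + offs$di[t]; jj <- p[2L] + offs$dj[t]
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  lab
}
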