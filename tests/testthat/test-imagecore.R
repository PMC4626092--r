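test_that("normalize_to_8bit maps range linearly with half-up rounding", {
  expect_equal(normalize_to_8bit(matrix(7, 3, 3)), matrix(0, 3, 3))
  expect_equal(normalize_to_8bit(matrix(c(0, 255), 1)),
               matrix(c(0, 255), 1))
  expect_equal(as.numeric(normalize_to_8bit(matrix(c(10, 20, 30), 1))),
               c(0, 128, 255))
  # monotone: pixel ordering preserved
  set.seed(7)
  m <- matrix(runif(64, 0, 1000), 8)
  n <- normalize_to_8bit(m)
  expect_true(all(diff(n[order(m)]) >= 0))
  # idempotent up to rounding on an already-normalized image
  expect_equal(normalize_to_8bit(n), n)
  expect_error(normalize_to_8bit(matrix(numeric(0), 0, 0)), "empty")
})

test_that("gaussian_blur: constant, symmetry, brute-force profile", {
  expect_equal(gaussian_blur(matrix(40, 6, 6), 2), matrix(40, 6, 6))
  # single bright pixel: symmetric under 90 degree rotation
  m <- matrix(0, 9, 9); m[5, 5] <- 255
  b <- gaussian_blur(m, 2, eight_bit = FALSE)
  expect_equal(b, t(b))
  expect_equal(b, b[9:1, ])
  # step edge equals naive convolution
  step <- matrix(rep(c(0, 255), each = 8), 1, 16)
  step <- step[rep(1, 8), ]
  expect_equal(gaussian_blur(step, 2, eight_bit = FALSE), bf_gaussian(step, 2),
               tolerance = 1e-12)
  expect_error(gaussian_blur(matrix(1, 3, 3), sigma = 0), "positive")
})

test_that("sobel_magnitude: constants, step edge, transpose symmetry", {
  expect_equal(sobel_magnitude(matrix(9, 5, 5)), matrix(0, 5, 5))
  m <- cbind(matrix(0, 6, 3), matrix(255, 6, 3))
  s <- sobel_magnitude(m, eight_bit = FALSE)
  expect_equal(s[3, 3], 4 * 255)  # interior column at the edge, pre-clamp
  expect_equal(max(sobel_magnitude(m)), 255)  # clamped in 8-bit mode
  set.seed(1)
  r <- random_img8(8, 12)
  expect_equal(sobel_magnitude(t(r), eight_bit = FALSE),
               t(sobel_magnitude(r, eight_bit = FALSE)))
  expect_error(sobel_magnitude(matrix(0, 2, 5)), "3x3")
})

test_that("local_variance: hand example and shift invariance", {
  m <- matrix(0:8, 3, 3, byrow = TRUE)
  v <- local_variance(m, 1, eight_bit = FALSE)
  expect_equal(v[2, 2], 4.0)  # var of {1,3,4,5,7}, population
  expect_equal(local_variance(matrix(5, 4, 4), 2), matrix(0, 4, 4))
  set.seed(2)
  r <- matrix(runif(100, 0, 50), 10)
  expect_equal(local_variance(r + 17, 2, eight_bit = FALSE),
               local_variance(r, 2, eight_bit = FALSE), tolerance = 1e-9)
  expect_error(local_variance(m, radius = 0.5), ">= 1")
})

test_that("local_median: speck removal and ramp preservation", {
  expect_equal(local_median(matrix(3, 5, 5), 3), matrix(3, 5, 5))
  m <- matrix(0, 11, 11); m[6, 6] <- 255
  expect_equal(local_median(m, 3), matrix(0, 11, 11))
  # monotone ramp: interior unchanged (symmetric neighbourhood)
  ramp <- matrix(rep(seq(0, 150, by = 10), each = 16), 16, 16)
  med <- local_median(ramp, 2, eight_bit = FALSE)
  expect_equal(med[5:12, 5:12], ramp[5:12, 5:12])
  expect_equal(med, bf_median(ramp, 2))
})

test_that("subtract/multiply/invert saturation semantics", {
  m <- matrix(c(0, 50, 200), 1)
  expect_equal(as.numeric(subtract_saturate(m, 50)), c(0, 0, 150))
  expect_equal(as.numeric(subtract_saturate(m, 0)), c(0, 50, 200))
  expect_equal(as.numeric(subtract_saturate(matrix(10, 1), 20)), 0)
  auto <- subtract_saturate(m, "auto", eight_bit = FALSE)
  expect_equal(attr(auto, "constant_used"), sd(c(0, 50, 200)))
  expect_error(subtract_saturate(m, -1), "non-negative")

  expect_equal(as.numeric(multiply_saturate(matrix(c(0, 1, 2), 1), 255)),
               c(0, 255, 255))
  expect_equal(multiply_saturate(matrix(0, 2, 2), 255), matrix(0, 2, 2))
  # rounding precedes multiply in 8-bit mode
  expect_equal(as.numeric(multiply_saturate(matrix(c(0.4, 0.6), 1), 255)),
               c(0, 255))
  expect_error(multiply_saturate(m, 0), "positive")

  expect_equal(as.numeric(invert8(matrix(c(0, 100, 255), 1))),
               c(255, 155, 0))
  r <- random_img8()
  expect_equal(invert8(invert8(r)), r)
  expect_error(invert8(matrix(300, 1)), "\\[0, 255\\]")
})

test_that("every filter matches its brute-force reference on random images", {
  set.seed(11)
  for (rep in 1:8) {
    m <- random_img8()
    expect_equal(gaussian_blur(m, 2), bf_round8(bf_gaussian(m, 2)))
    expect_equal(sobel_magnitude(m), bf_round8(bf_sobel(m)))
    expect_equal(local_variance(m, 5), bf_round8(bf_variance(m, 5)))
    expect_equal(local_variance(m, 1), bf_round8(bf_variance(m, 1)))
    expect_equal(local_median(m, 3), bf_round8(bf_median(m, 3)))
    expect_equal(local_median(m, 2), bf_round8(bf_median(m, 2)))
  }
})

test_that("8-bit mode yields integer output in range for every stage", {
  set.seed(3)
  m <- random_img8()
  for (out in list(gaussian_blur(m, 2), sobel_magnitude(m),
                   local_variance(m, 5), local_median(m, 3),
                   subtract_saturate(m, "auto"), multiply_saturate(m, 255),
                   invert8(m))) {
    expect_true(all(out == floor(out)))
    expect_true(all(out >= 0 & out <= 255))
  }
})

test_that("micrograph container validates and round-trips I/O", {
  m <- matrix(0:255, 16, 16)
  img <- micrograph(list(COL4 = m, DAPI = m * 0), pixel_size = 0.6)
  expect_equal(dim(img), c(16L, 16L))
  expect_equal(get_channel(img, "COL4"), m)
  expect_error(get_channel(img), "channel selector")
  expect_error(micrograph(list(A = m, B = matrix(0, 2, 2))), "dimensions")
  expect_error(micrograph(list(A = m - 1)), "negative")

  tf <- tempfile(fileext = ".png")
  write_micrograph(img, tf, channel = "COL4")
  back <- read_micrograph(tf, channel = "COL4")
  expect_equal(get_channel(back, "COL4"), m)

  tg <- tempfile(fileext = ".pgm")
  nvuquant:::write_pgm(m, tg)
  expect_equal(get_channel(read_micrograph(tg)), m)
})
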