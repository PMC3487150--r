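test_that("bilinear lookup interpolates and clamps at the border", {
  img <- scene_image(matrix(c(0, 1, 0, 1), 2, 2))  # columns: (0,1), (0,1)
  # center of the image averages all four pixels
  expect_equal(sample_image(img, c(0, 0)), 0.5)
  # far outside returns a border value
  expect_equal(sample_image(img, c(10, 10)), img$values[1, 2])
})

test_that("constant scenes produce (near-)zero channel responses", {
  ret <- retina_spec()
  flat <- scene_image(matrix(0.73, 96, 96))
  v <- sample_retina(flat, c(0.1, -0.2), ret)
  expect_equal(length(v), 256L)
  expect_lt(max(abs(v)), 1e-12)
})

test_that("shifting scene and gaze together leaves the responses unchanged", {
  ret <- retina_spec()
  gl <- cached_glyphs()
  img <- gl$hypotheses$upright
  shift_px <- 8L  # whole pixels so no interpolation error enters
  shifted <- scene_image(cbind(img$values[, (shift_px + 1):ncol(img$values)],
                               img$values[, 1:shift_px]))
  dx <- 2 * shift_px / ncol(img$values)
  v0 <- sample_retina(img, c(dx / 2, 0.1), ret)
  v1 <- sample_retina(shifted, c(dx / 2 - dx, 0.1), ret)
  # interior of both samplings sees the same content
  expect_equal(v1, v0, tolerance = 1e-10)
})

test_that("channel responses match a direct receptive-field summation", {
  ret <- retina_spec()
  gl <- cached_glyphs()
  img <- gl$hypotheses$upright
  n <- ncol(img$values)
  gaze <- c(1 / n, 1 / n)  # half-pixel shift puts channels on pixel centers
  v <- sample_retina(img, gaze, ret)

  # direct summation: explicit difference-of-Gaussians weights on the pixel
  # grid around each channel center
  px <- 2 / n
  s_c <- ret$dog_sigma_center * ret$spacing / px
  s_s <- ret$dog_sigma_surround * ret$spacing / px
  r <- ceiling(3 * s_s)
  d <- (-r):r
  kc <- exp(-outer(d^2, d^2, "+") / (2 * s_c^2)); kc <- kc / sum(kc)
  ks <- exp(-outer(d^2, d^2, "+") / (2 * s_s^2)); ks <- ks / sum(ks)
  for (ch in c(1L, 60L, 128L, 200L)) {
    p <- ret$offsets[ch, ] + gaze
    col <- round(p[1] * n / 2 + (n + 1) / 2)
    row <- round((n + 1) / 2 - p[2] * n / 2)
    patch <- img$values[row + d, col + d]
    direct <- sum((kc - ks) * patch) * ret$hamming[ch]
    expect_equal(v[ch], direct, tolerance = 1e-10)
  }
})

test_that("a step edge through the fovea yields an antisymmetric response", {
  ret <- retina_spec()
  n <- 96
  edge <- scene_image(matrix(rep(c(0, 1), each = n * n / 2), n, n))  # right half bright
  v <- matrix(sample_retina(edge, c(0, 0), ret), ret$n_side)  # y fast
  # channels mirrored across the (vertical) edge respond with opposite sign,
  # and the response is nonzero only near the edge
  expect_equal(v[, 8], -v[, 9], tolerance = 1e-8)
  expect_gt(max(abs(v[, 8:9])), 1e-3)
  expect_lt(max(abs(v[, c(1, 16)])), 1e-8)
})

test_that("glyph fixtures drive a strong, structured retinal response", {
  ret <- retina_spec()
  gl <- cached_glyphs()
  v <- sample_retina(gl$hypotheses$upright, c(0, 0), ret)
  expect_gt(diff(range(v)), 1e-3)
})
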