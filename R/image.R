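# Grayscale images with continuous lookup, small-kernel convolution, and
# plain-text / PNG input-output.

#' Grayscale image with continuous coordinates
#'
#' Wraps a numeric matrix of gray values in `[0, 1]` as a visual scene with a
#' continuous coordinate convention: the origin at the image center, `x`
#' rightward along columns, `y` upward along (reversed) rows, in units of the
#' image half-width, so a square image spans `[-1, 1]` on both axes. Lookups
#' outside the support return the nearest border value.
#'
#' @param values numeric matrix of gray values (rows are displayed top-down).
#' @return An object of class `scene_image`.
#' @export
scene_image <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("image values must be finite", call. = FALSE)
  structure(list(values = values, n_row = nrow(values), n_col = ncol(values)),
            class = "scene_image")
}

#' @export
print.scene_image <- function(x, ...) {
  cat(sprintf("scene_image: %d x %d, range [%.3f, %.3f]\n",
              x$n_row, x$n_col, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.scene_image <- function(x, ...) {
  graphics::image(t(x$values[x$n_row:1, , drop = FALSE]), col = grDevices::gray.colors(256),
                  asp = x$n_row / x$n_col, axes = FALSE, ...)
  invisible(x)
}

# continuous pixel index of coordinate points (n x 2 matrix of x, y):
# returns fractional (row, col); border-clamped
coord_to_index <- function(img, xy) {
  # both axes measured in units of the image half-width (square pixels)
  half_w <- img$n_col / 2
  col <- xy[, 1L] * half_w + (img$n_col + 1) / 2
  row <- (img$n_row + 1) / 2 - xy[, 2L] * half_w
  cbind(pmin(pmax(row, 1), img$n_row), pmin(pmax(col, 1), img$n_col))
}

#' Bilinear image lookup
#'
#' @param img a [scene_image()].
#' @param xy `n x 2` matrix of `(x, y)` coordinates (or a length-2 vector).
#' @return Numeric vector of interpolated gray values (border values outside
#'   the support).
#' @export
sample_image <- function(img, xy) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2L)
  rc <- coord_to_index(img, xy)
  r0 <- pmin(floor(rc[, 1L]), img$n_row - 1L); fr <- rc[, 1L] - r0
  c0 <- pmin(floor(rc[, 2L]), img$n_col - 1L); fc <- rc[, 2L] - c0
  v <- img$values
  v[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    v[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    v[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    v[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# 2D convolution with a small kernel by shift-and-add, border replicated
conv2_replicate <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) / 2
  kc <- (ncol(kernel) - 1L) / 2
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2 * kr, nc + 2 * kc)
  pad[kr + seq_len(nr), kc + seq_len(nc)] <- m
  if (kr > 0) {
    for (i in seq_len(kr)) { pad[i, ] <- pad[kr + 1, ]; pad[nr + kr + i, ] <- pad[nr + kr, ] }
  }
  if (kc > 0) {
    for (j in seq_len(kc)) { pad[, j] <- pad[, kc + 1]; pad[, nc + kc + j] <- pad[, nc + kc] }
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      if (kernel[i, j] != 0) {
        out <- out + kernel[i, j] * pad[(i - 1) + seq_len(nr), (j - 1) + seq_len(nc)]
      }
    }
  }
  out
}

gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  d <- (-r):r
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma_px^2))
  k / sum(k)
}

# central-difference gradient images in coordinate units (per half-width)
image_gradients <- function(img) {
  v <- img$values
  nr <- img$n_row; nc <- img$n_col
  px <- 2 / nc  # coordinate width of one pixel
  gx <- (v[, c(2:nc, nc)] - v[, c(1, 1:(nc - 1))]) / (2 * px)
  gy <- (v[c(1, 1:(nr - 1)), ] - v[c(2:nr, nr), ]) / (2 * px)  # y points up
  list(gx = scene_image(gx), gy = scene_image(gy))
}

#' Read and write plain-text PGM images
#'
#' Minimal ASCII (`P2`) PGM support for exporting salience maps and synthetic
#' scenes as text. Values are scaled to `[0, maxval]` on write and back to
#' `[0, 1]` on read.
#'
#' @param path file path.
#' @param img a [scene_image()] (for writing).
#' @param maxval maximum gray level written (default 255).
#' @return `read_pgm` returns a [scene_image()]; `write_pgm` returns `path`
#'   invisibly.
#' @export
read_pgm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") stop("only ASCII (P2) PGM files are supported", call. = FALSE)
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3]); mx <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM: wrong pixel count", call. = FALSE)
  scene_image(matrix(vals, nr, nc, byrow = TRUE) / mx)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, maxval = 255) {
  v <- img$values
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  v <- round(v * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(img$n_col, img$n_row), as.character(maxval)), con)
  write(t(v), file = con, ncolumns = img$n_col)
  invisible(path)
}

#' Read and write grayscale PNG images
#'
#' @param path file path.
#' @param img a [scene_image()].
#' @return `read_png_image` returns a [scene_image()] (color images are
#'   averaged to gray); `write_png_image` returns `path` invisibly.
#' @export
read_png_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  scene_image(a)
}

#' @rdname read_png_image
#' @export
write_png_image <- function(img, path) {
  v <- img$values
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  png::writePNG(v, path)
  invisible(path)
}
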