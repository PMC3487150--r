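# Center-surround retinal sampling: a square grid of channels with
# difference-of-Gaussians receptive fields under a Hamming sensitivity window.

#' Retinal sampling grid
#'
#' A square grid of `n_side x n_side` visual channels covering a local
#' (foveal) region of the scene. Each channel samples the image through an
#' on-off center-surround (difference-of-Gaussians) receptive field, and
#' channel gains are modulated by a two-dimensional Hamming window to model
#' the loss of precise information toward the periphery.
#'
#' @param n_side channels per side (default 16, i.e. 256 channels).
#' @param fov_halfwidth half-width of the sampled region in image coordinates
#'   (units of image half-width; default 0.25, a local fovea).
#' @param dog_sigma_center,dog_sigma_surround Gaussian widths of the
#'   receptive-field center and surround, in channel spacings.
#' @return An object of class `retina_spec` with channel offsets `offsets`
#'   (`n_side^2 x 2`), Hamming weights `hamming`, and the field geometry.
#' @export
retina_spec <- function(n_side = 16, fov_halfwidth = 0.25,
                        dog_sigma_center = 0.5, dog_sigma_surround = 1.0) {
  n_side <- as.integer(n_side)
  if (n_side < 2L) stop("n_side must be >= 2", call. = FALSE)
  if (dog_sigma_surround <= dog_sigma_center) {
    stop("surround width must exceed center width", call. = FALSE)
  }
  u <- (seq_len(n_side) - (n_side + 1) / 2) / n_side * 2 * fov_halfwidth
  offsets <- cbind(x = rep(u, each = n_side), y = rep(rev(u), n_side))
  h1 <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_side) - 1) / (n_side - 1))
  hamming <- as.numeric(outer(h1, h1))  # matches offsets' (y fast) ordering
  structure(list(n_side = n_side, n_channels = n_side^2,
                 fov_halfwidth = fov_halfwidth,
                 spacing = 2 * fov_halfwidth / n_side,
                 dog_sigma_center = dog_sigma_center,
                 dog_sigma_surround = dog_sigma_surround,
                 offsets = offsets, hamming = hamming),
            class = "retina_spec")
}

#' Center-surround filter an image for retinal sampling
#'
#' Convolves the scene with the difference of two unit-sum Gaussians (center
#' minus surround, widths set by the retina), producing the field of local
#' on-off contrast that each channel then samples pointwise. Constant
#' (luminance) levels are suppressed exactly because the two Gaussians each
#' integrate to one. The result caches the filtered image and its gradients
#' for fast repeated sampling.
#'
#' @param scene a [scene_image()].
#' @param retina a [retina_spec()].
#' @return A `scene_image` with attributes used by [sample_retina()].
#' @export
dog_filter <- function(scene, retina) {
  px <- 2 / scene$n_col
  s_c <- retina$dog_sigma_center * retina$spacing / px
  s_s <- retina$dog_sigma_surround * retina$spacing / px
  k <- {
    r <- max(1L, ceiling(3 * s_s))
    d <- (-r):r
    kc <- exp(-outer(d^2, d^2, "+") / (2 * s_c^2)); kc <- kc / sum(kc)
    ks <- exp(-outer(d^2, d^2, "+") / (2 * s_s^2)); ks <- ks / sum(ks)
    kc - ks
  }
  filt <- scene_image(conv2_replicate(scene$values, k))
  gr <- image_gradients(filt)
  attr(filt, "dog") <- TRUE
  attr(filt, "grad") <- gr
  filt
}

#' Sample a scene through the retina
#'
#' Channel `i` returns the center-surround filtered scene at the channel's
#' offset from the center of gaze, multiplied by the channel's Hamming
#' weight.
#'
#' @param scene a [scene_image()]; filtered internally unless already
#'   prepared with [dog_filter()].
#' @param gaze length-2 center of gaze `(x, y)` in scene coordinates.
#' @param retina a [retina_spec()].
#' @param gradient if `TRUE`, also return the Jacobian of the channel vector
#'   with respect to the gaze (an `n_channels x 2` matrix).
#' @return Numeric vector of `n_channels` responses, or (with
#'   `gradient = TRUE`) a list with `values` and `jacobian`.
#' @export
sample_retina <- function(scene, gaze, retina = retina_spec(), gradient = FALSE) {
  if (is.null(attr(scene, "dog"))) scene <- dog_filter(scene, retina)
  pts <- sweep(retina$offsets, 2L, as.numeric(gaze), "+")
  vals <- sample_image(scene, pts) * retina$hamming
  if (!gradient) return(vals)
  gr <- attr(scene, "grad")
  jac <- cbind(sample_image(gr$gx, pts), sample_image(gr$gy, pts)) * retina$hamming
  list(values = vals, jacobian = jac)
}
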