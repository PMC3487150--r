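# Seeded generators for test inputs: toy decision processes for the discrete
# scheme and synthetic glyph images for the visual-search simulator. These are
# first-class package functionality: the full test battery and the simulators'
# demonstrations run on them with no external data.

#' Generate a seeded toy partially observed decision process
#'
#' Builds a small random model in both the forward parameterization used by
#' the Bellman oracle (per-action transition matrices and a reward vector)
#' and the pullback parameterization used by the variational scheme (a
#' [discrete_model()] whose pullback matrices are the column-normalized
#' transposes of the forward transitions). Observations are the states
#' themselves (identity likelihood) and the sampling kernel equals the
#' forward transitions, so action selection and planning can be compared
#' directly with dynamic-programming solutions.
#'
#' @param n_states,n_actions,horizon problem size.
#' @param deterministic if `TRUE`, each forward transition column is a point
#'   mass on a random successor; otherwise columns are Dirichlet(1) draws.
#' @param reward_sparsity number of states carrying (positive) reward; reward
#'   values are jittered so the optimal policy is unique almost surely.
#' @param terminal_prior `"delta"` (point mass on a random state) or
#'   `"random"` (Dirichlet draw) for the pullback model's goal prior.
#' @param seed integer seed (reproducible).
#' @return A list with `model` (a [discrete_model()]), `Tr` (forward
#'   transition matrices), `R` (sampling kernels, equal to `Tr`), and
#'   `reward` (numeric vector).
#' @export
make_toy_mdp <- function(n_states = 4, n_actions = 3, horizon = 3,
                         deterministic = FALSE, reward_sparsity = 1,
                         terminal_prior = c("delta", "random"), seed = 1) {
  terminal_prior <- match.arg(terminal_prior)
  set.seed(as.integer(seed))
  rdirch <- function(n) { x <- stats::rgamma(n, 1); x / sum(x) }
  rcol <- function(n) {
    if (deterministic) { v <- numeric(n); v[sample.int(n, 1L)] <- 1; v } else rdirch(n)
  }
  Tr <- lapply(seq_len(n_actions), function(a) {
    vapply(seq_len(n_states), function(j) rcol(n_states), numeric(n_states))
  })
  reward <- numeric(n_states)
  hot <- sample.int(n_states, min(reward_sparsity, n_states))
  reward[hot] <- 1 + stats::runif(length(hot))  # jitter breaks policy ties
  reward <- reward + stats::rnorm(n_states, sd = 1e-3)

  cvec <- if (terminal_prior == "delta") {
    v <- numeric(n_states); v[sample.int(n_states, 1L)] <- 1; v
  } else rdirch(n_states)
  B <- lapply(Tr, function(M) normalize_columns(t(M) + 1e-12))
  model <- discrete_model(A = diag(n_states), B = B, c = cvec,
                          d = rep(1 / n_actions, n_actions), horizon = horizon)
  list(model = model, Tr = Tr, R = Tr, reward = reward)
}

# draw a Gaussian blob / oriented bar onto a coordinate grid
draw_blob <- function(gx, gy, cx, cy, sigma, amp) {
  amp * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sigma^2))
}

#' Generate synthetic glyph hypotheses and matched scenes
#'
#' Draws a deterministic, seeded "glyph": an asymmetric arrangement of
#' Gaussian blobs plus one oriented bar, with localized high-gradient
#' features so that salience maps computed on it are non-flat. Three
#' hypothesis images are returned — the upright glyph, the same glyph rotated
#' by 180 degrees (inverted), and by 90 degrees — which are exact pixel
#' permutations of one another, mirroring a categorization task among
#' upright, inverted, and rotated variants of one stimulus. Matched test
#' scenes equal each hypothesis, optionally with seeded Gaussian pixel noise.
#'
#' @param size image side in pixels (default 128).
#' @param n_blobs number of Gaussian blobs (3 to 5).
#' @param noise_sd pixel noise added to the scenes (0 = exact copies).
#' @param seed integer seed.
#' @return A list with `hypotheses` (list of 3 [scene_image()]s named
#'   `upright`, `inverted`, `rotated`) and `scenes` (matched list).
#' @export
make_glyph_hypotheses <- function(size = 128, n_blobs = 4, noise_sd = 0, seed = 1) {
  set.seed(as.integer(seed))
  n_blobs <- max(3L, min(5L, as.integer(n_blobs)))
  u <- seq(-1, 1, length.out = size)
  gx <- matrix(rep(u, each = size), size)         # x along columns
  gy <- matrix(rep(rev(u), size), size)           # y up along rows
  # small, sharp blobs: most of their energy falls in the retina's
  # center-surround passband, so they drive strong channel responses
  img <- matrix(0, size, size)
  for (b in seq_len(n_blobs)) {
    img <- img + draw_blob(gx, gy,
                           cx = stats::runif(1, -0.55, 0.55),
                           cy = stats::runif(1, -0.55, 0.55),
                           sigma = stats::runif(1, 0.02, 0.05),
                           amp = stats::runif(1, 0.7, 1))
  }
  # one bar: a thin ridge along a random direction through an off-center point
  th <- stats::runif(1, 0, pi)
  x0 <- stats::runif(1, -0.3, 0.3); y0 <- stats::runif(1, -0.3, 0.3)
  d <- abs((gx - x0) * sin(th) - (gy - y0) * cos(th))
  along <- (gx - x0) * cos(th) + (gy - y0) * sin(th)
  img <- img + 0.9 * exp(-d^2 / (2 * 0.012^2)) * (abs(along) < 0.45)
  img <- pmin(img, 1)

  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])        # 90 deg clockwise
  rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
  hyps <- list(upright = scene_image(img),
               inverted = scene_image(rot180(img)),
               rotated = scene_image(rot90(img)))
  scenes <- lapply(hyps, function(h) {
    v <- h$values
    if (noise_sd > 0) v <- pmin(pmax(v + stats::rnorm(length(v), sd = noise_sd), 0), 1)
    scene_image(v)
  })
  list(hypotheses = hyps, scenes = scenes)
}
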