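# Saccadic visual search: generative process and model, counterfactual
# salience maps, inhibition of return, and the saccade loop.

#' Generative model for visual search over competing hypotheses
#'
#' Wires a [level_spec()] for the filtering core. Hidden states are the
#' center of gaze `x_p` (2) and one perceptual log-weight `x_q` per
#' hypothesis image; the hidden control state `u` (2) is the fixation
#' attractor. The gaze expectation decays toward `u` with a time constant of
#' 4 bins; the perceptual states follow a dynamic softmax whose equilibrium
#' constrains the exponentiated weights to sum to (approximately) one, with a
#' slow decay (coefficient 1/1024 per bin). Predicted proprioception is the
#' gaze itself; predicted vision is the softmax-weighted mixture of the
#' hypothesis images sampled at the gaze through the retina.
#'
#' @param hyps list of hypothesis [scene_image()]s (all the same size).
#' @param retina a [retina_spec()].
#' @param log_prec_proprio,log_prec_visual,log_prec_states,log_prec_control
#'   log-precisions of the model's random fluctuations (defaults 8, 4, 8, 8:
#'   precise proprioception and state motion, noisy vision).
#' @param n_orders generalized embedding order (default 3).
#' @param decay_coef coefficient of the slow perceptual decay (default
#'   `1/1024` per bin).
#' @return A [level_spec()] with extra fields `hyps_filtered`, `retina`,
#'   `n_hyp`, and `decay_coef`; hidden states are ordered `(x_p, x_q)`.
#' @export
saccade_model <- function(hyps, retina = retina_spec(),
                          log_prec_proprio = 8, log_prec_visual = 4,
                          log_prec_states = 8, log_prec_control = 8,
                          n_orders = 3, decay_coef = 1 / 1024) {
  N <- length(hyps)
  if (N < 1L) stop("need at least one hypothesis image", call. = FALSE)
  hf <- lapply(hyps, dog_filter, retina = retina)
  n_s <- 2L + retina$n_channels
  n_x <- 2L + N

  f <- function(x, u) {
    xp <- x[1:2]; xq <- x[-(1:2)]
    c((u - xp) / 4, (1 - sum(exp(xq))) - decay_coef * xq)
  }
  f_jac <- function(x, u) {
    xq <- x[-(1:2)]
    jx <- matrix(0, n_x, n_x)
    jx[1:2, 1:2] <- -diag(2) / 4
    # d(xq_i dot)/d(xq_j) = -exp(xq_j) - delta_ij * decay
    jx[2 + seq_len(N), 2 + seq_len(N)] <-
      -matrix(exp(xq), N, N, byrow = TRUE) - diag(N) * decay_coef
    ju <- matrix(0, n_x, 2L)
    ju[1:2, ] <- diag(2) / 4
    list(x = jx, u = ju)
  }
  g <- function(x, u) {
    xp <- x[1:2]; w <- exp(x[-(1:2)])
    vis <- numeric(retina$n_channels)
    for (i in seq_len(N)) vis <- vis + w[i] * sample_retina(hf[[i]], xp, retina)
    c(xp, vis)
  }
  g_jac <- function(x, u) {
    xp <- x[1:2]; w <- exp(x[-(1:2)])
    jx <- matrix(0, n_s, n_x)
    jx[1:2, 1:2] <- diag(2)
    dvis_dxp <- matrix(0, retina$n_channels, 2L)
    for (i in seq_len(N)) {
      sr <- sample_retina(hf[[i]], xp, retina, gradient = TRUE)
      dvis_dxp <- dvis_dxp + w[i] * sr$jacobian
      jx[2L + seq_len(retina$n_channels), 2L + i] <- w[i] * sr$values
    }
    jx[2L + seq_len(retina$n_channels), 1:2] <- dvis_dxp
    list(x = jx, u = matrix(0, n_s, 2L))
  }

  spec <- level_spec(
    f = f, g = g, n_x = n_x, n_u = 2L, n_s = n_s,
    log_precisions = list(
      sensory = c(rep(log_prec_proprio, 2L), rep(log_prec_visual, retina$n_channels)),
      states = log_prec_states, control = log_prec_control),
    control_prior = c(0, 0), f_jac = f_jac, g_jac = g_jac, n_orders = n_orders)
  spec$hyps_filtered <- hf
  spec$retina <- retina
  spec$n_hyp <- N
  spec$decay_coef <- decay_coef
  spec
}

#' Equilibrium of the perceptual-state flow
#'
#' Integrates the perceptual log-weight dynamics
#' `dx_q/dt = (1 - sum(exp(x_q))) - decay_coef * x_q` with no prediction-error
#' drive until the per-bin state change falls below `tol`, and returns the
#' trajectory endpoint. At equilibrium the exponentiated weights sum to
#' approximately one (the dynamic-softmax fixed point), up to a small
#' residual set by the slow decay term.
#'
#' @param n number of hypotheses.
#' @param x0 starting log-weights (default `-2` each).
#' @param decay_coef slow decay coefficient (default `1/1024`).
#' @param dt integration step in bins.
#' @param tol convergence threshold on the per-bin change.
#' @param max_bins iteration guard.
#' @return A list with `x_q` (equilibrium log-weights), `sum_exp`
#'   (`sum(exp(x_q))`), and `n_bins` used.
#' @export
perceptual_equilibrium <- function(n = 3, x0 = rep(-2, n), decay_coef = 1 / 1024,
                                   dt = 0.1, tol = 1e-10, max_bins = 1e6) {
  x <- as.numeric(x0)
  flow <- function(x) (1 - sum(exp(x))) - decay_coef * x
  bins <- 0
  repeat {
    # one bin, integrated in sub-steps for stability
    xs <- x
    for (i in seq_len(round(1 / dt))) xs <- xs + dt * flow(xs)
    bins <- bins + 1
    if (max(abs(xs - x)) < tol || bins >= max_bins) { x <- xs; break }
    x <- xs
  }
  list(x_q = x, sum_exp = sum(exp(x)), n_bins = bins)
}

#' Counterfactual salience map over candidate fixations
#'
#' For each candidate fixation, substitutes the candidate for the gaze state
#' while holding the current perceptual expectations fixed, computes the
#' Laplace conditional precision over the perceptual states, and returns half
#' its log-determinant — the (negative) entropy of the counterfactual
#' posterior. Salience is a function of beliefs only: the true scene never
#' enters, only the hypothesis images and the current expectations.
#'
#' @param spec a [saccade_model()].
#' @param state a [filter_state()] (its perceptual expectations are used).
#' @param candidates `m x 2` matrix of candidate fixations; default a
#'   `grid_side x grid_side` grid spanning the scene.
#' @param grid_side side of the default candidate grid (default 32, i.e.
#'   1024 locations).
#' @return An object of class `salience_map`: a list with `values` (length
#'   `m`), `candidates`, `grid_side` (when the default grid is used),
#'   `argmax` (index) and `argmax_location`.
#' @export
salience_map <- function(spec, state, candidates = NULL, grid_side = 32) {
  if (is.null(candidates)) {
    u <- (seq_len(grid_side) - (grid_side + 1) / 2) / grid_side * 2
    candidates <- cbind(x = rep(u, each = grid_side), y = rep(rev(u), grid_side))
  } else {
    grid_side <- NA_integer_
  }
  if (!nrow(candidates)) stop("no candidate fixations", call. = FALSE)
  N <- spec$n_hyp
  w <- exp(state$mu_x[2L + seq_len(N), 1L])
  pi_vis <- spec$pi_v[-(1:2)]
  prior <- spec$pi_x[2L + seq_len(N)]

  # channel responses of every hypothesis at every candidate
  m <- nrow(candidates)
  Rh <- lapply(spec$hyps_filtered, function(h) {
    vapply(seq_len(m), function(j) sample_retina(h, candidates[j, ], spec$retina),
           numeric(spec$retina$n_channels))
  })
  # Gram matrices of precision-weighted responses, per candidate
  vals <- numeric(m)
  G <- array(0, c(N, N, m))
  for (a in seq_len(N)) for (b in a:N) {
    cab <- colSums(Rh[[a]] * Rh[[b]] * pi_vis)
    G[a, b, ] <- cab; G[b, a, ] <- cab
  }
  for (j in seq_len(m)) {
    Pi <- (w %o% w) * G[, , j] + diag(prior, N)
    vals[j] <- 0.5 * as.numeric(determinant(Pi, logarithm = TRUE)$modulus)
  }
  amax <- which.max(vals)
  structure(list(values = vals, candidates = candidates, grid_side = grid_side,
                 argmax = amax, argmax_location = candidates[amax, ]),
            class = "salience_map")
}

#' @export
print.salience_map <- function(x, ...) {
  cat(sprintf("salience map: %d candidates, range [%.4f, %.4f], argmax at (%.3f, %.3f)\n",
              length(x$values), min(x$values), max(x$values),
              x$argmax_location[1], x$argmax_location[2]))
  invisible(x)
}

#' @export
plot.salience_map <- function(x, ...) {
  if (is.na(x$grid_side)) stop("only grid salience maps can be plotted", call. = FALSE)
  m <- matrix(x$values, x$grid_side, x$grid_side)
  graphics::image(t(m[x$grid_side:1, ]), col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

# convert a salience_map's values to a scene_image (for PGM export)
salience_as_image <- function(s) {
  if (is.na(s$grid_side)) stop("not a grid salience map", call. = FALSE)
  scene_image(matrix(s$values, s$grid_side, s$grid_side))
}

#' Inhibition of return
#'
#' Applies the inhibition-of-return recursion to a raw salience map: the map
#' is first shifted to differential salience (its minimum subtracted), then
#' multiplied entrywise by one minus the decaying memory of recently foveated
#' locations. The memory is refreshed with a Gaussian bump (peak 1) centered
#' on the new argmax plus half the previous memory, clipped to `[0, 1]` — so
#' the location just foveated has zero salience for the next saccade and the
#' memory of older fixations halves with each saccade.
#'
#' @param S a [salience_map()] (raw values).
#' @param R_prev numeric vector of memory values over the same candidates
#'   (zeros on the first saccade).
#' @param rho_sigma standard deviation of the memory bump, in scene
#'   coordinates (default 1/16 of the image size, i.e. `2/16 = 0.125`).
#' @return A list with `S_final` (the inhibited [salience_map()]), `R_new`
#'   (updated memory vector), and `argmax` / `argmax_location` of the
#'   inhibited map.
#' @export
apply_inhibition_of_return <- function(S, R_prev = NULL, rho_sigma = 2 / 16) {
  v <- S$values - min(S$values)
  if (is.null(R_prev)) R_prev <- numeric(length(v))
  if (length(R_prev) != length(v)) stop("memory/map shape mismatch", call. = FALSE)
  v <- v * (1 - R_prev)
  amax <- which.max(v)
  loc <- S$candidates[amax, ]
  d2 <- (S$candidates[, 1L] - loc[1L])^2 + (S$candidates[, 2L] - loc[2L])^2
  rho <- exp(-d2 / (2 * rho_sigma^2))
  R_new <- pmin(pmax(rho + R_prev / 2, 0), 1)
  out <- S
  out$values <- v
  out$argmax <- amax
  out$argmax_location <- loc
  list(S_final = out, R_new = R_new, argmax = amax, argmax_location = loc)
}

# smoothed, seeded Gaussian noise: white noise convolved with a Gaussian
# kernel over time bins, rescaled to the target marginal sd
smooth_noise <- function(n_bins, n_ch, sd, kernel_sd = 1) {
  if (sd <= 0) return(matrix(0, n_ch, n_bins))
  r <- max(1L, ceiling(3 * kernel_sd))
  k <- exp(-((-r):r)^2 / (2 * kernel_sd^2))
  k <- k / sqrt(sum(k^2))
  w <- matrix(stats::rnorm(n_ch * (n_bins + 2 * r)), n_ch)
  out <- matrix(0, n_ch, n_bins)
  for (b in seq_len(n_bins)) {
    out[, b] <- as.numeric(w[, b:(b + 2 * r), drop = FALSE] %*% k)
  }
  out * sd
}

#' One step of the visual-search generative process
#'
#' Advances the true (world-side) state: the center of gaze integrates
#' `dx_p/dt = a - x_p/16` plus motion noise, and returns proprioceptive and
#' visual observations in generalized coordinates (values and first
#' derivatives; higher orders zero). Sensory noise has log-precision 16 and
#' motion noise log-precision 8 by default (effectively noiseless sensors,
#' weakly fluctuating motion).
#'
#' @param scene the true [scene_image()] (filtered internally if needed).
#' @param x_p current true center of gaze (length 2).
#' @param action current action (length 2).
#' @param retina a [retina_spec()].
#' @param dt bin length (default 1).
#' @param noise_x,noise_s motion / sensory noise values for this bin
#'   (length-2 and length-`n_s` vectors; zeros for a noiseless process).
#' @param n_orders generalized orders of the returned observations.
#' @return A list with `x_p` (new true gaze) and `s_tilde`
#'   (`(2 + n_channels) x n_orders` observation matrix).
#' @export
process_step <- function(scene, x_p, action, retina = retina_spec(), dt = 1,
                         noise_x = c(0, 0), noise_s = NULL, n_orders = 3) {
  if (is.null(attr(scene, "dog"))) scene <- dog_filter(scene, retina)
  n_s <- 2L + retina$n_channels
  if (is.null(noise_s)) noise_s <- numeric(n_s)
  xp_dot <- action - x_p / 16 + noise_x
  x_new <- x_p + dt * xp_dot
  sr <- sample_retina(scene, x_new, retina, gradient = TRUE)
  s0 <- c(x_new, sr$values) + noise_s
  xdot_new <- action - x_new / 16
  s1 <- c(xdot_new, as.numeric(sr$jacobian %*% xdot_new))
  s_tilde <- gen_vec(cbind(s0, s1), n_orders)
  list(x_p = x_new, s_tilde = s_tilde)
}

#' Simulate a saccadic visual search
#'
#' Runs the full active-inference search: within each saccade the filter and
#' the reflex-arc action are integrated in closed loop with the generative
#' process for `bins_per_saccade` time bins; at the saccade boundary a
#' salience map over candidate fixations is computed from the current
#' (counterfactual) beliefs, inhibition of return is applied, and the prior
#' expectation about the fixation attractor is reset to the most salient
#' location. The perceptual log-weights accumulate evidence about which
#' hypothesis causes the visual input.
#'
#' @param scene the true [scene_image()].
#' @param hyps list of hypothesis [scene_image()]s.
#' @param n_saccades number of saccades (default 8).
#' @param bins_per_saccade time bins between saccades (default 16; one bin
#'   nominally 12 ms).
#' @param retina a [retina_spec()].
#' @param seed integer seed for the process noise.
#' @param noise if `FALSE`, the generative process is noiseless.
#' @param grid_side side of the salience candidate grid (default 32).
#' @param n_orders generalized embedding order.
#' @param ... further arguments passed to [saccade_model()].
#' @return An object of class `saccade_trace`: per-bin records (`gaze_true`,
#'   `gaze_inferred`, `action`, `posterior` softmax weights, `free_energy`),
#'   per-saccade records (`fixations`, `salience_maps`, `ior_memory`,
#'   `entropy` of the hypothesis posterior at each saccade boundary,
#'   `ci_halfwidth` Laplace 90% intervals), and the final state.
#' @export
saccade_search <- function(scene, hyps, n_saccades = 8, bins_per_saccade = 16,
                           retina = retina_spec(), seed = 1, noise = TRUE,
                           grid_side = 32, n_orders = 3, ...) {
  if (n_saccades < 1L) stop("n_saccades must be >= 1", call. = FALSE)
  spec <- saccade_model(hyps, retina, n_orders = n_orders, ...)
  N <- spec$n_hyp
  scene_f <- dog_filter(scene, retina)
  n_bins <- n_saccades * bins_per_saccade
  n_s <- spec$n_s

  set.seed(as.integer(seed))
  nx <- if (noise) smooth_noise(n_bins, 2L, exp(-8 / 2)) else matrix(0, 2L, n_bins)
  ns <- if (noise) smooth_noise(n_bins, n_s, exp(-16 / 2)) else matrix(0, n_s, n_bins)

  state <- filter_state(spec,
                        mu_x = c(0, 0, rep(log(1 / N), N)),
                        mu_u = c(0, 0), n_action = 2L)
  x_true <- c(0, 0)
  sensitivity <- rbind(diag(2), matrix(0, n_s - 2L, 2L))

  gaze_true <- gaze_inferred <- matrix(NA_real_, n_bins, 2L)
  actions <- matrix(NA_real_, n_bins, 2L)
  posterior <- matrix(NA_real_, n_bins, N)
  free_energy <- numeric(n_bins)
  fixations <- matrix(NA_real_, n_saccades, 2L)
  entropy <- numeric(n_saccades)
  ci_halfwidth <- matrix(NA_real_, n_saccades, N)
  maps <- vector("list", n_saccades)
  R_ior <- NULL

  bin <- 0L
  for (sac in seq_len(n_saccades)) {
    for (b in seq_len(bins_per_saccade)) {
      bin <- bin + 1L
      ps <- process_step(scene_f, x_true, state$action, retina,
                         noise_x = nx[, bin], noise_s = ns[, bin],
                         n_orders = n_orders)
      x_true <- ps$x_p
      state <- filter_step(spec, state, ps$s_tilde, dt = 1)
      state <- action_step(spec, state, ps$s_tilde, sensitivity, dt = 1)
      gaze_true[bin, ] <- x_true
      gaze_inferred[bin, ] <- state$mu_x[1:2, 1L]
      actions[bin, ] <- state$action
      posterior[bin, ] <- softmax(state$mu_x[2L + seq_len(N), 1L])
      free_energy[bin] <- state$free_energy
    }
    S_raw <- salience_map(spec, state, grid_side = grid_side)
    ior <- apply_inhibition_of_return(S_raw, R_ior)
    R_ior <- ior$R_new
    maps[[sac]] <- ior$S_final
    fixations[sac, ] <- ior$argmax_location
    entropy[sac] <- entropy_nats(posterior[bin, ])
    Pi <- conditional_precision(spec, state$mu_x[, 1L], state$mu_u[, 1L],
                                which_x = 2L + seq_len(N))
    ci_halfwidth[sac, ] <- stats::qnorm(0.95) * sqrt(diag(solve(Pi)))
    # reset the prior expectation about the fixation attractor
    spec$eta_u <- gen_vec(ior$argmax_location, n_orders)
  }

  structure(list(
    gaze_true = gaze_true, gaze_inferred = gaze_inferred, action = actions,
    posterior = posterior, free_energy = free_energy,
    fixations = fixations, salience_maps = maps, ior_memory = R_ior,
    entropy = entropy, ci_halfwidth = ci_halfwidth,
    n_saccades = n_saccades, bins_per_saccade = bins_per_saccade,
    final_state = state, spec = spec
  ), class = "saccade_trace")
}

#' @export
print.saccade_trace <- function(x, ...) {
  n <- nrow(x$posterior)
  cat(sprintf("Saccadic search: %d saccades x %d bins\n",
              x$n_saccades, x$bins_per_saccade))
  cat("  final hypothesis posterior:",
      paste(sprintf("%.3f", x$posterior[n, ]), collapse = " "), "\n")
  cat("  per-saccade entropy:",
      paste(sprintf("%.3f", x$entropy), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.saccade_trace <- function(object, ...) {
  n <- nrow(object$posterior)
  out <- list(
    fixations = object$fixations,
    final_posterior = object$posterior[n, ],
    entropy = object$entropy,
    winner = which.max(object$posterior[n, ])
  )
  class(out) <- "summary.saccade_trace"
  out
}

#' @export
print.summary.saccade_trace <- function(x, ...) {
  cat("Fixations (x, y):\n"); print(round(x$fixations, 3))
  cat("Final posterior:", paste(sprintf("%.3f", x$final_posterior), collapse = " "), "\n")
  cat("Winning hypothesis:", x$winner, "\n")
  invisible(x)
}

#' @export
plot.saccade_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$gaze_true[, 1L], x$gaze_true[, 2L], type = "l", xlim = c(-1, 1),
       ylim = c(-1, 1), xlab = "x", ylab = "y", main = "gaze path")
  graphics::points(x$fixations[, 1L], x$fixations[, 2L], col = "red", pch = 19)
  graphics::matplot(x$posterior, type = "l", lty = 1, xlab = "time bin",
                    ylab = "softmax posterior", main = "hypotheses")
  invisible(x)
}

#' @export
as.data.frame.saccade_trace <- function(x, ...) {
  n <- nrow(x$posterior)
  df <- data.frame(
    bin = seq_len(n),
    saccade = rep(seq_len(x$n_saccades), each = x$bins_per_saccade),
    gaze_x_true = x$gaze_true[, 1L], gaze_y_true = x$gaze_true[, 2L],
    gaze_x_inferred = x$gaze_inferred[, 1L], gaze_y_inferred = x$gaze_inferred[, 2L],
    action_x = x$action[, 1L], action_y = x$action[, 2L],
    free_energy = x$free_energy
  )
  post <- as.data.frame(x$posterior)
  names(post) <- paste0("posterior_", seq_len(ncol(post)))
  cbind(df, post)
}
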