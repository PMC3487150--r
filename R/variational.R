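# Mean-field variational updates, free energy, action selection, and the
# perception-action episode loop for the discrete scheme.

# Precompute the (floored) logarithms used by the updates; cached across an
# episode because they dominate the cost for large state spaces.
model_logs <- function(model) {
  list(lnA = logp(model$A),
       lnB = lapply(model$B, logp),
       lnc = logp(model$c),
       lnd = logp(model$d))
}

# One or more full coordinate-ascent sweeps. Observed-time beliefs stay
# clamped to their normalized likelihood columns (for an identity likelihood
# these are exact posteriors, and clamping keeps the forward anchor hard) and
# alpha_T stays clamped to the terminal prior c. Sweeps run t = T-1 ... 0:
# hidden-state beliefs are updated for unobserved times, and the control
# belief of the adjacent transition t + 1 is updated at every t (so all of
# beta_1 ... beta_T are visited once per sweep). Every update is an exact
# coordinate-ascent step on the variational free energy, so the free energy
# cannot increase within or across sweeps.
vb_engine <- function(model, observations, alpha, beta, n_iterations, logs,
                      tol = 0) {
  Tn <- model$horizon
  nu <- model$n_controls
  k <- length(observations) - 1L
  lnB <- logs$lnB; lnd <- logs$lnd

  # enforce the clamps: observed times hold their normalized likelihood
  # columns (beliefs may carry over from before the observation arrived) and
  # the final time holds the terminal prior
  if (k >= 0L) {
    for (t in 0:min(k, Tn - 1L)) {
      lik <- model$A[observations[t + 1L], ]
      if (sum(lik) <= 0) {
        stop(sprintf("observation at t = %d has zero likelihood", t), call. = FALSE)
      }
      alpha[t + 1L, ] <- lik / sum(lik)
    }
  }
  alpha[Tn + 1L, ] <- model$c

  for (it in seq_len(n_iterations)) {
    max_delta <- 0
    # alternate sweep direction so that both the backward message from the
    # terminal prior and the forward message from the observed prefix
    # propagate through the whole horizon within a pair of sweeps
    times <- if (it %% 2L == 1L) (Tn - 1L):0L else 0L:(Tn - 1L)
    for (t in times) {
      if (t > k) {
        l <- numeric(model$n_states)
        a_next <- alpha[t + 2L, ]
        b_next <- beta[t + 1L, ]
        for (j in seq_len(nu)) {
          if (b_next[j] > 0) l <- l + b_next[j] * as.numeric(lnB[[j]] %*% a_next)
        }
        if (t >= 1L) {
          a_prev <- alpha[t, ]
          b_here <- beta[t, ]
          for (j in seq_len(nu)) {
            if (b_here[j] > 0) l <- l + b_here[j] * as.numeric(crossprod(lnB[[j]], a_prev))
          }
        }
        if (any(!is.finite(l))) {
          stop(sprintf("zero normalizer in alpha update at t = %d", t), call. = FALSE)
        }
        a_new <- norm_exp(l)
        max_delta <- max(max_delta, max(abs(a_new - alpha[t + 1L, ])))
        alpha[t + 1L, ] <- a_new
      }

      # control belief for the transition linking times t and t + 1
      lb <- vapply(seq_len(nu), function(i) {
        as.numeric(alpha[t + 1L, ] %*% lnB[[i]] %*% alpha[t + 2L, ])
      }, numeric(1)) + lnd
      if (any(!is.finite(lb))) {
        stop(sprintf("zero normalizer in beta update at t = %d", t + 1L), call. = FALSE)
      }
      b_new <- norm_exp(lb)
      max_delta <- max(max_delta, max(abs(b_new - beta[t + 1L, ])))
      beta[t + 1L, ] <- b_new
    }
    if (tol > 0 && max_delta < tol) break
  }
  list(alpha = alpha, beta = beta)
}

#' Variational belief updates for the discrete scheme
#'
#' Runs full sweeps of the mean-field coordinate-ascent updates for the
#' sufficient statistics of the factorized posterior over hidden states and
#' controls. Within a sweep, times are visited from `T - 1` down to `0`: the
#' hidden-state belief is updated at unobserved times (each update mixes the
#' backward message from the terminal prior with the forward message from the
#' preceding belief, weighted by the current control beliefs), and the control
#' belief of the adjacent transition is updated at every time; each updated
#' vector is renormalized. Beliefs at observed times stay clamped to their
#' normalized likelihood columns (exact posteriors when the likelihood is the
#' identity), and the belief at the final time stays clamped to the terminal
#' prior `c`, which keeps the goal constraint hard.
#'
#' Each update is an exact coordinate-ascent step on the variational free
#' energy, so [discrete_free_energy()] is non-increasing across sweeps.
#'
#' @param model a [discrete_model()].
#' @param observations integer observation indices at times `0 ... k`
#'   (`k < T`; may be empty).
#' @param beliefs a [beliefs()] object; defaults to [init_beliefs()].
#' @param n_iterations number of full sweeps.
#' @param tol optional early-stopping threshold on the maximum absolute belief
#'   change within a sweep (`0` disables early stopping).
#' @return The updated [beliefs()] object.
#' @export
variational_sweep <- function(model, observations = integer(0), beliefs = NULL,
                              n_iterations = 8, tol = 0) {
  if (is.null(beliefs)) beliefs <- init_beliefs(model, observations)
  observations <- as.integer(observations)
  if (length(observations) > model$horizon) {
    stop("observations must cover at most times 0 ... T - 1", call. = FALSE)
  }
  res <- vb_engine(model, observations, beliefs$alpha, beliefs$beta,
                   n_iterations, model_logs(model), tol = tol)
  beliefs(res$alpha, res$beta)
}

#' Variational free energy of discrete beliefs
#'
#' Evaluates the free energy `F = E_Q[-ln P(s, x, u | m)] - H[Q]` of a
#' mean-field belief set: the Gibbs energy expected under the factorized
#' conditional distribution minus that distribution's entropy. By the Gibbs
#' inequality `F` is an upper bound on the surprise `-ln P(s | m)` of the
#' observed prefix, with equality gap equal to the Kullback-Leibler divergence
#' from the exact posterior.
#'
#' @inheritParams variational_sweep
#' @param beliefs a [beliefs()] object.
#' @return The free energy in nats (a scalar).
#' @export
discrete_free_energy <- function(model, beliefs, observations = integer(0)) {
  observations <- as.integer(observations)
  alpha <- beliefs$alpha
  beta <- beliefs$beta
  Tn <- model$horizon
  logs <- model_logs(model)

  e_logp <- 0
  if (length(observations)) {
    for (t in seq_along(observations)) {
      e_logp <- e_logp + sum(alpha[t, ] * logs$lnA[observations[t], ])
    }
  }
  a_T <- alpha[Tn + 1L, ]
  e_logp <- e_logp + sum(a_T[a_T > 0] * logs$lnc[a_T > 0])
  for (t in seq_len(Tn)) {
    for (i in seq_len(model$n_controls)) {
      if (beta[t, i] > 0) {
        e_logp <- e_logp + beta[t, i] *
          as.numeric(alpha[t, ] %*% logs$lnB[[i]] %*% alpha[t + 1L, ])
      }
    }
    b <- beta[t, ]
    e_logp <- e_logp + sum(b[b > 0] * logs$lnd[b > 0])
  }

  H <- sum(apply(alpha, 1L, entropy_nats)) + sum(apply(beta, 1L, entropy_nats))
  -e_logp - H
}

#' Select the next action from current beliefs
#'
#' Active-inference action selection for the agency-based scheme: the action
#' whose sampled next observation has the highest expected log-likelihood
#' under the belief about the next hidden state,
#' `argmax_a sum_{s'} R(s'|s_now, a) E_{alpha_{k+1}}[ln A(s'|x)]`.
#' With an identity likelihood this picks the action whose sampling
#' distribution best matches the predicted next-state marginal.
#'
#' @param beliefs a [beliefs()] object updated through time `k`.
#' @param k current time index (0-based; the action moves the agent to
#'   `k + 1`).
#' @param R list of sampling-kernel matrices per action (columns = current
#'   observation).
#' @param A observation likelihood matrix.
#' @param s_now current observation index.
#' @return The selected action index (ties broken to the lowest index).
#' @export
select_control_action <- function(beliefs, k, R, A, s_now) {
  if (!is.list(R)) R <- list(R)
  Tn <- nrow(beliefs$alpha) - 1L
  if (k + 1L > Tn) stop("k + 1 exceeds the model horizon", call. = FALSE)
  a_next <- beliefs$alpha[k + 2L, ]
  ell <- as.numeric(logp(as.matrix(A)) %*% a_next)
  scores <- vapply(seq_along(R), function(a) {
    ra <- R[[a]][, s_now]
    if (sum(ra) <= 0) {
      stop(sprintf("sampling kernel has no reachable observation for action %d", a),
           call. = FALSE)
    }
    sum(ra * ell)
  }, numeric(1))
  which.max(scores)
}

#' Run a closed-loop discrete active-inference episode
#'
#' Alternates perception and action for `T` steps: at each time `k` the
#' variational updates are repeated `n_sweeps_per_step` times given the
#' observations so far, an action is selected with
#' [select_control_action()], and the environment returns the next
#' observation from the sampling kernel `R` — either the modal next
#' observation (default, reproducible) or a draw from the kernel.
#'
#' @param model a [discrete_model()].
#' @param R list of sampling-kernel matrices per action.
#' @param start_state initial hidden-state index; the initial observation is
#'   the modal (or sampled) observation under `A` at this state.
#' @param n_sweeps_per_step variational sweeps between actions (default 8).
#' @param mode `"modal"` propagates the most probable next observation;
#'   `"sampled"` draws it (requires `seed`).
#' @param seed integer seed for `"sampled"` mode and a stochastic initial
#'   observation.
#' @param coords optional `n_states x 2` matrix of continuous coordinates per
#'   state (e.g., position and velocity); when supplied, the trace records the
#'   expected coordinates of the anticipated trajectory at every step.
#' @return An object of class `episode_trace` with elements `states`,
#'   `observations` (indices at times `0 ... T`), `actions` (at times
#'   `1 ... T`), `free_energy` (per planning step), `beliefs` (final
#'   beliefs), `anticipated` (list of `(T + 1) x 2` expected-coordinate
#'   matrices per step, if `coords` given), and `coords`.
#' @export
run_episode <- function(model, R, start_state, n_sweeps_per_step = 8,
                        mode = c("modal", "sampled"), seed = NULL,
                        coords = NULL) {
  mode <- match.arg(mode)
  if (!is.list(R)) R <- list(R)
  Tn <- model$horizon
  if (start_state < 1L || start_state > model$n_states) {
    stop("start_state out of range", call. = FALSE)
  }
  if (mode == "sampled") {
    if (is.null(seed)) stop("sampled mode requires a seed", call. = FALSE)
    set.seed(as.integer(seed))
  }
  draw <- function(p) {
    if (mode == "modal") which.max(p) else sample.int(length(p), 1L, prob = p)
  }

  logs <- model_logs(model)
  observations <- integer(Tn + 1L)
  actions <- integer(Tn)
  free_energy <- numeric(Tn)
  observations[1L] <- draw(model$A[, start_state])
  bel <- init_beliefs(model, observations[1L])
  anticipated <- if (!is.null(coords)) vector("list", Tn) else NULL

  for (k in 0:(Tn - 1L)) {
    obs_now <- observations[seq_len(k + 1L)]
    res <- vb_engine(model, obs_now, bel$alpha, bel$beta, n_sweeps_per_step, logs)
    bel <- beliefs(res$alpha, res$beta)
    free_energy[k + 1L] <- discrete_free_energy(model, bel, obs_now)
    if (!is.null(coords)) anticipated[[k + 1L]] <- bel$alpha %*% coords
    a <- select_control_action(bel, k, R, model$A, observations[k + 1L])
    actions[k + 1L] <- a
    observations[k + 2L] <- draw(R[[a]][, observations[k + 1L]])
  }

  structure(
    list(states = observations, observations = observations, actions = actions,
         free_energy = free_energy, beliefs = bel, anticipated = anticipated,
         coords = coords, mode = mode, n_sweeps_per_step = n_sweeps_per_step),
    class = "episode_trace"
  )
}

#' @export
print.episode_trace <- function(x, ...) {
  Tn <- length(x$actions)
  cat(sprintf("Active-inference episode: %d steps (%s mode, %d sweeps/step)\n",
              Tn, x$mode, x$n_sweeps_per_step))
  if (!is.null(x$coords)) {
    xy <- x$coords[x$states[Tn + 1L], ]
    cat(sprintf("  final state %d at (%.4g, %.4g)\n", x$states[Tn + 1L], xy[1], xy[2]))
  } else {
    cat(sprintf("  final state %d\n", x$states[Tn + 1L]))
  }
  cat(sprintf("  final-step free energy: %.4f nats\n", x$free_energy[Tn]))
  invisible(x)
}

#' @export
as.data.frame.episode_trace <- function(x, ...) {
  Tn <- length(x$actions)
  pos <- vel <- rep(NA_real_, Tn + 1L)
  if (!is.null(x$coords)) {
    pos <- x$coords[x$states, 1L]
    vel <- x$coords[x$states, 2L]
  }
  data.frame(
    time = 0:Tn,
    state_index = x$states,
    position = pos,
    velocity = vel,
    observation = x$observations,
    action = c(NA_integer_, x$actions),
    free_energy = c(NA_real_, x$free_energy)
  )
}

#' @export
plot.episode_trace <- function(x, ...) {
  if (is.null(x$coords)) {
    plot(seq_along(x$free_energy), x$free_energy, type = "b",
         xlab = "step", ylab = "free energy (nats)", ...)
    return(invisible(x))
  }
  xy <- x$coords[x$states, , drop = FALSE]
  plot(x$coords[, 1L], x$coords[, 2L], pch = ".", col = "grey80",
       xlab = "position", ylab = "velocity", ...)
  if (!is.null(x$anticipated)) {
    for (tr in x$anticipated) graphics::lines(tr[, 1L], tr[, 2L], col = "grey60")
  }
  graphics::lines(xy[, 1L], xy[, 2L], lty = 3)
  graphics::points(xy[, 1L], xy[, 2L], pch = 19, cex = 0.6)
  graphics::points(xy[1L, 1L], xy[1L, 2L], pch = 1, cex = 1.4)
  graphics::points(xy[nrow(xy), 1L], xy[nrow(xy), 2L], pch = 17, col = "red")
  invisible(x)
}
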