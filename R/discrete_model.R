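#' Discrete generative model with pullback transitions and a terminal prior
#'
#' Constructs the generative model used by the discrete (agency-based)
#' planning-as-inference scheme. The model specifies a likelihood `A` mapping
#' hidden states to observations, one *pullback* transition matrix `B[[k]]`
#' per control level (mapping the state at time `t` to a distribution over the
#' state at time `t - 1`, so that the prior over a state sequence is anchored
#' on its final state), a prior `c` over the final (goal) hidden state, a
#' prior `d` over control states, and a horizon `T`. Costs are absorbed into
#' `c` and `d`: a desired terminal state is simply one with high prior mass.
#'
#' All matrices are column-stochastic: column `j` of `A` is the distribution
#' over observations given hidden state `j`, and column `j` of `B[[k]]` is the
#' distribution over the *previous* hidden state given current state `j` under
#' control `k`.
#'
#' @param A observation likelihood matrix (observations x hidden states),
#'   column-stochastic.
#' @param B list of pullback transition matrices, one per control level, each
#'   (hidden states x hidden states) and column-stochastic.
#' @param c prior probability vector over the final hidden state.
#' @param d prior probability vector over control states (one entry per
#'   element of `B`).
#' @param horizon number of transitions `T`; the model covers times
#'   `t = 0 ... T` with controls at `t = 1 ... T`.
#' @return An object of class `discrete_model`.
#' @seealso [variational_sweep()], [run_episode()], [exact_smoother()]
#' @export
discrete_model <- function(A, B, c, d, horizon) {
  A <- as.matrix(A)
  if (!is.list(B)) B <- list(B)
  B <- lapply(B, as.matrix)
  c <- as.numeric(c)
  d <- as.numeric(d)
  horizon <- as.integer(horizon)

  n_states <- ncol(A)
  assert_column_stochastic(A, "A")
  for (k in seq_along(B)) {
    if (!all(dim(B[[k]]) == n_states)) {
      stop(sprintf("B[[%d]] must be %d x %d", k, n_states, n_states), call. = FALSE)
    }
    assert_column_stochastic(B[[k]], sprintf("B[[%d]]", k))
  }
  if (length(c) != n_states) stop("length(c) must equal the number of hidden states", call. = FALSE)
  if (length(d) != length(B)) stop("length(d) must equal the number of control levels", call. = FALSE)
  stopifnot_prob_vector(c, "c")
  stopifnot_prob_vector(d, "d")
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)

  structure(
    list(A = A, B = B, c = c, d = d, horizon = horizon,
         n_states = n_states, n_obs = nrow(A), n_controls = length(B)),
    class = "discrete_model"
  )
}

#' @export
print.discrete_model <- function(x, ...) {
  cat("Discrete active-inference generative model\n")
  cat(sprintf("  hidden states : %d\n", x$n_states))
  cat(sprintf("  observations  : %d\n", x$n_obs))
  cat(sprintf("  control levels: %d\n", x$n_controls))
  cat(sprintf("  horizon T     : %d\n", x$horizon))
  cat(sprintf("  terminal prior: %s\n",
              if (sum(x$c > 0) == 1) sprintf("delta at state %d", which(x$c > 0))
              else sprintf("%d states with mass", sum(x$c > 0))))
  invisible(x)
}

#' Mean-field beliefs over hidden states and controls
#'
#' Container for the sufficient statistics of the factorized conditional
#' distribution: one probability vector `alpha[t, ]` over hidden states for
#' each time `t = 0 ... T` (rows `1 ... T + 1`) and one probability vector
#' `beta[t, ]` over controls for each transition `t = 1 ... T`.
#'
#' @param alpha `(T + 1) x n_states` matrix, rows summing to one.
#' @param beta `T x n_controls` matrix, rows summing to one.
#' @return An object of class `beliefs`.
#' @export
beliefs <- function(alpha, beta) {
  alpha <- as.matrix(alpha)
  beta <- as.matrix(beta)
  for (t in seq_len(nrow(alpha))) stopifnot_prob_vector(alpha[t, ], sprintf("alpha[%d,]", t))
  for (t in seq_len(nrow(beta))) stopifnot_prob_vector(beta[t, ], sprintf("beta[%d,]", t))
  if (nrow(alpha) != nrow(beta) + 1L) {
    stop("alpha must have one more row than beta (times 0..T vs 1..T)", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "beliefs")
}

#' @export
print.beliefs <- function(x, ...) {
  cat(sprintf("Mean-field beliefs: %d time points, %d hidden states, %d controls\n",
              nrow(x$alpha), ncol(x$alpha), ncol(x$beta)))
  invisible(x)
}

#' Initialize beliefs for a model and an observation prefix
#'
#' Starting values for the variational updates: `alpha[t, ]` is the normalized
#' likelihood column for observed times (`t <= k`), uniform for unobserved
#' intermediate times, and clamped to the terminal prior `c` at `t = T`;
#' `beta[t, ]` starts at the control prior `d`.
#'
#' @param model a [discrete_model()].
#' @param observations integer vector of observation indices at times
#'   `t = 0 ... k` (may be empty).
#' @return A [beliefs()] object.
#' @export
init_beliefs <- function(model, observations = integer(0)) {
  Tn <- model$horizon
  n <- model$n_states
  observations <- as.integer(observations)
  if (length(observations) > Tn + 1L) stop("more observations than time points", call. = FALSE)
  if (length(observations) && (any(observations < 1L) || any(observations > model$n_obs))) {
    stop("observation index out of range", call. = FALSE)
  }
  alpha <- matrix(1 / n, Tn + 1L, n)
  if (length(observations)) {
    for (t in seq_along(observations)) {
      if (t <= Tn) { # t - 1 in 0..T-1; time T stays clamped to c below
        lik <- model$A[observations[t], ]
        if (sum(lik) <= 0) stop(sprintf("observation at t=%d has zero likelihood", t - 1L), call. = FALSE)
        alpha[t, ] <- lik / sum(lik)
      }
    }
  }
  alpha[Tn + 1L, ] <- model$c
  beta <- matrix(rep(model$d, each = Tn), Tn, model$n_controls)
  beliefs(alpha, beta)
}
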