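#' Finite-horizon value iteration (backward induction)
#'
#' Solves a finite-horizon, undiscounted Markov decision process exactly by
#' backward induction on the Bellman optimality equation
#' `V_t(x) = r(x) + max_a sum_{x'} T(x'|x, a) V_{t+1}(x')`, with
#' `V_H(x) = r(x)` at the horizon. Used in this package as a verification
#' oracle for the active-inference action rules, not as a control law.
#'
#' @param Tr list of forward transition matrices, one per action; column `j`
#'   of `Tr[[a]]` is the distribution over next states given current state `j`
#'   (column-stochastic).
#' @param r numeric reward vector over states.
#' @param horizon integer number of transitions (`>= 1`).
#' @return A list with `V`, a `(horizon + 1) x n_states` matrix of values
#'   (`V[t + 1, ]` is the value with `horizon - t` transitions remaining), and
#'   `policy`, a `horizon x n_states` matrix of optimal action indices at
#'   times `t = 0 ... horizon - 1` (ties broken to the lowest action index).
#' @export
value_iteration <- function(Tr, r, horizon) {
  if (!is.list(Tr)) Tr <- list(Tr)
  Tr <- lapply(Tr, as.matrix)
  r <- as.numeric(r)
  horizon <- as.integer(horizon)
  n <- length(r)
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  for (a in seq_along(Tr)) {
    if (!all(dim(Tr[[a]]) == n)) {
      stop(sprintf("Tr[[%d]] dimensions do not match length(r) = %d", a, n), call. = FALSE)
    }
    assert_column_stochastic(Tr[[a]], sprintf("Tr[[%d]]", a))
  }
  if (any(!is.finite(r))) stop("rewards must be finite", call. = FALSE)

  V <- matrix(0, horizon + 1L, n)
  policy <- matrix(NA_integer_, horizon, n)
  V[horizon + 1L, ] <- r
  for (t in horizon:1L) {
    # Q[a, x] = expected value of V_{t+1} after action a in state x
    Q <- t(vapply(Tr, function(M) as.numeric(crossprod(M, V[t + 1L, ])), numeric(n)))
    best <- apply(Q, 2L, which.max)  # which.max takes the first (lowest) index on ties
    V[t, ] <- r + Q[cbind(best, seq_len(n))]
    policy[t, ] <- best
  }
  list(V = V, policy = policy)
}

#' Action selection without explicit beliefs about agency
#'
#' The agency-free active-inference action rule: choose the action whose
#' sampled observation is expected to be least surprising under the policy-
#' propagated posterior, i.e.
#' `argmax_a sum_{s'} R(s'|s, a) E_{Q(x')}[ln P(s'|x')]`, where
#' `Q(x') = sum_x T(x'|x, pi(x)) posterior(x)` is the posterior predictive over
#' the next hidden state under the optimal policy embodied in the transition
#' prior. When the policy is Bellman-optimal this selects exactly the same
#' action as the optimal policy.
#'
#' @param posterior_x probability vector over current hidden states.
#' @param policy integer vector mapping each state to an action index (e.g.,
#'   one row of the `policy` matrix from [value_iteration()]).
#' @param Tr list of forward transition matrices per action (column-stochastic,
#'   columns = current state).
#' @param A observation likelihood matrix (observations x states).
#' @param R list of sampling-kernel matrices per action; column `s` of
#'   `R[[a]]` is the distribution over the next observation given current
#'   observation `s`.
#' @param s_now current observation index.
#' @return The selected action index (ties broken to the lowest index).
#' @export
agency_free_action <- function(posterior_x, policy, Tr, A, R, s_now) {
  posterior_x <- as.numeric(posterior_x)
  stopifnot_prob_vector(posterior_x, "posterior_x")
  if (!is.list(Tr)) Tr <- list(Tr)
  if (!is.list(R)) R <- list(R)
  A <- as.matrix(A)
  policy <- as.integer(policy)
  n <- length(posterior_x)
  if (length(policy) != n) stop("policy must map every state to an action", call. = FALSE)

  # posterior predictive over next hidden state under the policy
  q_next <- numeric(n)
  for (x in seq_len(n)) {
    if (posterior_x[x] > 0) {
      q_next <- q_next + posterior_x[x] * Tr[[policy[x]]][, x]
    }
  }
  # expected log-likelihood of each candidate observation under Q(x')
  ell <- as.numeric(logp(A) %*% q_next)

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

#' Exact posterior marginals by enumeration
#'
#' Brute-force oracle for the discrete scheme: enumerates every joint sequence
#' of hidden states and controls, accumulates the exact joint probability
#' under the pullback generative model together with the likelihood of the
#' observed prefix, and returns the exact per-time marginals and log evidence.
#' Intended for tiny models only; enumeration is guarded.
#'
#' @param model a [discrete_model()].
#' @param observations integer vector of observation indices at times
#'   `t = 0 ... k` (may be empty).
#' @param max_sequences guard on `n_states^(T+1) * n_controls^T`.
#' @return A list with `alpha` (`(T + 1) x n_states` exact marginals), `beta`
#'   (`T x n_controls` exact marginals), and `log_evidence` (`ln P(s|m)`;
#'   `0` when there are no observations).
#' @export
exact_smoother <- function(model, observations = integer(0), max_sequences = 1e6) {
  Tn <- model$horizon
  n <- model$n_states
  nu <- model$n_controls
  observations <- as.integer(observations)
  n_seq <- as.numeric(n)^(Tn + 1) * as.numeric(nu)^Tn
  if (n_seq > max_sequences) {
    stop(sprintf("enumeration guard exceeded: %.3g sequences > %g", n_seq, max_sequences),
         call. = FALSE)
  }
  k <- length(observations) - 1L  # observations at t = 0..k

  xs <- as.matrix(expand.grid(rep(list(seq_len(n)), Tn + 1L)))
  us <- as.matrix(expand.grid(rep(list(seq_len(nu)), Tn)))
  alpha <- matrix(0, Tn + 1L, n)
  beta <- matrix(0, Tn, nu)
  Z <- 0
  for (i in seq_len(nrow(xs))) {
    x <- xs[i, ]
    p_x_base <- model$c[x[Tn + 1L]]
    if (k >= 0L) {
      for (t in 0:k) p_x_base <- p_x_base * model$A[observations[t + 1L], x[t + 1L]]
    }
    if (p_x_base == 0) next
    for (j in seq_len(nrow(us))) {
      u <- us[j, ]
      p <- p_x_base
      for (t in seq_len(Tn)) {
        p <- p * model$B[[u[t]]][x[t], x[t + 1L]] * model$d[u[t]]
        if (p == 0) break
      }
      if (p == 0) next
      Z <- Z + p
      for (t in seq_len(Tn + 1L)) alpha[t, x[t]] <- alpha[t, x[t]] + p
      for (t in seq_len(Tn)) beta[t, u[t]] <- beta[t, u[t]] + p
    }
  }
  if (Z <= 0) stop("observed sequence has zero probability under the model", call. = FALSE)
  list(alpha = alpha / Z, beta = beta / Z, log_evidence = log(Z))
}
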