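# Generalized (predictive-coding) filtering: precision-weighted prediction
# errors, free-energy gradient flows on generalized coordinates, reflex-arc
# action, and Laplace conditional precision.

#' Specify a generative model for generalized filtering
#'
#' A single-level dynamic generative model: hidden states `x` with flow
#' `dx/dt = f(x, u) + noise`, hidden control states `u` drawn toward a static
#' prior expectation, and observations `s = g(x, u) + noise`. All random
#' fluctuations are Gaussian with precisions given on the log scale
#' (per-channel vectors or scalars, exponentiated once at construction).
#'
#' @param f flow function `f(x, u) -> numeric(n_x)`.
#' @param g observation function `g(x, u) -> numeric(n_s)`.
#' @param n_x,n_u,n_s dimensions of hidden states, control states, and
#'   sensory channels (`n_x` or `n_u` may be 0).
#' @param log_precisions list with entries `sensory` (length `n_s` or scalar),
#'   `states` (length `n_x` or scalar), and `control` (length `n_u` or
#'   scalar).
#' @param control_prior prior expectation for the control states: a vector
#'   (order 0) or matrix in generalized coordinates.
#' @param f_jac,g_jac optional analytic Jacobians, called as `(x, u)` and
#'   returning `list(x = d/dx, u = d/du)` matrices; finite-differenced when
#'   omitted.
#' @param n_orders number of generalized orders of motion (default 3).
#' @return An object of class `level_spec`.
#' @export
level_spec <- function(f, g, n_x, n_u, n_s,
                       log_precisions = list(sensory = 0, states = 0, control = 0),
                       control_prior = NULL,
                       f_jac = NULL, g_jac = NULL, n_orders = 3) {
  n_x <- as.integer(n_x); n_u <- as.integer(n_u); n_s <- as.integer(n_s)
  if (n_s < 1L) stop("need at least one sensory channel", call. = FALSE)
  expand <- function(lp, n) {
    lp <- as.numeric(lp)
    if (length(lp) == 1L) lp <- rep(lp, n)
    if (length(lp) != n) stop("log-precision length mismatch", call. = FALSE)
    lp
  }
  pi_v <- exp(expand(log_precisions$sensory %||% 0, n_s))
  pi_x <- exp(expand(log_precisions$states %||% 0, n_x))
  pi_u <- exp(expand(log_precisions$control %||% 0, n_u))
  if (is.null(control_prior)) control_prior <- rep(0, n_u)
  eta_u <- gen_vec(control_prior, n_orders)
  if (nrow(eta_u) != n_u) stop("control_prior dimension mismatch", call. = FALSE)

  fd_jac <- function(fun, n_out) function(x, u) {
    h <- 1e-6
    jx <- matrix(0, n_out, length(x))
    if (length(x)) for (i in seq_along(x)) {
      e <- x; e[i] <- e[i] + h
      e2 <- x; e2[i] <- e2[i] - h
      jx[, i] <- (fun(e, u) - fun(e2, u)) / (2 * h)
    }
    ju <- matrix(0, n_out, length(u))
    if (length(u)) for (i in seq_along(u)) {
      e <- u; e[i] <- e[i] + h
      e2 <- u; e2[i] <- e2[i] - h
      ju[, i] <- (fun(x, e) - fun(x, e2)) / (2 * h)
    }
    list(x = jx, u = ju)
  }
  if (is.null(f_jac)) f_jac <- fd_jac(f, n_x)
  if (is.null(g_jac)) g_jac <- fd_jac(g, n_s)

  structure(list(f = f, g = g, n_x = n_x, n_u = n_u, n_s = n_s,
                 pi_v = pi_v, pi_x = pi_x, pi_u = pi_u,
                 eta_u = eta_u, f_jac = f_jac, g_jac = g_jac,
                 n_orders = as.integer(n_orders)),
            class = "level_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize a filter state
#'
#' @param spec a [level_spec()].
#' @param mu_x,mu_u starting expectations (order-0 vectors or generalized
#'   matrices); zero by default.
#' @param n_action number of action channels (default 0).
#' @return An object of class `filter_state` with generalized expectations
#'   `mu_x`, `mu_u`, the `action` vector, and `free_energy = NA` until the
#'   first evaluation.
#' @export
filter_state <- function(spec, mu_x = NULL, mu_u = NULL, n_action = 0) {
  n <- spec$n_orders
  structure(list(
    mu_x = gen_vec(mu_x %||% rep(0, spec$n_x), n),
    mu_u = gen_vec(mu_u %||% rep(0, spec$n_u), n),
    action = rep(0, n_action),
    free_energy = NA_real_
  ), class = "filter_state")
}

#' @export
print.filter_state <- function(x, ...) {
  cat(sprintf("Generalized filter state: %d hidden, %d control (%d orders); F = %s\n",
              nrow(x$mu_x), nrow(x$mu_u), ncol(x$mu_x),
              ifelse(is.na(x$free_energy), "unset", sprintf("%.4f", x$free_energy))))
  invisible(x)
}

# evaluate a model function in generalized coordinates by the first-order
# chain rule: order 0 exactly, higher orders through the Jacobians at order 0
gen_eval <- function(fun, jac, mu_x, mu_u, n_out) {
  n <- ncol(mu_x)
  out <- matrix(0, n_out, n)
  x0 <- mu_x[, 1L]; u0 <- mu_u[, 1L]
  out[, 1L] <- fun(x0, u0)
  if (n > 1L) {
    J <- jac(x0, u0)
    for (d in 2:n) {
      v <- numeric(n_out)
      if (length(x0)) v <- v + as.numeric(J$x %*% mu_x[, d])
      if (length(u0)) v <- v + as.numeric(J$u %*% mu_u[, d])
      out[, d] <- v
    }
  }
  out
}

#' Precision-weighted prediction errors
#'
#' Evaluates the three prediction errors of the generative model at the
#' current expectations: the sensory error (observations minus predictions),
#' the state error (generalized motion minus the flow), and the control error
#' (control expectations minus their prior), each weighted by its precision.
#' Model functions are evaluated order-by-order with the first-order chain
#' rule, omitting higher-order curvature terms.
#'
#' @param spec a [level_spec()].
#' @param state a [filter_state()].
#' @param s_tilde observations in generalized coordinates (`n_s x n_orders`
#'   matrix, or a vector for order 0 only).
#' @return A list with precision-weighted errors `xi_v`, `xi_x`, `xi_u`, raw
#'   errors `eps_v`, `eps_x`, `eps_u`, predictions `g_tilde`, `f_tilde`, and
#'   the Gibbs part of the free energy `F` (half the precision-weighted
#'   squared error; constant terms omitted).
#' @export
prediction_errors <- function(spec, state, s_tilde) {
  n <- spec$n_orders
  s_tilde <- gen_vec(s_tilde, n)
  if (nrow(s_tilde) != spec$n_s) stop("observation dimension mismatch", call. = FALSE)
  g_tilde <- gen_eval(spec$g, spec$g_jac, state$mu_x, state$mu_u, spec$n_s)
  f_tilde <- gen_eval(spec$f, spec$f_jac, state$mu_x, state$mu_u, spec$n_x)

  eps_v <- s_tilde - g_tilde
  eps_x <- gen_shift(state$mu_x) - f_tilde
  eps_u <- state$mu_u - spec$eta_u
  xi_v <- eps_v * spec$pi_v
  xi_x <- eps_x * spec$pi_x
  xi_u <- eps_u * spec$pi_u
  F <- 0.5 * (sum(eps_v * xi_v) + sum(eps_x * xi_x) + sum(eps_u * xi_u))
  list(xi_v = xi_v, xi_x = xi_x, xi_u = xi_u,
       eps_v = eps_v, eps_x = eps_x, eps_u = eps_u,
       g_tilde = g_tilde, f_tilde = f_tilde, F = F)
}

# free-energy gradient flow of the stacked expectations:
# mu_dot = D mu - dF/dmu, assembled from transposed-Jacobian contractions
filter_flow <- function(spec, mu_x, mu_u, s_tilde) {
  st <- list(mu_x = mu_x, mu_u = mu_u)
  pe <- prediction_errors(spec, st, s_tilde)
  J_g <- spec$g_jac(mu_x[, 1L], mu_u[, 1L])
  J_f <- spec$f_jac(mu_x[, 1L], mu_u[, 1L])

  dot_x <- gen_shift(mu_x)
  if (spec$n_x) {
    dot_x <- dot_x + crossprod(J_g$x, pe$xi_v) + crossprod(J_f$x, pe$xi_x) -
      gen_shift_t(pe$xi_x)
  }
  dot_u <- gen_shift(mu_u)
  if (spec$n_u) {
    dot_u <- dot_u + crossprod(J_g$u, pe$xi_v) + crossprod(J_f$u, pe$xi_x) -
      pe$xi_u
  }
  list(dot_x = dot_x, dot_u = dot_u, pe = pe)
}

# Analytic Jacobian of the gradient flow under the local-linearity
# (Gauss-Newton) assumption: with the error maps eps_b = const - M_b mu the
# flow is D mu - sum_b M_b' Pi_b eps_b, whose Jacobian D - sum_b M_b' Pi_b M_b
# has no positive real eigenvalues from omitted second-order curvature --
# which keeps the matrix-exponential integrator stable where the true
# curvature (e.g. of interpolated images) is indefinite.
lls_jacobian <- function(spec, mu_x, mu_u) {
  n <- spec$n_orders
  nx <- spec$n_x; nu <- spec$n_u; ns <- spec$n_s
  mx <- nx * n; m <- mx + nu * n
  J_g <- spec$g_jac(mu_x[, 1L], mu_u[, 1L])
  J_f <- spec$f_jac(mu_x[, 1L], mu_u[, 1L])

  D_mat <- matrix(0, m, m)
  for (d in seq_len(n - 1L)) {
    if (nx) {
      rows <- (d - 1L) * nx + seq_len(nx)
      D_mat[cbind(rows, rows + nx)] <- 1
    }
    if (nu) {
      rows <- mx + (d - 1L) * nu + seq_len(nu)
      D_mat[cbind(rows, rows + nu)] <- 1
    }
  }

  H <- matrix(0, m, m)
  add_block <- function(H, M, pi_b) H + crossprod(M * sqrt(pi_b))
  # sensory errors: M_v per order = [J_g$x, J_g$u]
  M_v <- matrix(0, ns * n, m)
  for (d in seq_len(n)) {
    rows <- (d - 1L) * ns + seq_len(ns)
    if (nx) M_v[rows, (d - 1L) * nx + seq_len(nx)] <- J_g$x
    if (nu) M_v[rows, mx + (d - 1L) * nu + seq_len(nu)] <- J_g$u
  }
  H <- add_block(H, M_v, rep(spec$pi_v, n))
  # state errors: M_x per order = shift - [J_f$x, J_f$u]
  if (nx) {
    M_x <- matrix(0, nx * n, m)
    for (d in seq_len(n)) {
      rows <- (d - 1L) * nx + seq_len(nx)
      M_x[rows, (d - 1L) * nx + seq_len(nx)] <- -J_f$x
      if (nu) M_x[rows, mx + (d - 1L) * nu + seq_len(nu)] <- -J_f$u
      if (d < n) {
        M_x[cbind(rows, d * nx + seq_len(nx))] <-
          M_x[cbind(rows, d * nx + seq_len(nx))] + 1
      }
    }
    H <- add_block(H, M_x, rep(spec$pi_x, n))
  }
  # control-prior errors: identity on the u block
  if (nu) {
    M_u <- matrix(0, nu * n, m)
    M_u[, mx + seq_len(nu * n)] <- diag(nu * n)
    H <- add_block(H, M_u, rep(spec$pi_u, n))
  }
  D_mat - H
}

stack_mu <- function(mu_x, mu_u) c(as.numeric(mu_x), as.numeric(mu_u))
unstack_mu <- function(v, spec) {
  n <- spec$n_orders
  nx <- spec$n_x * n
  list(mu_x = matrix(v[seq_len(nx)], spec$n_x, n),
       mu_u = matrix(v[nx + seq_len(spec$n_u * n)], spec$n_u, n))
}

#' Advance the filter by one time bin
#'
#' Integrates the generalized gradient flow
#' `mu_dot = D mu - dF/dmu` over `dt`. The default integrator is local
#' linearization: the flow Jacobian `J` is evaluated numerically at the
#' current expectations and the update is `(expm(J dt) - I) J^{-1} mu_dot`,
#' which handles the stiffness induced by large precisions. A plain explicit
#' Euler mode with substeps is available as a cross-check.
#'
#' @inheritParams prediction_errors
#' @param dt time-bin length.
#' @param integrator `"lls"` (local linearization, default) or `"euler"`.
#' @param euler_substeps substeps used by the Euler mode.
#' @return The updated [filter_state()] with `free_energy` refreshed.
#' @export
filter_step <- function(spec, state, s_tilde, dt,
                        integrator = c("lls", "euler"), euler_substeps = 8) {
  integrator <- match.arg(integrator)
  n <- spec$n_orders
  s_tilde <- gen_vec(s_tilde, n)
  mu <- stack_mu(state$mu_x, state$mu_u)
  m <- length(mu)
  if (m == 0L) stop("model has no latent variables to filter", call. = FALSE)

  flow_fn <- function(v) {
    parts <- unstack_mu(v, spec)
    fl <- filter_flow(spec, parts$mu_x, parts$mu_u, s_tilde)
    stack_mu(fl$dot_x, fl$dot_u)
  }

  F_of <- function(v) {
    parts <- unstack_mu(v, spec)
    prediction_errors(spec, list(mu_x = parts$mu_x, mu_u = parts$mu_u), s_tilde)$F
  }

  if (integrator == "euler") {
    h <- dt / euler_substeps
    for (i in seq_len(euler_substeps)) mu <- mu + h * flow_fn(mu)
  } else {
    one_lls <- function(v, step) {
      f0 <- flow_fn(v)
      if (any(!is.finite(f0))) return(rep(NaN, m))
      parts <- unstack_mu(v, spec)
      J <- lls_jacobian(spec, parts$mu_x, parts$mu_u)
      dmu <- tryCatch({
        E <- as.matrix(Matrix::expm(Matrix::Matrix(J * step)))
        as.numeric((E - diag(m)) %*% solve(J, f0))
      }, error = function(e) NULL)
      if (is.null(dmu) || any(!is.finite(dmu))) {
        # near-singular Jacobian: ridge it
        dmu <- tryCatch({
          Jr <- J - diag(1e-6, m)
          E <- as.matrix(Matrix::expm(Matrix::Matrix(Jr * step)))
          as.numeric((E - diag(m)) %*% solve(Jr, f0))
        }, error = function(e) rep(NaN, m))
      }
      v + dmu
    }
    bad <- function(v) !all(is.finite(v)) || isTRUE(F_of(v) > F0 + 5)
    # local linearization is exact for a linear flow but can badly overshoot
    # where the observation function's curvature changes within the step
    # (e.g. interpolated images); guard by retrying with substeps whenever a
    # step raises the free energy of the *same* input by more than a few nats
    F0 <- F_of(mu)
    cand <- one_lls(mu, dt)
    if (bad(cand)) {
      for (n_sub in c(4L, 16L)) {
        cand <- mu
        for (i in seq_len(n_sub)) cand <- one_lls(cand, dt / n_sub)
        if (!bad(cand)) break
      }
    }
    mu <- cand
  }
  if (any(!is.finite(mu))) {
    stop(sprintf("filter state diverged (non-finite expectations; F0 = %.3g); check precisions and dt",
                 F_of(stack_mu(state$mu_x, state$mu_u))), call. = FALSE)
  }
  parts <- unstack_mu(mu, spec)
  state$mu_x <- gen_vec(parts$mu_x, n)
  state$mu_u <- gen_vec(parts$mu_u, n)
  state$free_energy <- prediction_errors(spec, state, s_tilde)$F
  state
}

#' Update action through the reflex arc
#'
#' Action descends the free energy through its effect on sensations:
#' `da/dt = -(ds/da)' xi_v`, restricted to the proprioceptive channels whose
#' dependence on action the agent knows. The sensitivity matrix encodes
#' `ds/da` at one generalized order (order 1 by default: action accelerates
#' the sensed states it controls).
#'
#' @inheritParams prediction_errors
#' Because the reflex gain equals the proprioceptive precision (which is
#' typically large), the action dynamics are much faster than a time bin.
#' The update therefore integrates the locally linear reflex ODE exactly over
#' `dt` — relaxing the action toward the value that nulls the error it can
#' null — instead of taking an unstable explicit Euler step.
#'
#' @param sensitivity `n_s x n_action` matrix giving the derivative of each
#'   sensory channel with respect to each action channel (zero rows for
#'   channels action cannot affect).
#' @param dt time-bin length.
#' @param order generalized order at which action enters (default 1).
#' @return The updated [filter_state()] (only `action` changes).
#' @export
action_step <- function(spec, state, s_tilde, sensitivity, dt, order = 1) {
  pe <- prediction_errors(spec, state, s_tilde)
  if (order + 1L > spec$n_orders) stop("order exceeds the embedding order", call. = FALSE)
  a_dot <- -as.numeric(crossprod(sensitivity, pe$xi_v[, order + 1L]))
  if (all(a_dot == 0)) return(state)
  # da/dt = a_dot - K (a - a_now), K = S' Pi S: integrate exactly over dt
  K <- crossprod(sensitivity * sqrt(spec$pi_v))
  delta_eq <- tryCatch(solve(K, a_dot), error = function(e) NULL)
  if (is.null(delta_eq)) {
    state$action <- state$action + dt * a_dot  # rank-deficient reflex: plain step
    return(state)
  }
  E <- as.matrix(Matrix::expm(Matrix::Matrix(-K * dt)))
  state$action <- state$action + as.numeric((diag(nrow(K)) - E) %*% delta_eq)
  state
}

#' Laplace conditional precision (Gauss-Newton curvature)
#'
#' Curvature of the Gibbs energy with respect to a designated subset of
#' order-0 latent variables, under the Gauss-Newton approximation:
#' `Pi = J' Pi_sensory J + prior precision`, where `J` is the observation
#' Jacobian restricted to the designated variables and the prior precision is
#' the state-noise precision (for hidden states) or the control-prior
#' precision (for control states). At a zero-residual point this equals the
#' exact Hessian of the Gibbs energy. The result is symmetrized; a diagonal
#' jitter is added if it is not positive definite.
#'
#' @param spec a [level_spec()].
#' @param mu_x,mu_u order-0 expectations (vectors) at which to evaluate.
#' @param which_x,which_u indices of the hidden-state / control components to
#'   include (default: all hidden states).
#' @param jitter diagonal ridge added only if needed for positive
#'   definiteness.
#' @return The precision matrix over the designated components, with
#'   attribute `"log_det"` holding `log det(Pi)`.
#' @export
conditional_precision <- function(spec, mu_x, mu_u = NULL,
                                  which_x = seq_len(spec$n_x),
                                  which_u = integer(0), jitter = 1e-8) {
  mu_x <- as.numeric(mu_x)
  mu_u <- if (is.null(mu_u)) rep(0, spec$n_u) else as.numeric(mu_u)
  if (!length(which_x) && !length(which_u)) {
    stop("designated subset is empty", call. = FALSE)
  }
  J <- spec$g_jac(mu_x, mu_u)
  Jsub <- cbind(
    if (length(which_x)) J$x[, which_x, drop = FALSE],
    if (length(which_u)) J$u[, which_u, drop = FALSE]
  )
  if (any(!is.finite(Jsub))) stop("non-finite observation Jacobian", call. = FALSE)
  prior <- c(spec$pi_x[which_x], spec$pi_u[which_u])
  Pi <- crossprod(Jsub * sqrt(spec$pi_v)) + diag(prior, length(prior))
  Pi <- (Pi + t(Pi)) / 2
  ev <- eigen(Pi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    Pi <- Pi + diag(jitter - min(ev), nrow(Pi))
  }
  attr(Pi, "log_det") <- as.numeric(determinant(Pi, logarithm = TRUE)$modulus)
  Pi
}
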