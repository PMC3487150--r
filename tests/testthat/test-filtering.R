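test_that("the shift operator implements the generalized motion", {
  v <- gen_vec(cbind(c(1, 2), c(3, 4), c(5, 6)), 3)
  s <- gen_shift(v)
  expect_equal(s[, 1], c(3, 4))
  expect_equal(s[, 2], c(5, 6))
  expect_equal(s[, 3], c(0, 0))
  expect_equal(gen_shift(gen_vec(matrix(0, 2, 3))), gen_vec(matrix(0, 2, 3)))
  # nilpotence: n applications annihilate an order-n variable
  s3 <- gen_shift(gen_shift(gen_shift(v)))
  expect_true(all(s3 == 0))
})

scalar_linear_spec <- function(n_orders = 1) {
  level_spec(f = function(x, u) -x, g = function(x, u) x,
             n_x = 1, n_u = 0, n_s = 1, n_orders = n_orders)
}

test_that("prediction errors vanish at perfect prediction and scale with precision", {
  sp <- scalar_linear_spec(2)
  # state satisfying both D mu = f and s = g: x = 0
  st <- filter_state(sp, mu_x = 0)
  pe <- prediction_errors(sp, st, 0)
  expect_true(all(abs(pe$xi_v) < 1e-14))
  expect_true(all(abs(pe$xi_x) < 1e-14))

  # hand-computed residuals: mu = 1, s = 0, unit precisions
  sp1 <- scalar_linear_spec(1)
  st1 <- filter_state(sp1, mu_x = 1)
  pe1 <- prediction_errors(sp1, st1, 0)
  expect_equal(as.numeric(pe1$xi_x), 1)   # 0 - (-1)
  expect_equal(as.numeric(pe1$xi_v), -1)  # 0 - 1

  # raising a log-precision by ln 2 doubles the weighted error
  sp2 <- level_spec(f = function(x, u) -x, g = function(x, u) x,
                    n_x = 1, n_u = 0, n_s = 1,
                    log_precisions = list(sensory = log(2), states = 0,
                                          control = numeric(0)),
                    n_orders = 1)
  pe2 <- prediction_errors(sp2, filter_state(sp2, mu_x = 1), 0)
  expect_equal(as.numeric(pe2$xi_v), 2 * as.numeric(pe1$xi_v))
})

test_that("supplied Jacobians agree with finite differences", {
  spec_fd <- level_spec(f = function(x, u) c(-x[1] * x[2], x[1] - u),
                        g = function(x, u) c(sin(x[1]), x[2]^2),
                        n_x = 2, n_u = 1, n_s = 2, n_orders = 2)
  x0 <- c(0.3, -0.7); u0 <- 0.2
  Jf <- spec_fd$f_jac(x0, u0)
  expect_equal(Jf$x, rbind(c(-x0[2], -x0[1]), c(1, 0)), tolerance = 1e-5)
  expect_equal(Jf$u, matrix(c(0, -1), 2, 1), tolerance = 1e-5)
  Jg <- spec_fd$g_jac(x0, u0)
  expect_equal(Jg$x, rbind(c(cos(x0[1]), 0), c(0, 2 * x0[2])), tolerance = 1e-5)
})

test_that("filtering a static linear-Gaussian model recovers the conjugate posterior", {
  lam <- 1.7; lp_s <- log(4); lp_p <- log(2); eta <- 0.3; s_obs <- 2
  sp <- level_spec(f = function(x, u) numeric(0), g = function(x, u) lam * u,
                   n_x = 0, n_u = 1, n_s = 1,
                   log_precisions = list(sensory = lp_s, states = numeric(0),
                                         control = lp_p),
                   control_prior = eta, n_orders = 1)
  st <- filter_state(sp)
  for (i in 1:60) st <- filter_step(sp, st, s_obs, dt = 0.5)
  post_mean <- (lam * exp(lp_s) * s_obs + exp(lp_p) * eta) /
    (lam^2 * exp(lp_s) + exp(lp_p))
  expect_equal(st$mu_u[1, 1], post_mean, tolerance = 1e-6)

  # at the optimum the gradient part of the flow vanishes
  pe <- prediction_errors(sp, st, s_obs)
  grad <- lam * pe$xi_v[1, 1] - pe$xi_u[1, 1]
  expect_lt(abs(grad), 1e-6)

  # conditional precision matches the closed form exactly
  Pi <- conditional_precision(sp, numeric(0), st$mu_u[, 1],
                              which_x = integer(0), which_u = 1)
  expect_equal(Pi[1, 1], lam^2 * exp(lp_s) + exp(lp_p), tolerance = 1e-6)
})

test_that("free energy is non-increasing for fixed input on linear models", {
  for (s in 1:8) {
    set.seed(s)
    A <- matrix(rnorm(4), 2) - 2 * diag(2)
    C <- matrix(rnorm(4), 2)
    sp <- level_spec(f = function(x, u) A %*% x, g = function(x, u) C %*% x,
                     n_x = 2, n_u = 0, n_s = 2,
                     log_precisions = list(sensory = 1, states = 0,
                                           control = numeric(0)),
                     n_orders = 1)
    st <- filter_state(sp, mu_x = rnorm(2))
    s_obs <- rnorm(2)
    F_prev <- Inf
    for (i in 1:25) {
      st <- filter_step(sp, st, s_obs, dt = 0.3)
      expect_lte(st$free_energy, F_prev + 1e-9)
      F_prev <- st$free_energy
    }
  }
})

test_that("Euler and local-linearization integrators agree on a mild model", {
  sp <- scalar_linear_spec(2)
  s_obs <- 0.8
  st_l <- st_e <- filter_state(sp, mu_x = -0.5)
  for (i in 1:30) {
    st_l <- filter_step(sp, st_l, s_obs, dt = 0.1, integrator = "lls")
    st_e <- filter_step(sp, st_e, s_obs, dt = 0.1, integrator = "euler",
                        euler_substeps = 32)
    expect_lt(abs(st_l$mu_x[1, 1] - st_e$mu_x[1, 1]), 2e-3)
  }
})

test_that("the reflex arc holds still at zero error and descends otherwise", {
  sp <- level_spec(f = function(x, u) -x, g = function(x, u) x,
                   n_x = 1, n_u = 0, n_s = 1, n_orders = 2)
  st <- filter_state(sp, mu_x = 0, n_action = 1)
  st2 <- action_step(sp, st, gen_vec(matrix(0, 1, 2)), matrix(1, 1, 1), dt = 1)
  expect_equal(st2$action, 0)

  # positive order-1 error with positive sensitivity drives action down
  s_tilde <- gen_vec(cbind(0, 1), 2)  # observed velocity 1, predicted 0
  st3 <- action_step(sp, st, s_tilde, matrix(1, 1, 1), dt = 1)
  expect_lt(st3$action, 0)
})

test_that("closed-loop reflex control tracks a target prior", {
  # world: a leaky integrator driven by action and sensed directly; agent:
  # believes the state relaxes toward a control state whose prior sits at
  # the target -- the reflex arc must realize that belief. The analytic
  # fixed point of the loop is x = eta with action balancing the leak.
  eta <- 0.8
  sp <- level_spec(f = function(x, u) (u - x) / 4, g = function(x, u) x,
                   n_x = 1, n_u = 1, n_s = 1,
                   log_precisions = list(sensory = 8, states = 8, control = 8),
                   control_prior = eta, n_orders = 2)
  st <- filter_state(sp, mu_x = 0, mu_u = 0, n_action = 1)
  x_true <- 0
  for (i in 1:32) {
    x_true <- x_true + (st$action - x_true / 16)
    s_tilde <- gen_vec(cbind(x_true, st$action - x_true / 16), 2)
    st <- filter_step(sp, st, s_tilde, dt = 1)
    st <- action_step(sp, st, s_tilde, matrix(1, 1, 1), dt = 1)
  }
  expect_lt(abs(x_true - eta), 0.05)
  # at the fixed point the action exactly balances the world's leak
  expect_lt(abs(st$action - eta / 16), 1e-3)
})

test_that("Gauss-Newton precision matches the finite-difference Hessian at zero residual", {
  set.seed(21)
  for (rep in 1:5) {
    W <- matrix(rnorm(6), 3, 2)
    g_fun <- function(x, u) as.numeric(tanh(W %*% x))
    sp <- level_spec(f = function(x, u) -x, g = g_fun,
                     n_x = 2, n_u = 0, n_s = 3,
                     log_precisions = list(sensory = runif(1, 0, 2),
                                           states = runif(1, 0, 1),
                                           control = numeric(0)),
                     n_orders = 1)
    mu <- rnorm(2, sd = 0.5)
    s_obs <- g_fun(mu, numeric(0))  # zero residual: GN equals the Hessian
    Pi <- conditional_precision(sp, mu)

    gibbs <- function(v) {
      e_v <- s_obs - g_fun(v, numeric(0))
      e_x <- 0 - (-v)  # top-order state error at order 0 (D mu = 0)
      0.5 * sum(e_v^2 * sp$pi_v) + 0.5 * sum(e_x^2 * sp$pi_x)
    }
    h <- 1e-4
    H <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      ei <- ej <- numeric(2); ei[i] <- h; ej[j] <- h
      H[i, j] <- (gibbs(mu + ei + ej) - gibbs(mu + ei - ej) -
                    gibbs(mu - ei + ej) + gibbs(mu - ei - ej)) / (4 * h^2)
    }
    expect_equal(Pi[1:2, 1:2], H, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("doubling the sensory precision doubles the scalar precision", {
  mk <- function(lp) level_spec(f = function(x, u) numeric(0),
                                g = function(x, u) u,
                                n_x = 0, n_u = 1, n_s = 1,
                                log_precisions = list(sensory = lp,
                                                      states = numeric(0),
                                                      control = -30),
                                n_orders = 1)
  Pi1 <- conditional_precision(mk(0), numeric(0), 0, which_x = integer(0), which_u = 1)
  Pi2 <- conditional_precision(mk(log(2)), numeric(0), 0, which_x = integer(0), which_u = 1)
  expect_equal(Pi2[1, 1] / Pi1[1, 1], 2, tolerance = 1e-9)
  expect_equal(attr(Pi2, "log_det") - attr(Pi1, "log_det"), log(2), tolerance = 1e-9)
})
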