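uniform_model <- function(ns = 3, nu = 2, Tn = 3) {
  discrete_model(A = matrix(1 / ns, ns, ns),
                 B = rep(list(matrix(1 / ns, ns, ns)), nu),
                 c = rep(1 / ns, ns), d = rep(1 / nu, nu), horizon = Tn)
}

test_that("a fully symmetric model is a fixed point of the updates", {
  m <- uniform_model()
  bel <- variational_sweep(m, observations = 1L, n_iterations = 10)
  expect_equal(bel$alpha, matrix(1 / 3, 4, 3), tolerance = 1e-12)
  expect_equal(bel$beta, matrix(1 / 2, 3, 2), tolerance = 1e-12)
})

test_that("identity likelihood clamps observed times to deltas", {
  toy <- make_toy_mdp(n_states = 3, n_actions = 2, horizon = 3, seed = 5)
  obs <- c(2L, 1L)
  bel <- variational_sweep(toy$model, obs, n_iterations = 4)
  expect_equal(bel$alpha[1, ], c(0, 1, 0))
  expect_equal(bel$alpha[2, ], c(1, 0, 0))
})

test_that("belief vectors stay normalized after every sweep", {
  for (s in 1:10) {
    toy <- make_toy_mdp(n_states = sample(2:4, 1), n_actions = sample(2:3, 1),
                        horizon = sample(2:3, 1), seed = 100 + s)
    bel <- variational_sweep(toy$model, 1L, n_iterations = 3)
    expect_equal(rowSums(bel$alpha), rep(1, nrow(bel$alpha)), tolerance = 1e-10)
    expect_equal(rowSums(bel$beta), rep(1, nrow(bel$beta)), tolerance = 1e-10)
    expect_true(all(bel$alpha >= 0), info = paste("seed", s))
  }
})

test_that("free energy equals negative log evidence when the posterior factorizes", {
  # transitions identical and uniform across controls: time slices decouple,
  # so the exact posterior is a product of its marginals
  set.seed(9)
  ns <- 3
  A <- rand_stoch(ns)
  m <- discrete_model(A, B = rep(list(matrix(1 / ns, ns, ns)), 2),
                      c = rep(1 / ns, ns), d = c(0.3, 0.7), horizon = 2)
  obs <- c(1L, 3L)
  ex <- exact_smoother(m, obs)
  bel <- beliefs(ex$alpha, ex$beta)
  F <- discrete_free_energy(m, bel, obs)
  expect_equal(F, -ex$log_evidence, tolerance = 1e-10)
})

test_that("free energy upper-bounds surprise for arbitrary beliefs", {
  toy <- make_toy_mdp(n_states = 3, n_actions = 2, horizon = 2, seed = 42,
                      terminal_prior = "random")
  obs <- 2L
  ex <- exact_smoother(toy$model, obs)
  for (s in 1:50) {
    set.seed(s)
    alpha <- rand_stoch(3, 3)  # columns as random simplex points
    bel <- beliefs(t(alpha), t(rand_stoch(2, 2)))
    F <- discrete_free_energy(toy$model, bel, obs)
    expect_gte(F, -ex$log_evidence - 1e-10)
  }
})

test_that("coordinate-ascent sweeps never increase the free energy", {
  for (s in 1:5) {
    toy <- make_toy_mdp(n_states = 4, n_actions = 3, horizon = 3,
                        seed = 200 + s, terminal_prior = "random")
    obs <- 1L
    bel <- init_beliefs(toy$model, obs)
    F_prev <- discrete_free_energy(toy$model, bel, obs)
    for (it in 1:6) {
      bel <- variational_sweep(toy$model, obs, bel, n_iterations = 1)
      F_new <- discrete_free_energy(toy$model, bel, obs)
      expect_lte(F_new, F_prev + 1e-12)
      F_prev <- F_new
    }
  }
})

test_that("select_control_action matches the predicted state and breaks ties low", {
  # identity likelihood, delta belief about the next state, one action whose
  # kernel reaches that state with certainty
  toy <- make_toy_mdp(n_states = 3, n_actions = 2, horizon = 2,
                      deterministic = TRUE, seed = 8)
  bel <- init_beliefs(toy$model, 1L)
  target <- which.max(toy$Tr[[2]][, 1])
  bel$alpha[2, ] <- 0; bel$alpha[2, target] <- 1
  a <- select_control_action(bel, k = 0, R = toy$R, A = toy$model$A, s_now = 1)
  # direct evaluation of the objective over both actions
  obj <- vapply(1:2, function(ac) {
    sum(toy$R[[ac]][, 1] * (log(pmax(toy$model$A, 1e-32)) %*% bel$alpha[2, ]))
  }, numeric(1))
  expect_equal(a, which.max(obj))

  # two identical kernels tie; the lower index is returned
  Rtie <- list(toy$R[[1]], toy$R[[1]])
  a2 <- select_control_action(bel, k = 0, R = Rtie, A = toy$model$A, s_now = 1)
  expect_equal(a2, 1L)
  expect_error(select_control_action(bel, k = 2, R = toy$R, A = toy$model$A,
                                     s_now = 1), "horizon")
})

test_that("random-toy action selection agrees with brute-force objective evaluation", {
  for (s in 1:10) {
    toy <- make_toy_mdp(n_states = 4, n_actions = 3, horizon = 2, seed = 300 + s)
    obs <- sample.int(4, 1)
    bel <- variational_sweep(toy$model, obs, n_iterations = 8)
    a <- select_control_action(bel, k = 0, R = toy$R, A = toy$model$A, s_now = obs)
    lnA <- log(pmax(toy$model$A, 1e-32))
    obj <- vapply(1:3, function(ac) {
      sum(toy$R[[ac]][, obs] * (lnA %*% bel$alpha[2, ]))
    }, numeric(1))
    expect_equal(a, which.max(obj))
  }
})

test_that("an episode on a symmetric goal-at-start model stays home", {
  # terminal prior concentrated on the start state with near-identity
  # dynamics: the planner should keep the agent at (or return it to) home
  ns <- 3
  B <- lapply(1:2, function(i) normalize_columns(diag(ns) + 0.05))
  m <- discrete_model(diag(ns), B, c = c(1, 0, 0), d = c(0.5, 0.5), horizon = 4)
  R <- lapply(B, function(b) normalize_columns(t(as.matrix(b))))
  tr <- run_episode(m, R, start_state = 1L, n_sweeps_per_step = 8)
  expect_equal(tr$states[5], 1L)
  expect_s3_class(tr, "episode_trace")
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 5)
  expect_true(all(c("time", "state_index", "observation", "action",
                    "free_energy") %in% names(df)))
})
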