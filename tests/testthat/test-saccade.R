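test_that("the perceptual-state flow settles at its dynamic-softmax fixed point", {
  eq <- perceptual_equilibrium(3)
  # stationarity of the printed flow at the returned point
  resid <- (1 - sum(exp(eq$x_q))) - eq$x_q / 1024
  expect_lt(max(abs(resid)), 1e-7)
  # exponentiated weights sum to one up to the slow-decay residual
  expect_lt(abs(eq$sum_exp - 1), 2e-3)
  # equal weights at equilibrium: each close to log(1/3)
  expect_equal(eq$x_q, rep(log(1 / 3), 3), tolerance = 2e-3)
})

test_that("a degenerate mixture predicts exactly its single hypothesis", {
  gl <- cached_glyphs()
  ret <- retina_spec()
  spec <- saccade_model(gl$hypotheses, ret)
  xp <- c(0.1, -0.05)
  x <- c(xp, 0, -40, -40)  # weight 1 on hypothesis 1
  pred <- spec$g(x, c(0, 0))
  direct <- sample_retina(spec$hyps_filtered[[1]], xp, ret)
  expect_equal(pred[1:2], xp)
  expect_equal(pred[-(1:2)], direct, tolerance = 1e-12)
})

test_that("salience is flat for featureless hypotheses and structured for glyphs", {
  ret <- retina_spec()
  flat <- scene_image(matrix(0.5, 64, 64))
  spec_flat <- saccade_model(list(flat, flat, flat), ret)
  st <- filter_state(spec_flat, mu_x = c(0, 0, rep(log(1 / 3), 3)),
                     mu_u = c(0, 0), n_action = 2)
  S_flat <- salience_map(spec_flat, st, grid_side = 8)
  expect_lt(diff(range(S_flat$values)), 1e-9)

  gl <- cached_glyphs()
  spec_g <- saccade_model(gl$hypotheses, ret)
  st_g <- filter_state(spec_g, mu_x = c(0, 0, rep(log(1 / 3), 3)),
                       mu_u = c(0, 0), n_action = 2)
  S_g <- salience_map(spec_g, st_g)
  expect_equal(length(S_g$values), 1024L)
  expect_gt(diff(range(S_g$values)), 1e-6)
})

test_that("salience is a function of beliefs alone", {
  # identical beliefs, computed twice while 'looking at' different scenes:
  # the map never touches the scene, only the hypotheses and expectations
  gl <- cached_glyphs()
  ret <- retina_spec()
  spec <- saccade_model(gl$hypotheses, ret)
  st <- filter_state(spec, mu_x = c(0.2, -0.1, -0.8, -1.4, -1.2),
                     mu_u = c(0, 0), n_action = 2)
  S1 <- salience_map(spec, st, grid_side = 12)
  invisible(sample_retina(gl$scenes$rotated, c(0, 0), ret))  # unrelated scene access
  S2 <- salience_map(spec, st, grid_side = 12)
  expect_identical(S1$values, S2$values)
})

test_that("inhibition of return suppresses the foveated location and decays by halves", {
  vals <- c(0.5, 2, 1, 0.25)
  cand <- cbind(x = c(-0.5, -0.25, 0.25, 0.5), y = rep(0, 4))
  S <- structure(list(values = vals, candidates = cand, grid_side = NA_integer_,
                      argmax = 2L, argmax_location = cand[2, ]),
                 class = "salience_map")
  ior1 <- apply_inhibition_of_return(S, NULL, rho_sigma = 0.05)
  # no memory: only the minimum shift applies
  expect_equal(ior1$S_final$values, vals - min(vals))
  expect_equal(ior1$argmax, 2L)
  expect_equal(max(ior1$R_new), 1)

  # the location just foveated has exactly zero salience next time
  ior2 <- apply_inhibition_of_return(S, ior1$R_new, rho_sigma = 0.05)
  expect_identical(ior2$S_final$values[2], 0)
  # with the bump far away, memory halves at each subsequent saccade
  far <- S; far$values <- c(5, 0, 0, 0)
  iorA <- apply_inhibition_of_return(far, ior1$R_new, rho_sigma = 1e-3)
  iorB <- apply_inhibition_of_return(far, iorA$R_new, rho_sigma = 1e-3)
  expect_equal(iorB$R_new[2], ior1$R_new[2] / 4, tolerance = 1e-6)
})

test_that("the generative process integrates the printed gaze flow", {
  ret <- retina_spec()
  gl <- cached_glyphs()
  scene <- dog_filter(gl$scenes$upright, ret)
  # zero action: exponential decay toward the origin with time constant 16
  xp <- c(0.5, -0.3)
  for (i in 1:10) {
    ps <- process_step(scene, xp, c(0, 0), ret)
    expect_equal(ps$x_p, xp * (1 - 1 / 16))  # one Euler bin of dx/dt = -x/16
    xp <- ps$x_p
  }
  # constant action approaches the closed-form fixed point 16 a
  a <- c(0.02, -0.01)
  xp <- c(0, 0)
  for (i in 1:400) xp <- process_step(scene, xp, a, ret)$x_p
  expect_equal(xp, 16 * a, tolerance = 1e-2)
  # noiseless propagation reports the gaze exactly
  ps <- process_step(scene, c(0.1, 0.1), c(0, 0), ret)
  expect_equal(ps$s_tilde[1:2, 1], ps$x_p)
})

test_that("a short search runs closed-loop and never refixates immediately", {
  gl <- cached_glyphs()
  tr <- saccade_search(gl$scenes$upright, gl$hypotheses, n_saccades = 3,
                       bins_per_saccade = 8, seed = 2, noise = TRUE)
  expect_s3_class(tr, "saccade_trace")
  expect_equal(dim(tr$posterior), c(24L, 3L))
  expect_true(all(rowSums(abs(diff(tr$fixations))) > 0))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 24L)
  expect_true(all(is.finite(df$free_energy)))
})
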