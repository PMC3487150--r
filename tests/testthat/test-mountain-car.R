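test_that("the flow vanishes at the valley minimum and friction opposes motion", {
  dyn <- car_dynamics()
  expect_equal(car_flow(c(-0.5, 0), 0, dyn), c(0, 0), tolerance = 1e-12)
  # at the minimum with rightward motion, the only force is friction
  f <- car_flow(c(-0.5, 0.4), 0, dyn)
  expect_equal(f[1], 0.4)
  expect_equal(f[2], -dyn$friction * 0.4)
  # the landscape has minima at both the valley and the parking place
  expect_lt(abs(car_potential_grad(-0.5)), 1e-12)
  xs <- seq(0.9, 1.2, by = 0.001)
  xmin <- xs[which.min(car_potential(xs))]
  expect_lt(abs(car_potential_grad(xmin)), 0.02)
})

test_that("full throttle from rest at the minimum cannot climb to the parking place", {
  dyn <- car_dynamics()
  x <- c(-0.5, 0)
  pmax <- x[1]
  for (i in 1:120) {  # 60 s of forward integration
    x <- car_step(x, 2, dyn, dt = 0.5, h_max = 0.01)
    pmax <- max(pmax, x[1])
  }
  expect_lt(pmax, 1)
})

test_that("grid indexing round-trips and uses the stated conventions", {
  g <- grid_spec(n_pos = 2, pos_range = c(-1, 1), n_vel = 2, vel_range = c(-1, 1))
  xy <- state_coords(g, 1:4)
  expect_equal(sort(unique(xy[, 1])), c(-0.5, 0.5))
  expect_equal(sort(unique(xy[, 2])), c(-0.5, 0.5))

  g32 <- grid_spec()
  for (i in c(1L, 17L, 500L, 1024L)) {
    xy <- state_coords(g32, i)
    expect_equal(nearest_state(g32, xy[1], xy[2]), i)
  }
  expect_equal(control_value(g32, 1), -2)
  expect_equal(control_value(g32, 5), 2)
  expect_error(state_coords(g32, 0), "range")
  expect_error(control_value(g32, 6), "range")
})

test_that("zero-interval discretization is the identity and equilibria stay put", {
  g <- grid_spec(n_pos = 8, n_vel = 8)
  dyn0 <- car_dynamics(dt = 0)
  pb <- build_pullback(dyn0, g, smoothing_sigma = 0)
  for (k in 1:5) expect_equal(as.matrix(pb$B[[k]]), diag(64), tolerance = 1e-12)

  # equilibrium bin: the column of the bin containing the valley minimum
  # stays concentrated there for a small interval
  g2 <- grid_spec()
  dyn_small <- car_dynamics(dt = 0.05)
  pb2 <- build_pullback(dyn_small, g2, smoothing_sigma = 0)
  eq <- nearest_state(g2, -0.5, 0)
  expect_gt(pb2$B[[3]][eq, eq], 0.9)
})

test_that("expected coordinates in each pullback column reproduce one Euler step", {
  # at a small interval the integrated flow and the single Euler step agree,
  # so the mean predecessor of state j sits at x(j) - f(x(j), a) * dt to
  # within half a bin (interior, unsmoothed columns; the interval is kept
  # short because the landscape's curvature makes the one-step Euler map
  # diverge quadratically in dt from the integrated flow)
  g <- grid_spec()
  dyn <- car_dynamics(dt = 0.05)
  pb <- build_pullback(dyn, g, smoothing_sigma = 0)
  xy <- state_coords(g, seq_len(g$n_states))
  half <- c(g$pos_width, g$vel_width) / 2
  interior <- xy[, 1] > -1.5 & xy[, 1] < 1.5 & xy[, 2] > -2 & xy[, 2] < 2
  for (k in c(1L, 3L, 5L)) {
    target <- xy - car_flow(xy, g$control_values[k], dyn) * dyn$dt
    Bk <- pb$B[[k]]
    got <- cbind(as.numeric(Matrix::crossprod(Bk, xy[, 1])),
                 as.numeric(Matrix::crossprod(Bk, xy[, 2])))
    dev_p <- abs(got[interior, 1] - target[interior, 1])
    dev_v <- abs(got[interior, 2] - target[interior, 2])
    expect_lt(max(dev_p), half[1])
    expect_lt(max(dev_v), half[2])
  }
})

test_that("pullback and sampling kernels are column-stochastic", {
  mc <- cached_mountain_car()
  for (k in 1:5) {
    expect_equal(colSums(mc$model$B[[k]]), rep(1, 1024), tolerance = 1e-9)
    expect_equal(colSums(mc$R[[k]]), rep(1, 1024), tolerance = 1e-9)
    expect_true(all(mc$model$B[[k]] >= 0))
  }
})

test_that("free-rolling modal dynamics settle near a potential minimum", {
  mc <- cached_mountain_car()
  modal0 <- apply(mc$R[[3]], 2, which.max)  # zero-force kernel
  for (start in c(nearest_state(mc$grid, -1.5, 0.5),
                  nearest_state(mc$grid, 0.3, -0.4),
                  nearest_state(mc$grid, 1.3, 0.2))) {
    s <- start
    for (i in 1:60) s <- modal0[s]
    xy <- state_coords(mc$grid, s)
    near_valley <- abs(xy[1] - (-0.5)) < 0.45 && abs(xy[2]) < 0.4
    near_pocket <- abs(xy[1] - 1.06) < 0.25 && abs(xy[2]) < 0.4
    expect_true(near_valley || near_pocket,
                info = sprintf("settled at (%.2f, %.2f)", xy[1], xy[2]))
  }
})

test_that("the assembled model matches the stated configuration", {
  mc <- cached_mountain_car()
  expect_equal(mc$model$n_states, 1024L)
  expect_equal(sum(mc$model$c > 0), 1L)
  expect_equal(which(mc$model$c > 0), nearest_state(mc$grid, 1, 0))
  expect_equal(mc$model$d, rep(0.2, 5))
  expect_true(all(mc$model$A == diag(1024)))
  expect_error(make_mountain_car_model(goal = c(5, 0)), "inside the grid")
})
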