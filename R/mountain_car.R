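# Continuous mountain-car dynamics and their discretization into pullback
# transition matrices and a sampling kernel.

#' Default mountain-car landscape
#'
#' Height of the landscape as a function of position: a double-well profile
#' with a broad valley centered at `x = -0.5` and a narrow parking pocket
#' centered at `x = 1.0625`, separated by a barrier whose maximal uphill
#' slope (1, at the origin) exceeds the largest force the engine can exert
#' under the default gain. The car therefore cannot drive from the valley to
#' the parking place directly and must first swing left to gather momentum.
#'
#' The slope `dH/dx` is piecewise linear through fixed knots: the valley
#' branch `2x + 1` (minimum at -0.5), a barrier crest at `x = 0.45`, steep
#' pocket walls that capture a car cresting the barrier, and a gentle
#' harmonic core around the pocket minimum whose natural half-period matches
#' the 2-second planning step. A car that has settled into the core therefore
#' alternates between mirror states inside the parking bin's neighborhood,
#' which keeps the parked state resolvable -- and controllable -- on the
#' discretization grid.
#'
#' @param x position (dimensionless).
#' @return Height `H(x)`; `car_potential_grad` returns `dH/dx`.
#' @export
car_potential <- function(x) {
  kx <- car_landscape_knots$x
  ky <- car_landscape_knots$dH
  # integrate the piecewise-linear slope analytically from x = 0
  H1 <- function(z) {
    z <- pmin(pmax(z, kx[1]), kx[length(kx)])
    out <- numeric(length(z))
    cum <- c(0, cumsum(diff(kx) * (head(ky, -1) + tail(ky, -1)) / 2))
    i0 <- which(kx == 0)
    for (m in seq_along(z)) {
      j <- max(which(kx <= z[m])); j <- min(j, length(kx) - 1L)
      dx <- z[m] - kx[j]
      sl <- (ky[j + 1] - ky[j]) / (kx[j + 1] - kx[j])
      out[m] <- (cum[j] - cum[i0]) + ky[j] * dx + sl * dx^2 / 2
    }
    out
  }
  H1(x)
}

# slope knots shared by car_potential and car_potential_grad
car_landscape_knots <- list(
  x  = c(-2, 0, 0.45, 0.875, 1.0, 1.125, 1.25, 2),
  dH = c(-3, 1, 0, -1.85, -0.154, 0.154, 1.85, 6)
)

#' @rdname car_potential
#' @export
car_potential_grad <- function(x) {
  k <- car_landscape_knots
  z <- pmin(pmax(x, k$x[1]), k$x[length(k$x)])
  stats::approx(k$x, k$dH, xout = z, rule = 2)$y
}

#' Mountain-car equations of motion
#'
#' Bundles the landscape, friction, engine gain, and integration interval.
#' The engine force passes through a hyperbolic-tangent squashing function,
#' so `|force| < action_gain` however large the action.
#'
#' @param potential height function of position.
#' @param potential_grad its derivative (finite-differenced if omitted).
#' @param friction linear friction coefficient (per unit velocity); the
#'   default 0.15 lets resonant pumping build momentum while settling a
#'   captured car into the parking pocket within a few planning steps.
#' @param action_gain engine force scale; the default 0.5 makes the largest
#'   engine force (`0.5 * tanh(2) ~ 0.48`) strictly smaller than the maximal
#'   uphill slope, which is the defining weak-engine property.
#' @param dt discrete time interval in seconds used when discretizing.
#' @return An object of class `car_dynamics`.
#' @export
car_dynamics <- function(potential = car_potential,
                         potential_grad = car_potential_grad,
                         potential_scale = 1,
                         friction = 0.15, action_gain = 0.5, dt = 2) {
  if (is.null(potential_grad)) {
    potential_grad <- function(x) {
      h <- 1e-6
      (potential(x + h) - potential(x - h)) / (2 * h)
    }
  }
  if (friction < 0) stop("friction must be >= 0", call. = FALSE)
  structure(list(potential = potential, potential_grad = potential_grad,
                 potential_scale = potential_scale,
                 friction = friction, action_gain = action_gain, dt = dt),
            class = "car_dynamics")
}

#' Flow field of the mountain car
#'
#' Time derivatives of position and velocity:
#' `(dx/dt, dv/dt) = (v, tanh(a) * gain - H'(x) - friction * v)`.
#'
#' @param x numeric vector `c(position, velocity)` or a 2-column matrix of
#'   states (rows = states).
#' @param a real-valued action.
#' @param dynamics a [car_dynamics()] object.
#' @return Derivatives in the same shape as `x`.
#' @export
car_flow <- function(x, a, dynamics = car_dynamics()) {
  if (is.matrix(x)) {
    if (ncol(x) != 2L) stop("state matrix must have 2 columns", call. = FALSE)
    cbind(x[, 2L],
          tanh(a) * dynamics$action_gain -
            dynamics$potential_scale * dynamics$potential_grad(x[, 1L]) -
            dynamics$friction * x[, 2L])
  } else {
    c(x[2L],
      tanh(a) * dynamics$action_gain -
        dynamics$potential_scale * dynamics$potential_grad(x[1L]) -
        dynamics$friction * x[2L])
  }
}

#' Integrate the car flow over one discrete interval
#'
#' Propagates one or more car states through the equations of motion for a
#' time `dt` under a constant action, using classical fourth-order
#' Runge-Kutta with substeps of at most `h_max`. For small `dt` this agrees
#' with a single Euler step `x + f(x, a) * dt`; over the long discretization
#' intervals used by the planner it follows the true (stable, friction-bound)
#' flow that a single Euler step badly overshoots.
#'
#' @param x state `c(position, velocity)` or a 2-column matrix of states.
#' @param a real-valued action (held constant over the interval).
#' @param dynamics a [car_dynamics()].
#' @param dt integration interval (defaults to `dynamics$dt`).
#' @param h_max maximum substep length.
#' @return Propagated state(s), same shape as `x`.
#' @export
car_step <- function(x, a, dynamics = car_dynamics(), dt = dynamics$dt,
                     h_max = 0.1) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1L, 2L)
  n_sub <- max(1L, ceiling(dt / h_max))
  h <- dt / n_sub
  for (s in seq_len(n_sub)) {
    k1 <- car_flow(x, a, dynamics)
    k2 <- car_flow(x + h / 2 * k1, a, dynamics)
    k3 <- car_flow(x + h / 2 * k2, a, dynamics)
    k4 <- car_flow(x + h * k3, a, dynamics)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (vec) x[1L, ] else x
}

#' Discretization grid over position and velocity
#'
#' Bins for the two-dimensional car state and the discrete control levels.
#' States are indexed 1-based in row-major order with velocity as the fast
#' axis: state `i` has position-bin `(i - 1) %/% n_vel + 1` and velocity-bin
#' `(i - 1) %% n_vel + 1`.
#'
#' @param n_pos,n_vel number of position and velocity bins.
#' @param pos_range,vel_range coordinate ranges covered by the bins.
#' @param control_values sorted distinct real action levels.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_pos = 32, pos_range = c(-2, 2),
                      n_vel = 32, vel_range = c(-3, 3),
                      control_values = c(-2, -1, 0, 1, 2)) {
  n_pos <- as.integer(n_pos); n_vel <- as.integer(n_vel)
  if (n_pos < 2L || n_vel < 2L) stop("grids need at least 2 bins per axis", call. = FALSE)
  if (is.unsorted(control_values, strictly = TRUE)) {
    stop("control_values must be sorted and distinct", call. = FALSE)
  }
  structure(list(n_pos = n_pos, pos_range = as.numeric(pos_range),
                 n_vel = n_vel, vel_range = as.numeric(vel_range),
                 control_values = as.numeric(control_values),
                 n_states = n_pos * n_vel,
                 pos_width = diff(pos_range) / n_pos,
                 vel_width = diff(vel_range) / n_vel),
            class = "grid_spec")
}

#' Coordinates of grid states and controls
#'
#' `state_coords` returns the bin-center `(position, velocity)` of one or more
#' state indices; `nearest_state` inverts it (clipping to the grid);
#' `control_value` returns the real action of a control index.
#'
#' @param grid a [grid_spec()].
#' @param i state index or vector of indices (1-based).
#' @return For `state_coords`, a length-2 vector or an `n x 2` matrix.
#' @export
state_coords <- function(grid, i) {
  i <- as.integer(i)
  if (any(i < 1L) || any(i > grid$n_states)) stop("state index out of range", call. = FALSE)
  pi_ <- (i - 1L) %/% grid$n_vel
  vi <- (i - 1L) %% grid$n_vel
  out <- cbind(position = grid$pos_range[1L] + (pi_ + 0.5) * grid$pos_width,
               velocity = grid$vel_range[1L] + (vi + 0.5) * grid$vel_width)
  if (length(i) == 1L) out[1L, ] else out
}

#' @rdname state_coords
#' @param position,velocity continuous coordinates (clipped to the grid).
#' @export
nearest_state <- function(grid, position, velocity) {
  pi_ <- pmin(pmax(floor((position - grid$pos_range[1L]) / grid$pos_width), 0), grid$n_pos - 1L)
  vi <- pmin(pmax(floor((velocity - grid$vel_range[1L]) / grid$vel_width), 0), grid$n_vel - 1L)
  as.integer(pi_ * grid$n_vel + vi + 1L)
}

#' @rdname state_coords
#' @param k control index (1-based).
#' @export
control_value <- function(grid, k) {
  k <- as.integer(k)
  if (any(k < 1L) || any(k > length(grid$control_values))) {
    stop("control index out of range", call. = FALSE)
  }
  grid$control_values[k]
}

# Gaussian smoothing matrix along one axis (column-stochastic band matrix).
axis_smoother <- function(n, sigma_bins) {
  if (sigma_bins <= 0) return(Matrix::Diagonal(n))
  r <- max(1L, ceiling(3 * sigma_bins))
  offs <- -r:r
  w <- exp(-offs^2 / (2 * sigma_bins^2))
  i <- integer(0); j <- integer(0); xv <- numeric(0)
  for (d in seq_along(offs)) {
    cols <- seq_len(n)
    rows <- cols + offs[d]
    keep <- rows >= 1L & rows <= n
    i <- c(i, rows[keep]); j <- c(j, cols[keep]); xv <- c(xv, rep(w[d], sum(keep)))
  }
  G <- Matrix::sparseMatrix(i = i, j = j, x = xv, dims = c(n, n))
  G %*% Matrix::Diagonal(n, 1 / Matrix::colSums(G))
}

#' Discretize the dynamics into pullback transitions and a sampling kernel
#'
#' Discretizes one Euler step of the equations of motion over `dt`. Each
#' state `i` propagates forward to the point `x(i) + f(x(i), a(k)) * dt`,
#' whose probability mass is split bilinearly over the four neighboring bin
#' centers (clipped to the grid at the position walls and velocity limits).
#' Collecting these assignments per destination and normalizing each column
#' yields the *pullback* transition matrix `B[[k]]`: column `j` is the
#' distribution over the states adjacent to the backward-propagated point of
#' `j`, so the expected previous coordinates reproduce
#' `x(j) - f(x(j), a(k)) * dt` to first order in `dt`. Each pullback column
#' is then blurred with a separable Gaussian of `smoothing_sigma` bins --
#' augmenting the uncertainty about the previous state incurred by
#' discretizing state space -- and renormalized. The sampling kernel `R[[k]]`
#' (how observations follow actions) is the renormalized transpose of
#' `B[[k]]`, i.e. the smoothed forward Euler kernel.
#'
#' States that receive no forward mass under control `k` are unreachable
#' under that control; their pullback columns are maximum-entropy (uniform).
#'
#' @param dynamics a [car_dynamics()].
#' @param grid a [grid_spec()].
#' @param smoothing_sigma Gaussian blur width in bins (0 disables smoothing).
#' @return A list with `B` and `R`, each a list of column-stochastic
#'   `dgCMatrix` matrices (one per control level), and `n_clipped`, the
#'   number of forward-propagated points clipped to the grid boundary.
#' @export
build_pullback <- function(dynamics, grid, smoothing_sigma = 0.5) {
  if (smoothing_sigma < 0) stop("smoothing_sigma must be >= 0", call. = FALSE)
  n <- grid$n_states
  xy <- state_coords(grid, seq_len(n))
  half <- c(grid$pos_width, grid$vel_width) / 2
  lo <- c(grid$pos_range[1L], grid$vel_range[1L]) + half
  hi <- c(grid$pos_range[2L], grid$vel_range[2L]) - half
  G <- NULL
  if (smoothing_sigma > 0) {
    G <- Matrix::kronecker(axis_smoother(grid$n_pos, smoothing_sigma),
                           axis_smoother(grid$n_vel, smoothing_sigma))
  }

  B <- vector("list", length(grid$control_values))
  R <- vector("list", length(grid$control_values))
  n_clipped <- 0L
  for (k in seq_along(grid$control_values)) {
    fwd <- car_step(xy, grid$control_values[k], dynamics)
    clipped <- fwd[, 1L] < lo[1L] | fwd[, 1L] > hi[1L] |
      fwd[, 2L] < lo[2L] | fwd[, 2L] > hi[2L]
    n_clipped <- n_clipped + sum(clipped)
    gx <- pmin(pmax((fwd[, 1L] - lo[1L]) / grid$pos_width, 0), grid$n_pos - 1L)
    gv <- pmin(pmax((fwd[, 2L] - lo[2L]) / grid$vel_width, 0), grid$n_vel - 1L)
    ix0 <- pmin(floor(gx), grid$n_pos - 2L); fx <- gx - ix0
    iv0 <- pmin(floor(gv), grid$n_vel - 2L); fv <- gv - iv0
    rows <- rep(seq_len(n), 4L)  # current state i
    cols <- c(ix0 * grid$n_vel + iv0 + 1L,  # destination state j
              (ix0 + 1L) * grid$n_vel + iv0 + 1L,
              ix0 * grid$n_vel + iv0 + 2L,
              (ix0 + 1L) * grid$n_vel + iv0 + 2L)
    w <- c((1 - fx) * (1 - fv), fx * (1 - fv), (1 - fx) * fv, fx * fv)
    keep <- w > 0
    # B0[i, j]: forward mass sent from i to j; columns are therefore the
    # (unnormalized) distributions over the predecessors of each state j
    B0 <- Matrix::sparseMatrix(i = rows[keep], j = as.integer(cols[keep]),
                               x = w[keep], dims = c(n, n))
    cs <- Matrix::colSums(B0)
    unreachable <- which(cs == 0)
    B0 <- B0 %*% Matrix::Diagonal(n, ifelse(cs > 0, 1 / cs, 0))
    if (length(unreachable)) {
      U <- Matrix::Matrix(0, n, n, sparse = TRUE)
      U[, unreachable] <- 1 / n
      B0 <- B0 + U
    }
    Bk <- if (is.null(G)) B0 else G %*% B0
    Bk <- Bk %*% Matrix::Diagonal(n, 1 / Matrix::colSums(Bk))
    B[[k]] <- Bk
    # sampling kernel: renormalized transpose (the smoothed forward kernel);
    # every state sends forward mass somewhere, so no column is empty apart
    # from floating-point corner cases, which get a self-loop
    Rt <- Matrix::t(Bk)
    cs <- Matrix::colSums(Rt)
    empty <- which(cs == 0)
    if (length(empty)) {
      Rt <- Rt + Matrix::sparseMatrix(i = empty, j = empty,
                                      x = rep(1, length(empty)), dims = c(n, n))
      cs[empty] <- 1
    }
    R[[k]] <- Rt %*% Matrix::Diagonal(n, 1 / cs)
  }
  list(B = B, R = R, n_clipped = n_clipped)
}

#' Assemble the discretized mountain-car generative model
#'
#' Builds the full discrete model of the mountain-car problem: identity
#' observation likelihood (states are observed directly), uniform prior over
#' the five control levels, a delta terminal prior on the grid bin containing
#' the goal, and pullback transitions from [build_pullback()].
#'
#' @param grid a [grid_spec()] (defaults match the 32 x 32 binning over
#'   position `[-2, 2]` and velocity `[-3, 3]` with controls `{-2,...,2}`).
#' @param dynamics a [car_dynamics()].
#' @param goal target `c(position, velocity)`; default `c(1, 0)`, parking
#'   halfway up the right hill at rest.
#' @param smoothing_sigma blur width passed to [build_pullback()].
#' @param horizon number of discrete steps (default 16).
#' @return A list with `model` (a [discrete_model()]), `R` (sampling kernels),
#'   `grid`, `dynamics`, `coords` (bin-center coordinates per state), and
#'   `goal_state` (index of the goal bin).
#' @export
make_mountain_car_model <- function(grid = grid_spec(),
                                    dynamics = car_dynamics(),
                                    goal = c(1, 0),
                                    smoothing_sigma = 0.5,
                                    horizon = 16) {
  if (goal[1L] < grid$pos_range[1L] || goal[1L] > grid$pos_range[2L] ||
      goal[2L] < grid$vel_range[1L] || goal[2L] > grid$vel_range[2L]) {
    stop("goal must lie inside the grid", call. = FALSE)
  }
  pb <- build_pullback(dynamics, grid, smoothing_sigma)
  n <- grid$n_states
  goal_state <- nearest_state(grid, goal[1L], goal[2L])
  cvec <- numeric(n); cvec[goal_state] <- 1
  d <- rep(1 / length(grid$control_values), length(grid$control_values))
  model <- discrete_model(A = diag(n),
                          B = lapply(pb$B, as.matrix),
                          c = cvec, d = d, horizon = horizon)
  list(model = model, R = lapply(pb$R, as.matrix), grid = grid,
       dynamics = dynamics, coords = state_coords(grid, seq_len(n)),
       goal_state = goal_state)
}
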