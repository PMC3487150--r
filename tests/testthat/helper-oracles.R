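# Independent oracles and shared fixtures for the test battery. The oracles
# are deliberately written as plain enumerations, separate from the package's
# own (already more structured) implementations.

# random column-stochastic matrix (Dirichlet(1) columns)
rand_stoch <- function(nrow, ncol = nrow) {
  M <- matrix(stats::rgamma(nrow * ncol, 1), nrow, ncol)
  sweep(M, 2, colSums(M), "/")
}

# expected cumulative reward of a fixed action sequence from state x0,
# rewards collected at every time 0..horizon
seq_value <- function(Tr, r, x0, actions) {
  p <- numeric(length(r)); p[x0] <- 1
  total <- sum(p * r)
  for (a in actions) {
    p <- as.numeric(Tr[[a]] %*% p)
    total <- total + sum(p * r)
  }
  total
}

# brute-force optimum over all open-loop action sequences; with closed-loop
# optima for stochastic models this is a lower bound, but for deterministic
# transitions it equals the Bellman value
enum_value <- function(Tr, r, x0, horizon) {
  seqs <- as.matrix(expand.grid(rep(list(seq_along(Tr)), horizon)))
  max(apply(seqs, 1, function(s) seq_value(Tr, r, x0, s)))
}

# hand enumeration of the pullback-model posterior (independent of
# exact_smoother's loop structure: iterates a flat index)
hand_smoother <- function(model, observations) {
  Tn <- model$horizon; n <- model$n_states; nu <- model$n_controls
  alpha <- matrix(0, Tn + 1, n); beta <- matrix(0, Tn, nu); Z <- 0
  n_x_seq <- n^(Tn + 1); n_u_seq <- nu^Tn
  for (xi in 0:(n_x_seq - 1)) {
    x <- integer(Tn + 1); tmp <- xi
    for (t in 1:(Tn + 1)) { x[t] <- tmp %% n + 1; tmp <- tmp %/% n }
    for (ui in 0:(n_u_seq - 1)) {
      u <- integer(Tn); tmp <- ui
      for (t in 1:Tn) { u[t] <- tmp %% nu + 1; tmp <- tmp %/% nu }
      p <- model$c[x[Tn + 1]]
      for (t in 1:Tn) p <- p * model$B[[u[t]]][x[t], x[t + 1]] * model$d[u[t]]
      if (length(observations)) {
        for (t in seq_along(observations)) p <- p * model$A[observations[t], x[t]]
      }
      if (p > 0) {
        Z <- Z + p
        for (t in 1:(Tn + 1)) alpha[t, x[t]] <- alpha[t, x[t]] + p
        for (t in 1:Tn) beta[t, u[t]] <- beta[t, u[t]] + p
      }
    }
  }
  list(alpha = alpha / Z, beta = beta / Z, log_evidence = log(Z))
}

# the default mountain-car assembly is expensive; build it once per test run
mc_cache <- new.env(parent = emptyenv())
cached_mountain_car <- function() {
  if (is.null(mc_cache$mc)) mc_cache$mc <- make_mountain_car_model()
  mc_cache$mc
}

glyph_cache <- new.env(parent = emptyenv())
cached_glyphs <- function() {
  if (is.null(glyph_cache$g)) glyph_cache$g <- make_glyph_hypotheses(seed = 7)
  glyph_cache$g
}
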