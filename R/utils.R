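# Internal numeric helpers shared across modules.

# Probabilities are floored at PROB_FLOOR inside logarithms: priors c and d
# (and sparse transition columns) may contain exact zeros. The floor sets the
# implied cost of an "impossible" event at -ln(PROB_FLOOR) ~ 73.7 nats, which
# must exceed the free energy of any feasible trajectory -- otherwise the
# variational optimum can prefer a single zero-probability jump over a long
# chain of possible transitions (with 16-step mountain-car plans costing
# ~50-60 nats, a floor of 1e-16 is not safe; 1e-32 leaves a wide margin).
PROB_FLOOR <- 1e-32

logp <- function(x) log(pmax(x, PROB_FLOOR))

# Shannon entropy in nats with the 0 log 0 = 0 convention.
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# KL divergence KL(p || q) in nats; q floored to keep the quantity finite.
kl_divergence <- function(p, q) {
  keep <- p > 0
  sum(p[keep] * (log(p[keep]) - log(pmax(q[keep], 1e-300))))
}

# Normalize a nonnegative vector to sum to one via log-sum-exp when supplied
# in log space (guards exp underflow in variational updates).
norm_exp <- function(logw) {
  w <- exp(logw - max(logw))
  w / sum(w)
}

softmax <- function(x) norm_exp(x)

stopifnot_prob_vector <- function(p, name = deparse(substitute(p)), tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < -1e-12)) {
    stop(sprintf("'%s' must be a finite nonnegative vector", name), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must sum to 1 (got %.12g)", name, sum(p)), call. = FALSE)
  }
  invisible(TRUE)
}
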