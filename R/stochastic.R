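#' Column-normalize a nonnegative matrix
#'
#' Rescales each column of a nonnegative matrix to sum to one, yielding a
#' column-stochastic matrix. Throughout the package, stochastic matrices map a
#' state indexing the *column* to a probability distribution over the *rows*:
#' an observation likelihood `A` has columns indexed by hidden states, and a
#' pullback transition `B` has columns indexed by the current state with rows
#' indexing the previous state.
#'
#' @param M numeric matrix with nonnegative entries and no all-zero column.
#' @return A column-stochastic matrix with the same dimensions as `M`;
#'   proportions within each column are preserved.
#' @examples
#' normalize_columns(matrix(c(1, 1, 2, 6), 2, 2))
#' @export
normalize_columns <- function(M) {
  M <- as.matrix(M)
  if (any(!is.finite(M)) || any(M < 0)) {
    stop("matrix entries must be finite and nonnegative", call. = FALSE)
  }
  s <- colSums(M)
  bad <- which(s <= 0)
  if (length(bad)) {
    stop(sprintf("cannot normalize all-zero column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sweep(M, 2L, s, "/")
}

# Validate column-stochasticity (used by constructors and property tests).
is_column_stochastic <- function(M, tol = 1e-12) {
  M <- as.matrix(M)
  all(is.finite(M)) && all(M >= -tol) && all(abs(colSums(M) - 1) <= max(tol, 1e-12) * nrow(M))
}

assert_column_stochastic <- function(M, name = deparse(substitute(M)), tol = 1e-8) {
  M <- as.matrix(M)
  if (any(!is.finite(M)) || any(M < -1e-12)) {
    stop(sprintf("'%s' must have finite nonnegative entries", name), call. = FALSE)
  }
  dev <- abs(colSums(M) - 1)
  if (any(dev > tol)) {
    stop(sprintf("'%s' columns must sum to 1 (max deviation %.3g)", name, max(dev)),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Entropy decomposition of a discrete joint distribution
#'
#' Decomposes the joint entropy of a discrete (sensory, hidden) distribution
#' into its chain-rule and mutual-information identities:
#' `H(S, Psi) = H(S) + H(Psi | S)` and `H(Psi | S) = H(Psi) - I(Psi; S)`.
#' Minimizing the average conditional uncertainty about hidden states is
#' therefore the same as maximizing the mutual information between hidden and
#' sensory states (the Infomax principle); the two identities are returned as
#' computed quantities so they can serve as numeric self-checks.
#'
#' @param joint numeric matrix of joint probabilities with rows indexing
#'   sensory states and columns indexing hidden states; must be nonnegative
#'   and sum to one.
#' @return A list with entries `H_joint`, `H_S`, `H_cond` (the equivocation
#'   `H(Psi | S)`), `H_Psi`, and `MI`, all in nats.
#' @examples
#' entropy_decomposition(diag(2) / 2)$MI # ln 2: perfectly informative mapping
#' @export
entropy_decomposition <- function(joint) {
  joint <- as.matrix(joint)
  if (any(!is.finite(joint)) || any(joint < 0)) {
    stop("joint probabilities must be finite and nonnegative", call. = FALSE)
  }
  if (abs(sum(joint) - 1) > 1e-8) {
    stop("joint distribution must sum to 1", call. = FALSE)
  }
  p_s <- rowSums(joint)
  p_psi <- colSums(joint)
  H_joint <- entropy_nats(as.vector(joint))
  H_S <- entropy_nats(p_s)
  H_Psi <- entropy_nats(p_psi)
  # equivocation: expected entropy of the hidden state given each observation
  H_cond <- H_joint - H_S
  MI <- H_Psi - H_cond
  list(H_joint = H_joint, H_S = H_S, H_cond = H_cond, H_Psi = H_Psi, MI = MI)
}
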