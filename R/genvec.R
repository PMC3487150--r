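# Generalized coordinates of motion: a variable together with its temporal
# derivatives, stored as a (dimension x n_orders) matrix whose first column is
# the value, second the velocity, and so on.

#' Create a variable in generalized coordinates of motion
#'
#' @param value numeric vector (order 0) or a matrix whose columns are
#'   successive temporal derivatives.
#' @param n_orders number of orders to hold; missing higher orders are
#'   zero-filled.
#' @return A `dimension x n_orders` matrix of class `gen_vec`.
#' @export
gen_vec <- function(value, n_orders = 3) {
  m <- if (is.matrix(value)) value else matrix(value, ncol = 1L)
  if (n_orders < 1) stop("n_orders must be >= 1", call. = FALSE)
  if (ncol(m) > n_orders) m <- m[, seq_len(n_orders), drop = FALSE]
  if (ncol(m) < n_orders) {
    m <- cbind(m, matrix(0, nrow(m), n_orders - ncol(m)))
  }
  structure(m, class = c("gen_vec", "matrix"))
}

#' Shift operator on generalized coordinates
#'
#' The differential operator `D` that returns the generalized motion of a
#' variable: order `i` of the output is order `i + 1` of the input and the
#' top order becomes zero, so `D` applied `n` times annihilates an `n`-order
#' variable.
#'
#' @param v a [gen_vec()] or plain matrix whose columns are orders of motion.
#' @return The shifted matrix, same shape and class as `v`.
#' @export
gen_shift <- function(v) {
  n <- ncol(v)
  out <- v
  if (n > 1L) {
    out[, seq_len(n - 1L)] <- v[, 2L:n, drop = FALSE]
  }
  out[, n] <- 0
  out
}

# transpose-shift: order i of output is order i - 1 of input (order 0 -> 0);
# arises from the D^T term in the free-energy gradient
gen_shift_t <- function(v) {
  n <- ncol(v)
  out <- v
  if (n > 1L) {
    out[, 2L:n] <- v[, seq_len(n - 1L), drop = FALSE]
  }
  out[, 1L] <- 0
  out
}
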