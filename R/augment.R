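#' Perturb a feature matrix with Gaussian noise and a Bernoulli mask
#'
#' `x_tilde = b * (x + alpha * eps)` with `eps ~ N(0, 1)` and
#' `b ~ Bernoulli(keep_p)`, drawn i.i.d. per entry and fresh per call from
#' R's global RNG stream. With `alpha = 0` and `keep_p = 1` the input is
#' returned unchanged (and no random numbers are consumed).
#'
#' @param X finite numeric matrix.
#' @param alpha noise standard-deviation multiplier, `>= 0`.
#' @param keep_p probability an entry is kept (not zeroed).
#' @return perturbed matrix, same shape. When the Bernoulli mask is drawn it
#'   is attached as attribute `"mask"` (needed for backpropagation).
#' @export
perturb_features <- function(X, alpha, keep_p) {
  if (alpha == 0 && keep_p == 1) return(X)
  out <- X
  if (alpha > 0)
    out <- out + alpha * matrix(stats::rnorm(length(X)), nrow(X), ncol(X))
  mask <- matrix(stats::rbinom(length(X), 1L, keep_p), nrow(X), ncol(X))
  out <- out * mask
  attr(out, "mask") <- mask
  out
}

#' Randomly mask edges of a graph operator
#'
#' Multiplies the operator elementwise with an i.i.d. Bernoulli(`keep_p`)
#' mask over its *stored nonzeros*; structural zeros stay zero, which is
#' mathematically identical to masking the full matrix. A fresh mask is drawn
#' per call.
#'
#' @param A_tilde sparse nonnegative operator (`dgCMatrix`).
#' @param keep_p probability an edge survives.
#' @return sparse operator with a subset of the edges.
#' @export
corrupt_graph <- function(A_tilde, keep_p) {
  if (keep_p == 1) return(A_tilde)
  A <- methods::as(A_tilde, "CsparseMatrix")
  keep <- stats::rbinom(length(A@x), 1L, keep_p)
  A@x <- A@x * keep
  A
}
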