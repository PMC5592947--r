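## Exact finite-population Wright-Fisher Markov chain, used as a reference
## in validation: the engine's empirical distributions must match matrix
## powers of this chain, and its absorption probabilities recover the
## neutral martingale result and Kimura's diffusion approximation.

#' Exact Wright-Fisher transition matrix
#'
#' Builds the `(Ne+1) x (Ne+1)` single-population transition matrix on
#' derived-allele counts `0..Ne`: from count `i`, the next-generation count
#' is `Binomial(Ne, x_i')` with `x_i' = select_freq(i/Ne, s, h, F)`. Counts
#' 0 and `Ne` are absorbing. Intended for small `Ne` (test scale); refuses
#' `Ne > 500` because of quadratic memory.
#'
#' @param Ne effective chromosome count (`2..500`).
#' @param s,h,F selection, dominance, inbreeding parameters.
#' @return Matrix with rows summing to 1; row/column names are counts.
#' @export
wf_transition_matrix <- function(Ne, s = 0, h = 0.5, F = 0) {
  stopifnot(Ne >= 2)
  if (Ne > 500) stop("transition matrix restricted to Ne <= 500 (quadratic memory)")
  counts <- 0:Ne
  xprime <- select_freq(counts / Ne, s, h, F)
  P <- t(vapply(xprime, function(p) stats::dbinom(counts, Ne, p),
                numeric(Ne + 1)))
  dimnames(P) <- list(counts, counts)
  P
}

#' Fixation probability from the exact chain
#'
#' Probability that the chain started at derived-allele count `start` is
#' absorbed at `Ne` (fixation) rather than 0 (loss), computed by the linear
#' first-step system `(I - Q) u = R` over the transient counts. For the
#' neutral chain this equals `start/Ne` exactly (the martingale property);
#' for weak selection it approaches Kimura's diffusion result
#' `(1 - exp(-Ne*s*p)) / (1 - exp(-Ne*s))` (codominant, outbred).
#'
#' @param matrix a [wf_transition_matrix()].
#' @param start starting count in `0..Ne`.
#' @return Fixation probability.
#' @export
absorption_probability <- function(matrix, start) {
  Ne <- nrow(matrix) - 1L
  stopifnot(start >= 0, start <= Ne)
  if (start == 0) return(0)
  if (start == Ne) return(1)
  interior <- 2:Ne                       # counts 1..Ne-1
  Q <- matrix[interior, interior, drop = FALSE]
  R <- matrix[interior, Ne + 1L]
  u <- solve(diag(Ne - 1L) - Q, R)
  unname(u[start])
}
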