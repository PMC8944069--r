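# Compact radial basis function (CRBF) parameterization of muscle
# excitations.  Each muscle's excitation is the inverse-logit of a sum of
# fixed-center, fixed-width bumps whose amplitudes are the free parameters;
# changing one amplitude alters the excitation only inside that bump's
# support, which keeps the MCMC parameters locally decoupled in time.

#' CRBF basis definition
#'
#' Defines the shared centers and width of the compact radial basis
#' functions used to build muscle excitation signals.  The defaults place
#' ten evenly spaced centers between -0.05 s and 0.55 s (spacing 0.6/9 s)
#' for a 0.5 s motion, with the width equal to twice the node spacing, so
#' each amplitude shapes the excitation over a ~0.27 s window.
#'
#' @param n_nodes number of basis functions per muscle.
#' @param t_start,t_end centers of the first and last node (seconds).
#' @param width common bump half-width (seconds); defaults to twice the
#'   node spacing.
#' @param t_f motion duration (seconds).
#' @return An object of class `crbf_basis` with fields `centers`, `width`,
#'   `n_nodes` and `t_f`.
#' @examples
#' b <- crbf_basis()
#' diff(b$centers)[1]  # 0.0667 s
#' @export
crbf_basis <- function(n_nodes = 10L, t_start = -0.05, t_end = 0.55,
                       width = NULL, t_f = 0.5) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop_invalid("n_nodes must be at least 2")
  centers <- seq(t_start, t_end, length.out = n_nodes)
  spacing <- centers[2L] - centers[1L]
  if (is.null(width)) width <- 2 * spacing
  if (!is.finite(width) || width <= 0) stop_invalid("width must be > 0")
  structure(list(centers = centers, width = width, n_nodes = n_nodes,
                 t_f = t_f),
            class = "crbf_basis")
}

#' @export
print.crbf_basis <- function(x, ...) {
  cat(sprintf("CRBF basis: %d nodes on [%.3f, %.3f] s, width %.4f s\n",
              x$n_nodes, x$centers[1L], x$centers[x$n_nodes], x$width))
  invisible(x)
}

#' Evaluate a single compact radial basis function
#'
#' Computes `A * exp(1 - 1/(1 - ((t - c)/w)^2))` for `|t - c| < w` and
#' exactly 0 for `|t - c| >= w` (the continuous limit at the support
#' boundary).  The peak value at `t = c` is `A`.
#'
#' @param t evaluation times (seconds); may be a vector.
#' @param c bump center (seconds).
#' @param w bump half-width (seconds), `w > 0`.
#' @param A bump amplitude (dimensionless).
#' @return Numeric vector of the same length as `t`.
#' @export
eval_crbf <- function(t, c, w, A = 1) {
  if (!all(is.finite(t)) || !is.finite(c) || !is.finite(w) || !is.finite(A))
    stop_invalid("eval_crbf: t, c, w and A must all be finite")
  if (w <= 0) stop_invalid("eval_crbf: w must be > 0")
  cpp_crbf(as.numeric(t), c, w, A)
}

#' Sum a muscle's CRBFs over a time grid
#'
#' @param basis a [crbf_basis()].
#' @param A_row amplitudes for one muscle, length `basis$n_nodes`.
#' @param t time grid (seconds).
#' @return The pointwise sum `F_m(t)` of the amplitude-scaled bumps.
#' @export
sum_basis <- function(basis, A_row, t) {
  stopifnot(inherits(basis, "crbf_basis"))
  if (length(A_row) != basis$n_nodes)
    stop_shape(sprintf("sum_basis: expected %d amplitudes, got %d",
                       basis$n_nodes, length(A_row)))
  if (!all(is.finite(A_row)) || !all(is.finite(t)))
    stop_invalid("sum_basis: non-finite inputs")
  out <- numeric(length(t))
  for (i in seq_len(basis$n_nodes))
    out <- out + cpp_crbf(as.numeric(t), basis$centers[i], basis$width,
                          A_row[i])
  out
}

#' Numerically stable inverse logit
#'
#' Evaluates `1/(1 + exp(-F))` through a two-branch form in which the
#' exponential is only applied to negative arguments, so there is no
#' overflow even for very large `|F|`.
#'
#' @param F finite numeric vector.
#' @return Values strictly inside (0, 1).
#' @export
inverse_logit_stable <- function(F) {
  if (anyNA(F) || !all(is.finite(F)))
    stop_invalid("inverse_logit_stable: F must be finite")
  pos <- F > 0
  out <- numeric(length(F))
  out[pos] <- 1 / (1 + exp(-F[pos]))
  e <- exp(F[!pos])
  out[!pos] <- e / (1 + e)
  out
}

# canonical amplitude layout: one row per muscle, one column per node;
# flat vectors are filled muscle-major (muscle 1 nodes 1..n, then muscle 2)
as_amplitude_matrix <- function(A, n_muscles, n_nodes) {
  if (is.matrix(A)) {
    if (nrow(A) != n_muscles || ncol(A) != n_nodes)
      stop_shape(sprintf("amplitudes must be %d x %d", n_muscles, n_nodes))
    return(A)
  }
  if (length(A) != n_muscles * n_nodes)
    stop_shape(sprintf("amplitude vector must have length %d",
                       n_muscles * n_nodes))
  matrix(as.numeric(A), nrow = n_muscles, byrow = TRUE)
}

#' Muscle excitations from CRBF amplitudes
#'
#' Maps an amplitude matrix (one row per muscle) to excitation signals on a
#' time grid via [sum_basis()] followed by [inverse_logit_stable()].  The
#' amplitude bounds are enforced as a validity check (matching the uniform
#' prior), not by clipping.
#'
#' @param basis a [crbf_basis()].
#' @param A amplitude matrix `n_muscles x n_nodes`, or a flat vector filled
#'   muscle by muscle.
#' @param t time grid (seconds).
#' @param amp_bound validity bound on each amplitude (default 30).
#' @param n_muscles number of muscles when `A` is a flat vector.
#' @return An object of class `excitation_set`: list with `t` and the
#'   `length(t) x n_muscles` matrix `u`.
#' @export
excitations_from_amplitudes <- function(basis, A, t, amp_bound = 30,
                                        n_muscles = 6L) {
  stopifnot(inherits(basis, "crbf_basis"))
  if (is.matrix(A)) n_muscles <- nrow(A)
  A <- as_amplitude_matrix(A, n_muscles, basis$n_nodes)
  if (!all(is.finite(A)))
    stop_invalid("excitations_from_amplitudes: non-finite amplitudes")
  if (any(abs(A) > amp_bound))
    stop_bounds(sprintf("amplitudes must lie in [-%g, %g]", amp_bound,
                        amp_bound))
  u <- cpp_excitations(A, basis$centers, basis$width, as.numeric(t))
  structure(list(t = as.numeric(t), u = u), class = "excitation_set")
}
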