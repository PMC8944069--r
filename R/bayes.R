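# Log-likelihood, log-prior and log-posterior over the CRBF amplitudes.
#
# The likelihood scores how well a proposal's simulated elbow kinematics
# track the (noisy, filtered) reference; the prior down-weights effortful
# solutions through the integrated-cubed-excitation cost and restricts each
# amplitude to [-amp_bound, amp_bound] via a uniform box.

#' Bayesian model constants
#'
#' @param sigma_pos position denominator of the tracking likelihood (rad).
#' @param sigma_vel velocity denominator (rad/s).
#' @param sigma_effort effort-prior denominator (dimensionless).
#' @param amp_bound uniform box half-width on each CRBF amplitude.
#' @param t_lik likelihood/observation time grid (s).
#' @param dt_sim forward integrator step (s); must divide the likelihood
#'   grid spacing exactly.
#' @return Object of class `bayes_config`.
#' @export
bayes_config <- function(sigma_pos = 0.4, sigma_vel = 1.6,
                         sigma_effort = 0.08, amp_bound = 30,
                         t_lik = seq(0, 0.5, by = 0.01), dt_sim = 0.002) {
  if (sigma_pos <= 0 || sigma_vel <= 0 || sigma_effort <= 0)
    stop_invalid("all sigmas must be > 0")
  step <- (t_lik[2L] - t_lik[1L]) / dt_sim
  if (abs(step - round(step)) > 1e-9)
    stop_invalid("dt_sim must divide the likelihood grid spacing")
  structure(list(sigma_pos = sigma_pos, sigma_vel = sigma_vel,
                 sigma_effort = sigma_effort, amp_bound = amp_bound,
                 t_lik = t_lik, dt_sim = dt_sim),
            class = "bayes_config")
}

# 0-based indices of the likelihood grid inside the integrator grid
lik_indices <- function(cfg) {
  idx <- round(cfg$t_lik / cfg$dt_sim)
  as.integer(idx)
}

#' Tracking log-likelihood
#'
#' `-1/2 * sum_t [ ((theta_ref - theta_pro)/sigma_pos)^2 +
#' ((omega_ref - omega_pro)/sigma_vel)^2 ]` with angles in radians.
#'
#' @param traj proposal trajectory (`mb_trajectory`) on the integrator grid.
#' @param reference a `reference_data` object (see
#'   [make_reference_dataset()]), or any list with `t`, `theta_ref`,
#'   `omega_ref` on the likelihood grid.
#' @param cfg a [bayes_config()].
#' @return Log-density (always <= 0).
#' @export
log_likelihood <- function(traj, reference, cfg = bayes_config()) {
  idx <- match_grid(traj$t, reference$t)
  ep <- (reference$theta_ref - traj$theta[idx]) / cfg$sigma_pos
  ev <- (reference$omega_ref - traj$omega[idx]) / cfg$sigma_vel
  -0.5 * sum(ep^2 + ev^2)
}

match_grid <- function(t_traj, t_ref) {
  idx <- round((t_ref - t_traj[1L]) / (t_traj[2L] - t_traj[1L])) + 1L
  if (any(idx < 1L) || any(idx > length(t_traj)) ||
      any(abs(t_traj[idx] - t_ref) > 1e-9))
    stop_shape("trajectory grid does not contain the likelihood grid")
  idx
}

#' Integrated cubed muscle excitation (effort)
#'
#' Trapezoid-rule value of `sum_m integral u_m(t)^3 dt` over the
#' excitation grid.
#'
#' @param excitations an `excitation_set` on a uniform grid.
#' @return Non-negative scalar.
#' @export
effort_integral <- function(excitations) {
  stopifnot(inherits(excitations, "excitation_set"))
  t <- excitations$t
  dt <- t[2L] - t[1L]
  u3 <- excitations$u^3
  w <- rep(1, length(t))
  w[c(1L, length(t))] <- 0.5
  sum(colSums(u3 * w)) * dt
}

#' Effort log-prior with uniform amplitude box
#'
#' `-1/2 * (effort/sigma_effort)^2 + U(A)` where `U(A)` is 0 when every
#' amplitude lies in the box and `-Inf` otherwise.
#'
#' @param A amplitude matrix or flat vector.
#' @param excitations `excitation_set` derived from `A` on the likelihood
#'   grid.
#' @param cfg a [bayes_config()].
#' @return Log-density; `-Inf` signals an invalid amplitude vector.
#' @export
log_prior <- function(A, excitations, cfg = bayes_config()) {
  if (any(abs(A) > cfg$amp_bound)) return(-Inf)
  -0.5 * (effort_integral(excitations) / cfg$sigma_effort)^2
}

#' Elbow log-posterior closure
#'
#' Builds the black-box target density over the CRBF amplitudes used by the
#' DRAM sampler: amplitudes -> excitations -> forward simulation ->
#' tracking likelihood + effort prior.  Out-of-box amplitude vectors
#' short-circuit to `-Inf` before any simulation; diverged simulations also
#' map to `-Inf` (the chain continues) and are counted.
#'
#' @param reference a `reference_data` object.
#' @param spec an [elbow_spec()].
#' @param basis a [crbf_basis()].
#' @param cfg a [bayes_config()].
#' @param x0 initial [model_state()].
#' @return A function `f(A)` returning a list with `lp`, `loglik`,
#'   `logprior`, `effort` and `diverged`.  The closure tracks `n_sim`
#'   (forward simulations executed) and `n_diverged`, retrievable with
#'   [posterior_counters()].
#' @export
make_elbow_posterior <- function(reference, spec = elbow_spec(),
                                 basis = crbf_basis(),
                                 cfg = bayes_config(),
                                 x0 = model_state(n_muscles = spec$n_muscles)) {
  mp <- muscle_par_matrix(spec)
  idx <- lik_indices(cfg)
  nstep <- max(idx)
  theta_ref <- reference$theta_ref
  omega_ref <- reference$omega_ref
  if (length(theta_ref) != length(idx))
    stop_shape("reference is not on the likelihood grid")
  # CRBF design matrix on the half-step grid; fixed for the basis, so each
  # posterior evaluation only pays for a small matrix product
  thalf <- seq(0, nstep * cfg$dt_sim, by = cfg$dt_sim / 2)
  Bhalf <- sapply(seq_len(basis$n_nodes), function(i)
    cpp_crbf(thalf, basis$centers[i], basis$width, 1))
  counters <- new.env(parent = emptyenv())
  counters$n_sim <- 0L
  counters$n_diverged <- 0L
  f <- function(A, want_traj = FALSE) {
    Am <- as_amplitude_matrix(A, spec$n_muscles, basis$n_nodes)
    res <- cpp_elbow_logpost(Am, Bhalf, mp, spec$I,
                             spec$m_g_d, cfg$dt_sim, nstep, x0$theta,
                             x0$omega, as.numeric(x0$a), idx, theta_ref,
                             omega_ref, cfg$sigma_pos, cfg$sigma_vel,
                             cfg$sigma_effort, cfg$amp_bound, want_traj)
    if (isTRUE(res$simulated)) counters$n_sim <- counters$n_sim + 1L
    if (isTRUE(res$diverged)) {
      counters$n_diverged <- counters$n_diverged + 1L
      warning("forward simulation diverged; proposal given -Inf density")
    }
    res
  }
  attr(f, "counters") <- counters
  attr(f, "d") <- spec$n_muscles * basis$n_nodes
  f
}

#' Evaluation counters of a posterior closure
#'
#' @param posterior closure from [make_elbow_posterior()].
#' @return list with `n_sim` and `n_diverged`.
#' @export
posterior_counters <- function(posterior) {
  cn <- attr(posterior, "counters")
  list(n_sim = cn$n_sim, n_diverged = cn$n_diverged)
}

#' One-shot log-posterior evaluation
#'
#' Convenience wrapper around [make_elbow_posterior()] for a single
#' amplitude vector.
#'
#' @inheritParams make_elbow_posterior
#' @param A amplitude matrix or flat vector.
#' @param want_traj if TRUE, include the simulated kinematics and forces on
#'   the likelihood grid.
#' @return list with `lp`, `loglik`, `logprior`, `effort` and optionally
#'   the trajectory pieces.
#' @export
log_posterior <- function(A, reference, spec = elbow_spec(),
                          basis = crbf_basis(), cfg = bayes_config(),
                          want_traj = FALSE) {
  f <- make_elbow_posterior(reference, spec, basis, cfg)
  f(A, want_traj = want_traj)
}
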