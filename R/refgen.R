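# Reference-data generation: the synthetic "experiment" the sampler is
# asked to explain.  A smooth raised-cosine elbow flexion-extension motion
# is tracked by an effort-penalized optimization in CRBF space to obtain
# ground-truth excitations and forces; measurement noise, zero-phase
# Butterworth filtering and numerical differentiation then produce the
# observed kinematics used by the likelihood.  A closed-form
# mass-spring-damper fixture provides a sampler benchmark with known
# parameters.

#' Smooth reference elbow motion
#'
#' Raised-cosine profile `theta(t) = peak * (1 - cos(2 pi t / t_f))/2`:
#' starts and ends at full extension with zero velocity and reaches `peak`
#' at mid-motion.  The analytic velocity is returned alongside.
#'
#' @param t_f motion duration (s).
#' @param peak peak flexion angle (rad).
#' @param dt grid spacing (s).
#' @return list with `t`, `theta`, `omega`.
#' @export
reference_trajectory <- function(t_f = 0.5, peak = pi / 2, dt = 0.002) {
  if (t_f <= 0) stop_invalid("t_f must be > 0")
  t <- seq(0, t_f, by = dt)
  list(t = t,
       theta = peak * (1 - cos(2 * pi * t / t_f)) / 2,
       omega = peak * pi / t_f * sin(2 * pi * t / t_f))
}

#' Ground-truth excitations by effort-penalized tracking
#'
#' Stand-in for a direct-collocation solve: minimizes the negative
#' log-posterior of the clean target (tracking error in the likelihood
#' metric plus `lambda` times the effort prior term) over the CRBF
#' amplitudes with box constraints, using L-BFGS-B.  Deterministic for a
#' fixed starting point.  Errors if the achieved angle RMSE is not below
#' 1 degree, which indicates an infeasible model specification.
#'
#' @param spec an [elbow_spec()].
#' @param basis a [crbf_basis()].
#' @param cfg a [bayes_config()].
#' @param target clean trajectory from [reference_trajectory()] (any grid
#'   containing the likelihood grid).
#' @param lambda weight on the effort prior term.
#' @param maxit L-BFGS-B iteration cap.
#' @param init starting amplitudes: each value is one start (recycled over
#'   the 60 parameters); the start reaching the lowest objective wins.
#' @return list with `A` (6 x 10 matrix), `excitations`, `forces`,
#'   `trajectory` (full integrator grid), `rmse_deg`, `effort`.
#' @export
solve_reference_excitations <- function(spec = elbow_spec(),
                                        basis = crbf_basis(),
                                        cfg = bayes_config(),
                                        target = reference_trajectory(
                                          dt = cfg$dt_sim),
                                        lambda = 1, maxit = 400,
                                        init = c(-1, -2, -3)) {
  idx <- match_grid(target$t, cfg$t_lik)
  clean <- list(t = cfg$t_lik, theta_ref = target$theta[idx],
                omega_ref = target$omega[idx])
  post <- make_elbow_posterior(clean, spec, basis, cfg)
  d <- spec$n_muscles * basis$n_nodes
  obj <- function(a) {
    r <- post(a)
    if (!is.finite(r$lp)) return(1e10)
    -(r$loglik + lambda * r$logprior)
  }
  fit <- NULL
  for (x0 in init) {
    f <- optim(rep_len(x0, d), obj, method = "L-BFGS-B",
               lower = -cfg$amp_bound + 1e-6, upper = cfg$amp_bound - 1e-6,
               control = list(maxit = maxit, factr = 1e7))
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  A <- as_amplitude_matrix(fit$par, spec$n_muscles, basis$n_nodes)
  traj <- forward_simulate(spec, amplitudes = A, basis = basis,
                           dt = cfg$dt_sim, t_f = max(target$t))
  tidx <- match_grid(traj$t, cfg$t_lik)
  rmse_deg <- sqrt(mean((traj$theta[tidx] - clean$theta_ref)^2)) * 180 / pi
  if (rmse_deg >= 1)
    stop_invalid(sprintf(
      paste0("reference solve tracked to %.2f deg RMSE (>= 1 deg); ",
             "revise the model specification"), rmse_deg))
  exc <- excitations_from_amplitudes(basis, A, cfg$t_lik,
                                     amp_bound = cfg$amp_bound)
  list(A = A, excitations = exc, forces = traj$forces[tidx, , drop = FALSE],
       trajectory = traj, rmse_deg = rmse_deg,
       effort = effort_integral(exc), convergence = fit$convergence)
}

#' Noise, zero-phase filtering and differentiation
#'
#' Adds iid Gaussian measurement noise to an angle series, smooths it with
#' a zero-phase (forward-backward) Butterworth low-pass filter of order 2
#' per pass, and differentiates by central differences (one-sided at the
#' endpoints).
#'
#' @param theta clean angle series (rad) on a uniform grid.
#' @param dt grid spacing (s).
#' @param noise_sd measurement noise SD (rad).
#' @param cutoff filter cutoff (Hz); must be below the Nyquist frequency.
#' @param order Butterworth order per pass.
#' @return list with `theta_f` (filtered angles) and `omega`
#'   (differentiated velocity).
#' @export
add_noise_filter_diff <- function(theta, dt, noise_sd = 0.01, cutoff = 15,
                                  order = 2) {
  fs <- 1 / dt
  if (cutoff >= fs / 2)
    stop_invalid(sprintf("cutoff %g Hz is not below Nyquist %g Hz",
                         cutoff, fs / 2))
  noisy <- theta + rnorm(length(theta), 0, noise_sd)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  n <- length(noisy)
  p <- min(n - 1L, 3L * (2L * order + 1L) * 3L)
  padded <- c(2 * noisy[1L] - noisy[(p + 1L):2L], noisy,
              2 * noisy[n] - noisy[(n - 1L):(n - p)])
  filt <- as.numeric(signal::filtfilt(bf, padded))
  theta_f <- filt[(p + 1L):(p + n)]
  omega <- numeric(n)
  omega[2:(n - 1)] <- (theta_f[3:n] - theta_f[1:(n - 2)]) / (2 * dt)
  omega[1L] <- (theta_f[2L] - theta_f[1L]) / dt
  omega[n] <- (theta_f[n] - theta_f[n - 1L]) / dt
  list(theta_f = theta_f, omega = omega)
}

#' Generate the full synthetic reference dataset
#'
#' Composes [reference_trajectory()], [solve_reference_excitations()] and
#' [add_noise_filter_diff()] into the seeded dataset consumed by the
#' likelihood: noisy filtered angles and differentiated velocities on the
#' observation grid, plus the ground truth (amplitudes, excitations,
#' forces, clean kinematics) for later comparison.
#'
#' @param seed RNG seed for the measurement noise.
#' @param spec an [elbow_spec()].
#' @param basis a [crbf_basis()].
#' @param cfg a [bayes_config()]; its `t_lik` is the observation grid.
#' @param noise_sd measurement noise SD (rad).
#' @param cutoff Butterworth cutoff (Hz).
#' @param peak peak flexion angle (rad).
#' @param solve_args extra arguments for [solve_reference_excitations()].
#' @return Object of class `reference_data` with fields `t`, `theta_ref`,
#'   `omega_ref`, `truth`, `noise_sd`, `cutoff`, `seed`.
#' @export
make_reference_dataset <- function(seed = 1L, spec = elbow_spec(),
                                   basis = crbf_basis(),
                                   cfg = bayes_config(), noise_sd = 0.01,
                                   cutoff = 15, peak = pi / 2,
                                   solve_args = list()) {
  t_f <- max(cfg$t_lik)
  clean_fine <- reference_trajectory(t_f = t_f, peak = peak,
                                     dt = cfg$dt_sim)
  truth <- do.call(solve_reference_excitations,
                   c(list(spec = spec, basis = basis, cfg = cfg,
                          target = clean_fine), solve_args))
  dt_obs <- cfg$t_lik[2L] - cfg$t_lik[1L]
  clean_obs <- reference_trajectory(t_f = t_f, peak = peak, dt = dt_obs)
  set.seed(seed)
  obs <- add_noise_filter_diff(clean_obs$theta, dt_obs,
                               noise_sd = noise_sd, cutoff = cutoff)
  structure(list(
    t = cfg$t_lik, theta_ref = obs$theta_f, omega_ref = obs$omega,
    truth = list(A = truth$A, excitations = truth$excitations,
                 forces = truth$forces, trajectory = truth$trajectory,
                 effort = truth$effort, rmse_deg = truth$rmse_deg,
                 clean = clean_obs),
    noise_sd = noise_sd, cutoff = cutoff, seed = seed, basis = basis,
    peak = peak), class = "reference_data")
}

#' @export
print.reference_data <- function(x, ...) {
  cat(sprintf(
    paste0("Reference dataset: %d samples over %.2f s, noise SD %.3f rad,",
           " %g Hz filter, seed %d\n"),
    length(x$t), max(x$t), x$noise_sd, x$cutoff, x$seed))
  cat(sprintf("  ground-truth effort %.4f, tracking RMSE %.3f deg\n",
              x$truth$effort, x$truth$rmse_deg))
  invisible(x)
}

# --- mass-spring-damper benchmark ------------------------------------------

#' Mass-spring-damper fixture
#'
#' Underdamped oscillator used to validate the sampler on a model with
#' known parameters.
#'
#' @param mass mass (kg).
#' @param k stiffness (N/m).
#' @param c damping (N s/m); must satisfy `c^2 < 4 m k`.
#' @param x0,v0 initial displacement (m) and velocity (m/s).
#' @param t_f,dt observation window and spacing (s).
#' @param noise_sd observation noise SD (m).
#' @return Object of class `msd_fixture`.
#' @export
msd_fixture <- function(mass = 1, k = 100, c = 2, x0 = 0.1, v0 = 0,
                        t_f = 2, dt = 0.01, noise_sd = 0.005) {
  if (mass <= 0 || k <= 0 || c < 0) stop_invalid("need mass, k > 0, c >= 0")
  if (c^2 >= 4 * mass * k) stop_invalid("fixture must be underdamped")
  structure(list(mass = mass, k = k, c = c, x0 = x0, v0 = v0,
                 t = seq(0, t_f, by = dt), noise_sd = noise_sd),
            class = "msd_fixture")
}

#' Closed-form mass-spring-damper displacement
#'
#' @param fix an [msd_fixture()]; `k` and `c` may be overridden to
#'   evaluate candidate parameters against the fixture's grid.
#' @param k,c optional parameter overrides.
#' @param noise if TRUE, adds iid observation noise.
#' @return Displacement series on the fixture grid (m).
#' @export
msd_simulate <- function(fix, k = fix$k, c = fix$c, noise = FALSE) {
  m <- fix$mass
  w0 <- sqrt(k / m)
  zeta <- c / (2 * sqrt(m * k))
  wd <- w0 * sqrt(1 - zeta^2)
  t <- fix$t
  env <- exp(-zeta * w0 * t)
  x <- env * (fix$x0 * cos(wd * t) +
                (fix$v0 + zeta * w0 * fix$x0) / wd * sin(wd * t))
  if (noise) x <- x + rnorm(length(x), 0, fix$noise_sd)
  x
}

#' Log-posterior for mass-spring-damper parameter recovery
#'
#' Gaussian observation likelihood on displacement with the fixture's
#' noise SD and a wide uniform prior (`k` in \[1, 1000\], `c` in
#' \[0.01, 50\]).
#'
#' @param fix an [msd_fixture()].
#' @param data observed displacement series.
#' @return Function of `par = c(k, c)` returning the log-density.
#' @export
msd_log_posterior <- function(fix, data) {
  s2 <- fix$noise_sd^2
  function(par) {
    k <- par[1L]
    c <- par[2L]
    if (k < 1 || k > 1000 || c < 0.01 || c > 50 ||
        c^2 >= 4 * fix$mass * k) return(-Inf)
    x <- msd_simulate(fix, k = k, c = c)
    -0.5 * sum((data - x)^2) / s2
  }
}
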