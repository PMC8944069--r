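# Single degree-of-freedom elbow flexion-extension model actuated by six
# Hill-type muscle-tendon units with rigid tendons and constant moment arms.
# Flexion is positive; moment arms are signed (+ flexor, - extensor).

#' Muscle parameter record
#'
#' @param name muscle name.
#' @param f_max peak isometric force (N).
#' @param l_opt optimal fiber length (m).
#' @param l_ts tendon slack length (m); the tendon is rigid.
#' @param alpha0 pennation angle at optimal length (rad).
#' @param r signed constant moment arm (m); positive for flexors.
#' @param tau_act,tau_deact activation / deactivation time constants (s).
#' @param l_mt0 muscle-tendon unit length at elbow angle 0 (m).  The default
#'   places the fiber at optimal length when the elbow is at 45 degrees.
#' @return One-row data.frame.
#' @export
muscle_params <- function(name, f_max, l_opt, l_ts, alpha0 = 0, r,
                          tau_act = 0.01, tau_deact = 0.04, l_mt0 = NULL) {
  if (f_max <= 0 || l_opt <= 0 || tau_act <= 0 || tau_deact <= 0)
    stop_invalid("f_max, l_opt and time constants must be positive")
  if (is.null(l_mt0)) l_mt0 <- l_ts + l_opt * cos(alpha0) + r * pi / 4
  data.frame(name = name, f_max = f_max, l_opt = l_opt, l_ts = l_ts,
             alpha0 = alpha0, r = r, l_mt0 = l_mt0, tau_act = tau_act,
             tau_deact = tau_deact, stringsAsFactors = FALSE)
}

#' Default six-muscle elbow actuator set
#'
#' Three flexors (brachialis, biceps long and short heads) and three
#' extensors (triceps lateral, medial and long heads).  Peak forces and
#' fiber lengths are in the range typical for adult upper-arm muscles;
#' moment arms are constant-valued stand-ins for the true path geometry.
#'
#' @return data.frame with one row per muscle.
#' @export
default_muscles <- function() {
  rbind(
    muscle_params("brachialis",   987, 0.086, 0.054, 0,  0.025),
    muscle_params("biceps_long",  624, 0.116, 0.272, 0,  0.040),
    muscle_params("biceps_short", 436, 0.132, 0.192, 0,  0.035),
    muscle_params("triceps_long", 799, 0.134, 0.143, 0, -0.025),
    muscle_params("triceps_lat",  624, 0.114, 0.098, 0, -0.022),
    muscle_params("triceps_med",  624, 0.114, 0.091, 0, -0.022)
  )
}

#' Elbow model specification
#'
#' @param muscles data.frame as from [default_muscles()].
#' @param I forearm + hand moment of inertia about the elbow (kg m^2).
#' @param m_g_d peak gravitational torque coefficient (N m); the
#'   gravitational torque is `-m_g_d * sin(theta)`.  Set 0 to disable.
#' @param theta_range allowed elbow angle range (rad).
#' @return Object of class `elbow_spec`.
#' @export
elbow_spec <- function(muscles = default_muscles(), I = 0.06, m_g_d = 2.2,
                       theta_range = c(0, pi)) {
  if (I <= 0) stop_invalid("inertia must be positive")
  structure(list(muscles = muscles, I = I, m_g_d = m_g_d,
                 theta_range = theta_range, n_muscles = nrow(muscles)),
            class = "elbow_spec")
}

#' @export
print.elbow_spec <- function(x, ...) {
  cat(sprintf("Elbow model: %d muscles, I = %.3f kg m^2, m_g_d = %.2f N m\n",
              x$n_muscles, x$I, x$m_g_d))
  print(x$muscles[, c("name", "f_max", "l_opt", "r")], row.names = FALSE)
  invisible(x)
}

#' Initial model state
#'
#' @param theta elbow angle (rad).
#' @param omega angular velocity (rad/s).
#' @param a initial activations per muscle (all 0.02 by default).
#' @param n_muscles number of muscles.
#' @return Object of class `model_state`.
#' @export
model_state <- function(theta = 0, omega = 0, a = rep(0.02, n_muscles),
                        n_muscles = 6L) {
  if (any(a < 0 | a > 1)) stop_invalid("activations must lie in [0, 1]")
  structure(list(theta = theta, omega = omega, a = a), class = "model_state")
}

muscle_par_matrix <- function(spec) {
  m <- spec$muscles
  as.matrix(m[, c("f_max", "l_opt", "l_ts", "alpha0", "r", "l_mt0",
                  "tau_act", "tau_deact")])
}

#' First-order activation dynamics
#'
#' `da/dt = (u - a)/tau_act` when `u > a`, else `(u - a)/tau_deact`.
#'
#' @param u excitation in \[0, 1\].
#' @param a activation in \[0, 1\].
#' @param tau_act,tau_deact time constants (s).
#' @return Activation rate (1/s), vectorized over `u` and `a`.
#' @export
activation_rate <- function(u, a, tau_act = 0.01, tau_deact = 0.04) {
  if (any(u < 0 | u > 1) || any(a < 0 | a > 1))
    stop_invalid("u and a must lie in [0, 1]")
  ifelse(u > a, (u - a) / tau_act, (u - a) / tau_deact)
}

#' Fiber length and velocity from joint state (rigid tendon)
#'
#' With a rigid tendon and constant moment arm, the muscle-tendon length is
#' `l_mt0 - r * theta` and the fiber carries all length change:
#' `l_fiber = (l_mt - l_ts)/cos(alpha0)`, `v_fiber = -r * omega/cos(alpha0)`
#' (positive lengthening).  Fiber length is floored at 1% of optimal.
#'
#' @param theta elbow angle (rad).
#' @param omega angular velocity (rad/s).
#' @param muscle one-row data.frame of muscle parameters.
#' @return list with `l_fiber` (m) and `v_fiber` (m/s).
#' @export
fiber_kinematics <- function(theta, omega, muscle) {
  ca <- cos(muscle$alpha0)
  l_mt <- muscle$l_mt0 - muscle$r * theta
  l_fiber <- (l_mt - muscle$l_ts) / ca
  floor_l <- 0.01 * muscle$l_opt
  if (any(l_fiber < floor_l)) {
    warning("fiber length floored at 1% of optimal length")
    l_fiber <- pmax(l_fiber, floor_l)
  }
  list(l_fiber = l_fiber, v_fiber = -muscle$r * omega / ca)
}

#' Hill-type muscle force
#'
#' `F = F_max * (a * f_L * f_V + f_PE) * cos(alpha0)`, with a Gaussian
#' active force-length curve (`f_L(1) = 1`), a hyperbolic force-velocity
#' curve (`f_V(0) = 1`, zero at normalized shortening velocity -1,
#' eccentric plateau 1.4) and an exponential passive curve that engages
#' beyond optimal length.  Velocity is normalized by `v_max = 10 l_opt/s`.
#' The force is never negative.
#'
#' @param a activation in \[0, 1\].
#' @param l_fiber fiber length (m).
#' @param v_fiber fiber velocity (m/s, positive lengthening).
#' @param muscle one-row data.frame of muscle parameters.
#' @return Muscle force (N).
#' @export
muscle_force <- function(a, l_fiber, v_fiber, muscle) {
  if (any(a < 0 | a > 1)) stop_invalid("activation must lie in [0, 1]")
  ln <- l_fiber / muscle$l_opt
  vn <- v_fiber / (10 * muscle$l_opt)
  cv <- cpp_muscle_curves(ln, vn)
  f <- muscle$f_max * (a * cv[["fl"]] * cv[["fv"]] + cv[["fpe"]]) *
    cos(muscle$alpha0)
  max(f, 0)
}

#' Net joint torque from muscle forces
#'
#' `tau = sum(r_m * F_m) - m_g_d * sin(theta)`; flexion positive.
#'
#' @param forces per-muscle forces (N).
#' @param spec an [elbow_spec()].
#' @param theta elbow angle (rad).
#' @return Torque (N m).
#' @export
joint_torque <- function(forces, spec, theta) {
  if (length(forces) != spec$n_muscles)
    stop_shape("one force per muscle required")
  sum(spec$muscles$r * forces) - spec$m_g_d * sin(theta)
}

#' Forward dynamic simulation of the elbow
#'
#' Integrates the 8-state ODE (angle, angular velocity, six activations)
#' with fixed-step RK4.  Excitations may be given either as CRBF
#' `amplitudes` (with a `basis`), in which case they are evaluated
#' analytically at the RK4 stage times, or as an `excitation_set` on a
#' grid, in which case stage values are linearly interpolated.
#'
#' @param spec an [elbow_spec()].
#' @param amplitudes CRBF amplitude matrix/vector (requires `basis`).
#' @param basis a [crbf_basis()].
#' @param excitations an `excitation_set` (alternative to `amplitudes`).
#' @param x0 initial [model_state()].
#' @param dt integrator step (s).
#' @param t_f final time (s).
#' @return Object of class `mb_trajectory`: list with `t`, `theta`, `omega`,
#'   `activations` and `forces` on the integrator grid.
#' @export
forward_simulate <- function(spec, amplitudes = NULL, basis = NULL,
                             excitations = NULL,
                             x0 = model_state(n_muscles = spec$n_muscles),
                             dt = 0.002, t_f = 0.5) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  nstep <- as.integer(round(t_f / dt))
  thalf <- seq(0, t_f, by = dt / 2)
  if (!is.null(amplitudes)) {
    stopifnot(inherits(basis, "crbf_basis"))
    A <- as_amplitude_matrix(amplitudes, spec$n_muscles, basis$n_nodes)
    uhalf <- cpp_excitations(A, basis$centers, basis$width, thalf)
  } else if (!is.null(excitations)) {
    stopifnot(inherits(excitations, "excitation_set"))
    if (min(excitations$t) > 0 || max(excitations$t) < t_f)
      stop_invalid("excitation grid must cover [0, t_f]")
    uhalf <- apply(excitations$u, 2L, function(col)
      stats::approx(excitations$t, col, xout = thalf, rule = 2)$y)
  } else {
    stop_invalid("supply either amplitudes + basis or excitations")
  }
  res <- cpp_forward(uhalf, muscle_par_matrix(spec), spec$I, spec$m_g_d,
                     dt, nstep, x0$theta, x0$omega, as.numeric(x0$a))
  if (isTRUE(res$diverged))
    stop_diverged(sprintf("simulation diverged at t = %.4f s",
                          res$fail_time), res$fail_time)
  colnames(res$forces) <- spec$muscles$name
  colnames(res$activations) <- spec$muscles$name
  structure(list(t = res$t, theta = res$theta, omega = res$omega,
                 activations = res$activations, forces = res$forces,
                 dt = dt),
            class = "mb_trajectory")
}

#' @export
print.mb_trajectory <- function(x, ...) {
  cat(sprintf(
    "Elbow trajectory: %d samples over %.3f s, peak angle %.1f deg\n",
    length(x$t), max(x$t), max(x$theta) * 180 / pi))
  invisible(x)
}

#' Convert a trajectory to a data.frame
#'
#' @param x an `mb_trajectory`.
#' @param ... unused.
#' @return data.frame with time, kinematics, activations and forces.
#' @export
as.data.frame.mb_trajectory <- function(x, ...) {
  act <- x$activations
  frc <- x$forces
  colnames(act) <- paste0("a_", colnames(act))
  colnames(frc) <- paste0("F_", colnames(frc))
  data.frame(time = x$t, theta = x$theta, omega = x$omega, act, frc,
             check.names = FALSE)
}
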