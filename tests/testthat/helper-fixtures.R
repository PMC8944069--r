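# Shared fixtures, memoized so expensive objects are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_muscle_names <- function() default_muscles()$name

# reference-shaped object built from the clean analytic motion (no noise,
# no optimization) -- enough for likelihood/posterior arithmetic tests
fake_reference <- function(dt = 0.01, t_f = 0.5) {
  rt <- reference_trajectory(t_f = t_f, dt = dt)
  list(t = rt$t, theta_ref = rt$theta, omega_ref = rt$omega)
}

# full reference dataset with a cheap single-start solve, shared by the
# refgen/bayes/diagnostics unit tests
cached_ref_fast <- function() {
  cached("ref_fast", make_reference_dataset(
    seed = 1L, solve_args = list(init = -2, maxit = 250)))
}

# spec with no passive force at full extension (fibers at optimal length
# when theta = 0) and no gravity: at rest with zero excitation nothing
# moves, which makes deterministic dynamics tests exact
passive_free_spec <- function(m_g_d = 0) {
  mus <- default_muscles()
  mus$l_mt0 <- mus$l_ts + mus$l_opt * cos(mus$alpha0)
  elbow_spec(muscles = mus, m_g_d = m_g_d)
}

zero_excitations <- function(t_f = 0.5, dt = 0.002, n_muscles = 6L) {
  t <- seq(0, t_f, by = dt)
  structure(list(t = t, u = matrix(0, length(t), n_muscles)),
            class = "excitation_set")
}

const_excitations <- function(u, t = seq(0, 0.5, by = 0.01),
                              n_muscles = 6L) {
  structure(list(t = t, u = matrix(u, length(t), n_muscles)),
            class = "excitation_set")
}
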