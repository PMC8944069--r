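# Hill-type muscle mechanics and the forward-dynamics integrator.

test_that("activation dynamics follow the two-time-constant first-order lag", {
  expect_equal(activation_rate(0.3, 0.3), 0)
  expect_equal(activation_rate(1, 0, tau_act = 0.01), 100)
  expect_equal(activation_rate(0, 1, tau_deact = 0.04), -25)
  expect_error(activation_rate(1.2, 0), class = "musclebayes_invalid_error")
})

test_that("rigid-tendon fiber kinematics invert the joint state", {
  mus <- default_muscles()[2L, ]  # biceps long head
  k0 <- fiber_kinematics(0.3, 0, mus)
  expect_equal(k0$v_fiber, 0)
  # r = 0 decouples fiber length from the joint angle
  mus0 <- mus; mus0$r <- 0
  expect_equal(fiber_kinematics(0, 0, mus0)$l_fiber,
               fiber_kinematics(1.2, 0, mus0)$l_fiber)
  # construct l_mt0 so the fiber is exactly optimal at theta = pi/2
  mus1 <- muscle_params("probe", 500, 0.1, 0.2, 0, 0.04,
                        l_mt0 = 0.2 + 0.1 + 0.04 * pi / 2)
  expect_equal(fiber_kinematics(pi / 2, 0, mus1)$l_fiber / mus1$l_opt, 1,
               tolerance = 1e-12)
  # extreme flexion shortens below the floor and warns
  expect_warning(fiber_kinematics(20, 0, mus), "floored")
})

test_that("muscle force obeys the Hill scaling laws", {
  mus <- default_muscles()[1L, ]
  lopt <- mus$l_opt
  expect_equal(muscle_force(0, lopt, 0, mus), 0)
  expect_equal(muscle_force(1, lopt, 0, mus), mus$f_max * cos(mus$alpha0))
  # maximal shortening velocity kills active force
  expect_equal(muscle_force(1, lopt, -10 * lopt, mus), 0)
  # eccentric plateau and passive stretch stay below 1.5 F_max
  set.seed(1)
  for (i in 1:50) {
    f <- muscle_force(runif(1), lopt * runif(1, 0.5, 1.4),
                      lopt * runif(1, -12, 12), mus)
    expect_gte(f, 0)
    expect_lte(f, 1.5 * mus$f_max)
  }
})

test_that("joint torque combines signed moment arms and gravity", {
  spec <- elbow_spec(m_g_d = 0)
  expect_equal(joint_torque(rep(0, 6), spec, 0.4), 0)
  # biceps long head (r = 0.04) at 100 N gives +4 N m
  expect_equal(joint_torque(c(0, 100, 0, 0, 0, 0), spec, 0), 4)
  # flexor and extensor torques of equal magnitude cancel
  f_flex <- c(100, 0, 0, 0, 0, 0)                       # r = +0.025
  f_ext <- c(0, 0, 0, 100, 0, 0)                        # r = -0.025
  expect_equal(joint_torque(f_flex + f_ext, spec, 0), 0)
  specg <- elbow_spec(m_g_d = 2.2)
  expect_equal(joint_torque(rep(0, 6), specg, pi / 2), -2.2)
})

test_that("a passive-free model at rest with zero drive stays at rest", {
  spec <- passive_free_spec()
  tr <- forward_simulate(spec, excitations = zero_excitations(),
                         x0 = model_state(a = rep(0, 6)))
  expect_equal(tr$theta, rep(0, length(tr$t)), tolerance = 1e-12)
  expect_equal(tr$omega, rep(0, length(tr$t)), tolerance = 1e-12)
  expect_equal(max(abs(tr$forces)), 0)
})

test_that("with no muscle force and no gravity the joint coasts", {
  # all flexor moment arms, fibers kept short of optimal while flexing:
  # zero activation + zero passive force means exactly zero torque
  mus <- default_muscles()
  mus$r <- abs(mus$r)
  mus$l_mt0 <- mus$l_ts + 0.95 * mus$l_opt
  spec <- elbow_spec(muscles = mus, m_g_d = 0)
  tr <- forward_simulate(spec, excitations = zero_excitations(),
                         x0 = model_state(omega = 3, a = rep(0, 6)))
  expect_equal(tr$omega, rep(3, length(tr$t)), tolerance = 1e-10)
  expect_equal(tr$theta, 3 * tr$t, tolerance = 1e-9)
})

test_that("flexor drive accelerates flexion, extensor drive extension", {
  spec <- passive_free_spec()
  b <- crbf_basis()
  flex <- matrix(-30, 6, 10); flex[1:3, ] <- 5
  ext <- matrix(-30, 6, 10); ext[4:6, ] <- 5
  x0 <- model_state(a = rep(0, 6))
  tr_f <- forward_simulate(spec, amplitudes = flex, basis = b, x0 = x0)
  tr_e <- forward_simulate(spec, amplitudes = ext, basis = b, x0 = x0)
  expect_gt(tail(tr_f$theta, 1), 0.1)
  expect_lt(tail(tr_e$theta, 1), -0.1)
})

test_that("RK4 integration converges and is deterministic", {
  spec <- elbow_spec()
  b <- crbf_basis()
  set.seed(11)
  A <- matrix(runif(60, -4, 1), 6, 10)
  t1 <- forward_simulate(spec, amplitudes = A, basis = b, dt = 0.002)
  t2 <- forward_simulate(spec, amplitudes = A, basis = b, dt = 0.001)
  expect_lt(abs(tail(t1$theta, 1) - tail(t2$theta, 1)), 1e-6)
  t3 <- forward_simulate(spec, amplitudes = A, basis = b, dt = 0.002)
  expect_identical(t1$theta, t3$theta)  # bit-reproducible
  expect_identical(t1$forces, t3$forces)
})

test_that("activations stay in [0,1] and forces stay physical", {
  spec <- elbow_spec()
  b <- crbf_basis()
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(runif(60, -30, 30), 6, 10)
    tr <- forward_simulate(spec, amplitudes = A, basis = b)
    expect_true(all(tr$activations >= 0 & tr$activations <= 1))
    expect_true(all(tr$forces >= 0))
    expect_true(all(t(tr$forces) <= 1.5 * spec$muscles$f_max))
  }
})

test_that("trajectories flatten to a well-formed data frame", {
  spec <- elbow_spec()
  tr <- forward_simulate(spec, excitations = zero_excitations())
  df <- as.data.frame(tr)
  expect_equal(nrow(df), length(tr$t))
  expect_equal(ncol(df), 3 + 2 * 6)
  expect_true(!anyDuplicated(names(df)))
})
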