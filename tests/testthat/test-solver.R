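test_that("straight undriven filament is an equilibrium of the RHS", {
  sys <- ehd_system(ehd_structure(NULL, filament(6, 1)), overlap_corrected = TRUE)
  X0 <- initial_state(sys)
  expect_equal(max(abs(ehd_rhs(sys, X0, 0))), 0, tolerance = 1e-12)
  # quaternion backend agrees
  expect_equal(max(abs(ehd_rhs_quat(sys, state_to_quat(sys, X0), 0))), 0,
               tolerance = 1e-12)
})

test_that("relaxation reduces elastic energy from the first step", {
  scn <- scenario_relaxation(N = 8, n = 1, S = 3, tend = 0.1, nout = 3)
  sys <- scn$system; X0 <- scn$state0
  E0 <- elastic_energy(sys, X0)
  Xdot <- ehd_rhs(sys, X0, 0)
  h <- 1e-4
  expect_lt(elastic_energy(sys, X0 + h * Xdot), E0)
})

test_that("backends give identical sphere velocities at the same state", {
  ps <- perturbed_filament_system(N = 5, n = 1, seed = 61, body = TRUE)
  sys <- ps$sys; X <- ps$X
  sol <- ehd_rhs(sys, X, 0.3, extras = TRUE)
  # quaternion backend: V = Q W from its own solve
  Xq <- state_to_quat(sys, X)
  up <- elastocg:::.quat_unpack(sys, Xq)
  op <- elastocg:::.ehd_operators(sys, up$X, 0.3, quats = up$quats)
  A <- op$MF %*% apply_inverse_mobility(op$MH, op$Q)
  Wq <- solve(A, op$K)
  expect_equal(drop(op$Q %*% Wq), sol$V, tolerance = 1e-9)
})

test_that("post-solve balance residual is tiny, with and without constraints", {
  ps <- perturbed_filament_system(N = 5, n = 2, seed = 62, body = FALSE)
  expect_lt(balance_residual(ps$sys, ps$X, 0), 1e-10)
  cons <- list(kinematic_constraint(1,
    translation = function(t) c(0.1 * sin(t), 0, 0),
    rotation = function(t) c(0, 0.05 * cos(t), 0)))
  expect_lt(balance_residual(ps$sys, ps$X, 0.4, cons), 1e-10)
})

test_that("force-free structures carry zero total force and torque", {
  ps <- perturbed_filament_system(N = 4, n = 2, seed = 63, body = TRUE)
  sol <- ehd_rhs(ps$sys, ps$X, 0, extras = TRUE)
  expect_equal(colSums(sol$forces), c(0, 0, 0), tolerance = 1e-10)
  g <- elastocg:::system_geometry(ps$sys, ps$X)
  tor <- colSums(t(vapply(seq_len(ps$sys$M), function(k)
    vcross(g$Y[k, ] - g$struct[[1]]$x_b, sol$forces[k, ]) + sol$torques[k, ],
    numeric(3))))
  expect_equal(tor, c(0, 0, 0), tolerance = 1e-10)
})

test_that("pinning the base clamps the filament like a cantilever", {
  scn <- scenario_relaxation(N = 6, n = 1, S = 2, tend = 0.5, nout = 3)
  cons <- list(kinematic_constraint(1,
    translation = function(t) c(0, 0, 0),
    rotation = function(t) c(0, 0, 0)))
  traj <- ehd_integrate(scn$system, scn$state0, scn$times, constraints = cons)
  X0 <- scn$state0; Xf <- trajectory_state(traj, 3)
  expect_equal(Xf[1:6], X0[1:6], tolerance = 1e-6) # base pose unchanged
  expect_gt(max(abs(Xf - X0)), 0.01)               # but the tail relaxed
})

test_that("helical constraint traces the prescribed base circle", {
  scn <- scenario_helical(delta0 = 0.1, alpha0 = 0.2618, Sp = 2, N = 6,
                          periods = 1, nout_per_period = 8)
  res <- run_scenario(scn)
  xb <- t(vapply(seq_along(res$trajectory$times), function(k)
    trajectory_state(res$trajectory, k)[1:3], numeric(3)))
  tt <- res$trajectory$times
  expect_equal(xb, 0.1 * cbind(cos(tt), -sin(tt), 0), tolerance = 1e-3,
               ignore_attr = TRUE)
  # generator follows r_1(t) = alpha0/2 (sin t, cos t, 0)
  rb <- t(vapply(seq_along(tt), function(k)
    trajectory_state(res$trajectory, k)[4:6], numeric(3)))
  expect_equal(rb, 0.2618 / 2 * cbind(sin(tt), cos(tt), 0), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("duplicate constraints and fixed-structure constraints are rejected", {
  sys <- ehd_system(ehd_structure(NULL, filament(3, 1)), overlap_corrected = TRUE)
  c1 <- kinematic_constraint(1, translation = function(t) c(0, 0, 0))
  expect_error(ehd_rhs(sys, initial_state(sys), 0, list(c1, c1)), "duplicate")
  wall <- ehd_system(ehd_structure(build_wall(2, 2),
                                   filament(3, 1, attach_offset = c(0, 0, 0.1)),
                                   fixed = TRUE), overlap_corrected = TRUE)
  expect_error(ehd_rhs(wall, initial_state(wall), 0, list(c1)), "fixed")
})

test_that("generator rescaling is transparent to the dynamics", {
  # spin a filament base fast enough that |r_b| crosses pi/2 mid-run
  sys <- ehd_system(ehd_structure(NULL, filament(4, 1)), overlap_corrected = TRUE)
  X0 <- initial_state(sys)
  cons <- list(kinematic_constraint(1,
    translation = function(t) c(0, 0, 0),
    rotation = function(t) c(0.6, 0, 0)))
  times <- seq(0, 3.6, by = 0.3) # |r_b| = 0.6 t crosses pi/2 near t = 2.6
  traj <- ehd_integrate(sys, X0, times, constraints = cons, rtol = 1e-8,
                        atol = 1e-10)
  expect_gt(traj$stats["events"], 0) # rescaling did fire
  # |r| stayed below pi/2 + one step's growth
  rmax <- max(vapply(seq_along(times), function(k) {
    X <- trajectory_state(traj, k)
    max(vapply(sys$gen_slices, function(sl) sqrt(sum(X[sl]^2)), numeric(1)))
  }, numeric(1)))
  expect_lt(rmax, pi / 2 + 0.3)
  # sphere positions match the quaternion backend (which never rescales)
  trajq <- ehd_integrate(sys, X0, times, backend = "quaternion",
                         constraints = cons, rtol = 1e-8, atol = 1e-10)
  expect_equal(trajectory_positions(traj, length(times)),
               trajectory_positions(trajq, length(times)), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("quaternion norms stay near 1 over a relaxation run", {
  scn <- scenario_relaxation(N = 6, n = 1, S = 3, tend = 2, nout = 5)
  traj <- ehd_integrate(scn$system, scn$state0, scn$times,
                        backend = "quaternion", rtol = 1e-9, atol = 1e-11)
  info <- scn$system$struct[[1]]
  for (k in seq_along(traj$times)) {
    Xq <- traj$X[k, ]
    qs <- c(list(Xq[info$qstate_qb]),
            lapply(info$fil[[1]]$qstate_q, function(sl) Xq[sl]))
    for (q in qs) expect_equal(sum(q^2), 1, tolerance = 1e-6)
  }
})

test_that("halving tolerances changes the endpoint negligibly (convergence)", {
  scn <- scenario_relaxation(N = 6, n = 1, S = 3, tend = 1, nout = 3)
  t1 <- ehd_integrate(scn$system, scn$state0, scn$times, rtol = 1e-6, atol = 1e-8)
  t2 <- ehd_integrate(scn$system, scn$state0, scn$times, rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(trajectory_state(t1, 3) - trajectory_state(t2, 3))), 1e-5)
})
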