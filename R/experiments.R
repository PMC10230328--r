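# Scenario builders and measurements: filament relaxation, helical actuation,
# undulatory swimmers, bi-flagellate puller, sperm-egg scattering, cilia array
# with tracer transport.
#
# Dimensionless conventions: lengths in units of the filament length L,
# viscosity eta = 1, drive frequency 1 (period 2*pi), and Eb = Et = 1/S^4
# where S^4 = L^4 eta omega / Eb is the stiffness parameter. Preferred
# curvatures are in 1/L, active moment densities in Eb/L^2.

.period <- 2 * pi

.scenario <- function(id, params, system, state0, times, constraints = list(),
                      measure, solver = list()) {
  structure(list(id = id, params = params, system = system, state0 = state0,
                 times = times, constraints = constraints, measure = measure,
                 solver = solver),
            class = "ehd_scenario")
}

#' @export
print.ehd_scenario <- function(x, ...) {
  cat("ehd_scenario:", x$id, "\n")
  str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Run a scenario
#'
#' Integrates a scenario built by one of the `scenario_*()` constructors and
#' applies its measurement function.
#'
#' @param scn An `ehd_scenario`.
#' @param backend Integration backend.
#' @param rtol,atol Solver tolerances (defaults may be overridden per
#'   scenario).
#' @param ... Passed to [ehd_integrate()].
#' @return List with elements `trajectory` and `measurements` (named list).
#' @export
run_scenario <- function(scn, backend = "expmap", rtol = NULL, atol = NULL, ...) {
  stopifnot(inherits(scn, "ehd_scenario"))
  rtol <- if (is.null(rtol)) scn$solver$rtol %||% 1e-6 else rtol
  atol <- if (is.null(atol)) scn$solver$atol %||% 1e-8 else atol
  traj <- ehd_integrate(scn$system, scn$state0, scn$times, backend = backend,
                        constraints = scn$constraints, rtol = rtol,
                        atol = atol, ...)
  list(trajectory = traj, measurements = scn$measure(traj))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# displacement of the centre of mass per drive period, from output times that
# include the period marks; steady when the last two periods agree to 0.1%
.per_period_displacement <- function(traj, period = .period, structure = NULL) {
  com <- com_positions(traj, structure)
  tt <- traj$times
  marks <- which(abs(tt / period - round(tt / period)) < 1e-8)
  if (length(marks) < 2) stop("output times do not include period marks")
  d <- sqrt(rowSums((com[marks[-1], , drop = FALSE] -
                     com[marks[-length(marks)], , drop = FALSE])^2))
  np <- length(d)
  steady <- np >= 2 && abs(d[np] - d[np - 1]) <= 1e-3 * abs(d[np])
  list(displacements = d, last = d[np], steady = steady,
       com = com, marks = marks)
}

# ---- relaxation (free filament, semicircle initial condition) --------------

#' Relaxation of a bent free filament
#'
#' A free filament initially bent into a semicircle (segment generators
#' `r_i = (theta_i/2) * (0,1,0)` with `theta_i = (i-1) pi / (N-1)`) relaxes
#' to a straight configuration. Measurements: maximum centre-of-mass drift
#' over the run (conserved to within 2e-2 L) and the final maximum joint
#' curvature (straightness).
#'
#' @param N Segments (default 40).
#' @param n Spheres per segment (default 2).
#' @param S Stiffness parameter (default 3).
#' @param tend Final time (default 20).
#' @param nout Number of output times.
#' @return An `ehd_scenario`.
#' @export
scenario_relaxation <- function(N = 40, n = 2, S = 3, tend = 20, nout = 41) {
  params <- list(N = N, n = n, S = S, tend = tend, nout = nout)
  fil <- filament(N, n, Eb = 1 / S^4)
  sys <- ehd_system(ehd_structure(NULL, fil), overlap_corrected = TRUE)
  X0 <- initial_state(sys)
  nhat <- c(0, 1, 0)
  info <- sys$struct[[1]]
  # theta_1 = 0 so r_b (= r_1) stays zero
  for (i in 2:N) {
    theta <- (i - 1) * pi / (N - 1)
    X0[info$fil[[1]]$state_r[[i - 1]]] <- theta / 2 * nhat
  }
  times <- seq(0, tend, length.out = nout)
  measure <- function(traj) {
    com <- com_positions(traj)
    drift <- sqrt(rowSums((com - rep(com[1, ], each = nrow(com)))^2))
    Xf <- trajectory_state(traj, length(traj$times))
    list(com_drift = max(drift),
         final_max_curvature = max_curvature(traj$sys, Xf))
  }
  .scenario("relax", params, sys, X0, times, measure = measure)
}

# ---- helical actuation -----------------------------------------------------

#' Helically actuated filament
#'
#' One end of a filament is driven on a circle of radius `delta0` about the
#' z-axis while tilted at angle `alpha0`, by replacing the force-free rows
#' with `xdot_1 = -delta0 (sin t, cos t, 0)` and the torque-free rows with
#' `rdot_1 = (alpha0/2) (cos t, -sin t, 0)`. The sperm number sets the
#' stiffness through `Sp^4 = (4 pi / (log(L/a) + 0.5)) S^4`. Measurement:
#' time-averaged distance of the filament tip from the rotation axis over the
#' final period.
#'
#' @param delta0 Base circle radius (L).
#' @param alpha0 Tilt angle (radians; default 0.2618).
#' @param Sp Sperm number.
#' @param N,n Discretization (defaults 20, 1).
#' @param periods Number of drive periods to integrate.
#' @param nout_per_period Output density.
#' @return An `ehd_scenario`.
#' @export
scenario_helical <- function(delta0 = 0.1, alpha0 = 0.2618, Sp = 2, N = 20,
                             n = 1, periods = 8, nout_per_period = 16) {
  params <- list(delta0 = delta0, alpha0 = alpha0, Sp = Sp, N = N, n = n,
                 periods = periods, nout_per_period = nout_per_period)
  a <- 1 / (2 * N * n)
  S4 <- Sp^4 * (log(1 / a) + 0.5) / (4 * pi)
  fil <- filament(N, n, Eb = 1 / S4)
  sys <- ehd_system(ehd_structure(NULL, fil, x_b = c(delta0, 0, 0)),
                    overlap_corrected = TRUE)
  X0 <- initial_state(sys)
  info <- sys$struct[[1]]
  r0 <- alpha0 / 2 * c(0, 1, 0)
  X0[info$state_rb] <- r0
  for (i in 2:N) X0[info$fil[[1]]$state_r[[i - 1]]] <- r0
  cons <- list(kinematic_constraint(1,
    translation = function(t) -delta0 * c(sin(t), cos(t), 0),
    rotation = function(t) alpha0 / 2 * c(cos(t), -sin(t), 0)))
  times <- seq(0, periods * .period, by = .period / nout_per_period)
  measure <- function(traj) {
    tipd <- vapply(seq_along(traj$times), function(k) {
      g <- system_geometry(traj$sys, trajectory_state(traj, k))
      ends <- g$struct[[1]]$fil[[1]]$ends
      tip <- ends[N, ] + fil$ds * g$struct[[1]]$fil[[1]]$dirs[, 3, N]
      sqrt(sum(tip[1:2]^2))
    }, numeric(1))
    npp <- nout_per_period
    last <- mean(tipd[(length(tipd) - npp + 1):length(tipd)])
    prev <- if (length(tipd) > 2 * npp)
      mean(tipd[(length(tipd) - 2 * npp + 1):(length(tipd) - npp)]) else NA_real_
    list(tip_distance = last, prev_period = prev,
         steady = isTRUE(abs(last - prev) <= 5e-3 * abs(last)))
  }
  .scenario("helix", params, sys, X0, times, constraints = cons,
            measure = measure)
}

# ---- undulatory swimmer(s) -------------------------------------------------

.swimmer_K0 <- function(s) if (s <= 0.5) 8.25 else 16.5 * (1 - s)

.swimmer_drive <- function(k, phase = 0) {
  force(k); force(phase)
  function(s, t) c(-.swimmer_K0(s) * sin(k * s - t - phase), 0, 0)
}

#' Undulatory swimmer (single or hydrodynamically coupled pair)
#'
#' Free filament(s) driven by the piecewise curvature wave
#' `kappa0(s,t) = -K0(s) sin(k s - t) d1` with `K0 = 8.25` for `s <= L/2` and
#' `16.5 (L - s)/L` beyond, at stiffness `S = 22.6^(1/4)`. The beat is planar
#' (in the y-z plane for the default orientation). For a pair, the swimmers
#' start a distance `l` apart along y (in the beat plane) and beat in phase or
#' in anti-phase. Measurement: centre-of-mass distance travelled per stroke
#' (per drive period) once periodic steady state is reached.
#'
#' @param pair Simulate two swimmers.
#' @param phase `"in"` or `"anti"` (pair only).
#' @param l Initial pair separation (L).
#' @param k Curvature wavenumber. Not printed in the source material; the
#'   default `2*pi/1.54` is one undulation wavelength per 1.54 L, the measured
#'   swimming gait of the C. elegans-like undulator this drive models.
#' @param S Stiffness parameter (default `22.6^0.25`).
#' @param N,n Discretization (defaults 16, 1).
#' @param periods Drive periods to integrate.
#' @param nout_per_period Output density.
#' @param init_state Optional single-swimmer state (e.g. the steady state) to
#'   use as the initial shape; replicated with the offset for pairs, or a
#'   list of two states (one per swimmer; for anti-phase pairs the second
#'   swimmer's shape should be the solo state half a drive period earlier,
#'   consistent with its shifted drive).
#' @return An `ehd_scenario`.
#' @export
scenario_swimmer <- function(pair = FALSE, phase = c("in", "anti"), l = 0.5,
                             k = 2 * pi / 1.54, S = 22.6^0.25, N = 16, n = 1,
                             periods = 10, nout_per_period = 8,
                             init_state = NULL) {
  phase <- match.arg(phase)
  params <- list(pair = pair, phase = phase, l = l, k = k, S = S, N = N,
                 n = n, periods = periods, nout_per_period = nout_per_period)
  Eb <- 1 / S^4
  mk_fil <- function(ph) filament(N, n, Eb = Eb,
                                  drive_curvature = .swimmer_drive(k, ph))
  if (!pair) {
    sys <- ehd_system(ehd_structure(NULL, mk_fil(0)), overlap_corrected = TRUE)
    X0 <- if (is.null(init_state)) initial_state(sys) else init_state
  } else {
    ph2 <- if (phase == "anti") pi else 0
    sys <- ehd_system(list(
      ehd_structure(NULL, mk_fil(0)),
      ehd_structure(NULL, mk_fil(ph2), x_b = c(0, l, 0))),
      overlap_corrected = TRUE)
    X0 <- initial_state(sys)
    if (!is.null(init_state)) {
      st2 <- if (is.list(init_state)) init_state[[2]] else init_state
      st1 <- if (is.list(init_state)) init_state[[1]] else init_state
      half <- length(st1)
      X0[1:half] <- st1
      X0[half + 1:half] <- st2
      X0[sys$struct[[2]]$state_x] <- st2[1:3] + c(0, l, 0)
    }
  }
  times <- seq(0, periods * .period, by = .period / nout_per_period)
  measure <- function(traj) {
    if (!pair) {
      pp <- .per_period_displacement(traj)
      list(distance_per_stroke = pp$last, steady = pp$steady,
           displacements = pp$displacements)
    } else {
      p1 <- .per_period_displacement(traj, structure = 1)
      p2 <- .per_period_displacement(traj, structure = 2)
      list(distance_per_stroke = mean(c(p1$last, p2$last)),
           swimmer1 = p1$last, swimmer2 = p2$last,
           steady = p1$steady && p2$steady)
    }
  }
  .scenario("swim", params, sys, X0, times, measure = measure)
}

# ---- bi-flagellate puller (Chlamydomonas-like) -----------------------------

#' Bi-flagellate puller swimmer
#'
#' A spherical body of radius `R` built from `Nbody` spheres with two flagella
#' clamped at angles `+-theta` from the body axis, driven by the preferred
#' curvature `kappa0 = kappa1 d1 +- 4 (1 + sin(2 pi s - t)) d2` (mirrored
#' between the flagella, which beat in the x-z plane with `d2` along y).
#' Symmetric out-of-plane curvature `kappa1` bends the path into a circle;
#' equal-and-opposite `kappa1` gives straight swimming with body roll.
#' `coupling = "reduced"` switches off RPY terms between body and flagella
#' (and between the flagella).
#'
#' @param R Body radius (L).
#' @param Nbody Spheres in the body shell.
#' @param theta Half-angle between the flagella (radians; default 11.5
#'   degrees).
#' @param N,n Flagellum discretization.
#' @param S Stiffness parameter.
#' @param kappa1 Length-2 out-of-plane preferred curvatures of the two
#'   flagella (1/L).
#' @param coupling `"full"` or `"reduced"`.
#' @param periods Drive periods.
#' @param nout_per_period Output density.
#' @return An `ehd_scenario`.
#' @export
scenario_chlamydomonas <- function(R = 0.35, Nbody = 184,
                                   theta = 11.5 * pi / 180, N = 15, n = 1,
                                   S = 3, kappa1 = c(0, 0),
                                   coupling = c("full", "reduced"),
                                   periods = 6, nout_per_period = 8) {
  coupling <- match.arg(coupling)
  params <- list(R = R, Nbody = Nbody, theta = theta, N = N, n = n, S = S,
                 kappa1 = kappa1, coupling = coupling, periods = periods,
                 nout_per_period = nout_per_period)
  Eb <- 1 / S^4
  body <- build_spherical_body(R, Nbody)
  drive <- function(sign, k1) {
    force(sign); force(k1)
    function(s, t) c(k1, sign * 4 * (1 + sin(2 * pi * s - t)), 0)
  }
  mk_fil <- function(sgn, k1) {
    filament(N, n, Eb = Eb, drive_curvature = drive(sgn, k1),
             attach_offset = R * c(sgn * sin(theta), 0, cos(theta)),
             clamp = quat_from_axis_angle(c(0, 1, 0), sgn * theta))
  }
  st <- ehd_structure(body, list(mk_fil(+1, kappa1[1]), mk_fil(-1, kappa1[2])))
  sys <- ehd_system(st, overlap_corrected = TRUE, coupling = coupling)
  X0 <- initial_state(sys)
  times <- seq(0, periods * .period, by = .period / nout_per_period)
  measure <- function(traj) {
    pp <- .per_period_displacement(traj, structure = 1)
    com <- pp$com[pp$marks, , drop = FALSE]
    np <- nrow(com) - 1
    # per-period displacement vectors; turning angle between the last two
    v1 <- com[np, ] - com[np - 1, ]; v2 <- com[np + 1, ] - com[np, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    turn <- acos(pmin(1, pmax(-1, cosang)))
    radius <- if (turn > 1e-6) pp$last / (2 * sin(turn / 2)) else Inf
    # body roll: rotation about the swimming direction over the last period
    k1 <- pp$marks[np]; k2 <- pp$marks[np + 1]
    q1 <- exp_map(trajectory_state(traj, k1)[traj$sys$struct[[1]]$state_rb])
    q2 <- exp_map(trajectory_state(traj, k2)[traj$sys$struct[[1]]$state_rb])
    qrel <- quat_multiply(q2, quat_conjugate(q1))
    rrel <- log_map(qrel) # angle 2|r| about axis r
    dir <- v2 / sqrt(sum(v2^2))
    roll <- 2 * sum(rrel * dir)
    list(distance_per_stroke = pp$last, steady = pp$steady,
         turn_per_stroke = turn, path_radius = radius, roll_per_stroke = roll)
  }
  .scenario("chlamy", params, sys, X0, times, measure = measure)
}

# ---- sperm-egg scattering --------------------------------------------------

#' Sperm-egg elastohydrodynamic scattering
#'
#' A sperm (spherical head of radius 0.2 L, flagellum of `N` segments driven
#' by the active moment density `m_a = 12 k cos(k s - t) d2`, stiffness
#' `S = 6`) swims past a free spherical egg of radius 1 L. The initial
#' head-egg separation is `separation` and the sperm axis makes angle `theta`
#' with the line to the egg. Measurements: swimming speed versus time and
#' versus sperm-egg separation.
#'
#' @param theta Initial heading offset (radians).
#' @param separation Initial head-egg centre distance (L; default 5).
#' @param egg Include the egg (set `FALSE` for the free-space reference).
#' @param S Stiffness parameter (default 6).
#' @param N,n Flagellum discretization (defaults 16, 1).
#' @param k Active-moment wavenumber (default `2*pi`, not printed in the
#'   source material).
#' @param head_radius,egg_radius Sphere radii (L).
#' @param egg_nspheres Spheres in the egg shell. A single force- and
#'   torque-free RPY sphere scatters no flow at all (it is hydrodynamically
#'   invisible to the swimmer), so reproducing the published speed modulation
#'   requires a sphere-composite egg; the default is a 128-sphere shell.
#' @param periods Drive periods to integrate.
#' @param nout_per_period Output density.
#' @return An `ehd_scenario`.
#' @export
scenario_sperm_egg <- function(theta = pi / 12, separation = 5, egg = TRUE,
                               S = 6, N = 16, n = 1, k = 2 * pi,
                               head_radius = 0.2, egg_radius = 1,
                               egg_nspheres = 128,
                               periods = 40, nout_per_period = 4) {
  params <- list(theta = theta, separation = separation, egg = egg, S = S,
                 N = N, n = n, k = k, head_radius = head_radius,
                 egg_radius = egg_radius, egg_nspheres = egg_nspheres,
                 periods = periods, nout_per_period = nout_per_period)
  Eb <- 1 / S^4
  fil <- filament(N, n, Eb = Eb,
                  active_moment = active_moment_wave(12 * k, k, component = 2),
                  attach_offset = c(0, 0, -head_radius),
                  clamp = quat_from_axis_angle(c(1, 0, 0), pi)) # tail along -z
  sperm <- ehd_structure(build_spherical_body(head_radius, 1), fil,
                         x_b = c(0, 0, -separation),
                         q_b = quat_from_axis_angle(c(1, 0, 0), theta))
  structures <- list(sperm)
  if (egg) structures <- c(structures,
                           list(ehd_structure(build_spherical_body(egg_radius,
                                                                   egg_nspheres))))
  sys <- ehd_system(structures, overlap_corrected = TRUE)
  X0 <- initial_state(sys)
  times <- seq(0, periods * .period, by = .period / nout_per_period)
  measure <- function(traj) {
    com <- com_positions(traj, structure = 1)
    tt <- traj$times
    npp <- nout_per_period
    # speed over sliding one-period windows (stroke-averaged)
    idx <- seq_len(length(tt) - npp)
    speed <- sqrt(rowSums((com[idx + npp, , drop = FALSE] -
                           com[idx, , drop = FALSE])^2)) / .period
    tmid <- (tt[idx] + tt[idx + npp]) / 2
    sep <- if (egg) {
      d <- t(vapply(seq_along(tt), function(kk) {
        X <- trajectory_state(traj, kk)
        X[traj$sys$struct[[1]]$state_x] - X[traj$sys$struct[[2]]$state_x]
      }, numeric(3)))
      sqrt(rowSums(d^2))
    } else rep(NA_real_, length(tt))
    list(speed = speed, time = tmid,
         separation = if (egg) (sep[idx] + sep[idx + npp]) / 2 else sep[idx],
         min_separation = if (egg) min(sep) else NA_real_,
         final_speed = speed[length(speed)],
         min_speed = min(speed[-seq_len(min(2 * npp, length(speed) - 1))]))
  }
  .scenario("sperm-egg", params, sys, X0, times, measure = measure)
}

# ---- cilia array and tracer transport --------------------------------------

#' Cilia array over a sphere-built wall, with passive tracers
#'
#' `rows x cols` cilia (N segments each) clamped upright on a fixed wall of
#' touching spheres, driven by the preferred curvature
#' `kappa0 = (1 + 5 sin(1.5 pi s - t + phi)) d1` with the phase advancing by
#' `2 pi` across the rows (`phi = (row - 1)/rows * 2 pi`), so a metachronal
#' wave travels in +y and the beat plane is y-z. Tracer spheres (radius
#' `tracer_radius`) seeded on a regular lattice at `tracer_heights` are
#' advected one-way by the flow. Measurements: per-tracer mean y-velocity and
#' velocity samples grouped by initial height.
#'
#' @param rows,cols Cilia grid (defaults 5 x 5).
#' @param N,n Cilium discretization (defaults 7, 1).
#' @param S Stiffness parameter (default 3; not printed in the source
#'   material).
#' @param spacing Cilia grid spacing (L).
#' @param wall_spacing Wall sphere diameter.
#' @param wall_margin Extra wall extent beyond the cilia grid (L).
#' @param tracer_heights Initial tracer heights (L).
#' @param tracer_grid Tracers per side per height (square lattice over the
#'   array footprint).
#' @param tracer_radius Tracer radius (default 0.01 L).
#' @param periods Drive periods.
#' @param nout_per_period Output density (also the tracer advection grid).
#' @return An `ehd_scenario`.
#' @export
scenario_cilia_array <- function(rows = 5, cols = 5, N = 7, n = 1, S = 3,
                                 spacing = 0.5, wall_spacing = 0.2,
                                 wall_margin = 0.4,
                                 tracer_heights = c(1.0, 1.4, 1.8),
                                 tracer_grid = 3, tracer_radius = 0.01,
                                 periods = 1, nout_per_period = 24) {
  params <- list(rows = rows, cols = cols, N = N, n = n, S = S,
                 spacing = spacing, wall_spacing = wall_spacing,
                 wall_margin = wall_margin, tracer_heights = tracer_heights,
                 tracer_grid = tracer_grid, tracer_radius = tracer_radius,
                 periods = periods, nout_per_period = nout_per_period)
  Eb <- 1 / S^4
  ext_x <- (cols - 1) * spacing + 2 * wall_margin
  ext_y <- (rows - 1) * spacing + 2 * wall_margin
  wall <- build_wall(max(1, ceiling(ext_x / wall_spacing)),
                     max(1, ceiling(ext_y / wall_spacing)), wall_spacing)
  drive <- function(phi) {
    force(phi)
    function(s, t) c(1 + 5 * sin(1.5 * pi * s - t + phi), 0, 0)
  }
  fils <- list()
  for (i in seq_len(rows)) {      # rows advance in y: metachronal wave
    phi <- (i - 1) / rows * 2 * pi
    for (j in seq_len(cols)) {
      off <- c((j - (cols + 1) / 2) * spacing, (i - (rows + 1) / 2) * spacing,
               wall_spacing / 2)
      # clamp rotated half a turn about z: the drive's positive mean curvature
      # then bends the cilia toward +y, so transport follows the metachronal
      # wave (+y), the published orientation of this beat
      fils <- c(fils, list(filament(N, n, Eb = Eb, drive_curvature = drive(phi),
                                    attach_offset = off,
                                    clamp = quat_from_axis_angle(c(0, 0, 1), pi))))
    }
  }
  sys <- ehd_system(ehd_structure(wall, fils, fixed = TRUE),
                    overlap_corrected = TRUE)
  X0 <- initial_state(sys)
  times <- seq(0, periods * .period, by = .period / nout_per_period)
  gl <- (seq_len(tracer_grid) - (tracer_grid + 1) / 2) / tracer_grid
  g <- expand.grid(x = gl * ext_x * 0.5, y = gl * ext_y * 0.5,
                   h = tracer_heights)
  tracers0 <- cbind(g$x, g$y, g$h)
  measure <- function(traj) {
    adv <- advect_tracers(traj, tracers0, tracer_radius)
    dt <- traj$times[length(traj$times)] - traj$times[1]
    mean_vy <- (adv$final[, 2] - tracers0[, 2]) / dt
    h <- tracers0[, 3]
    vy_mean_by_height <- tapply(mean_vy, h, mean)
    list(mean_vy = mean_vy, heights = h,
         vy_mean_by_height = vy_mean_by_height,
         vy_samples = adv$vy_samples, sample_heights = adv$sample_heights,
         trajectories = adv$paths)
  }
  .scenario("cilia", params, sys, X0, times, measure = measure)
}

#' Advect passive tracers through a stored trajectory
#'
#' One-way coupling: at every stored output state the sphere forces/torques
#' are recovered by re-solving the governing system, and the tracers are
#' advanced over each output interval with Heun's method using the RPY
#' velocity field of those forces.
#'
#' @param traj An `ehd_trajectory`.
#' @param tracers0 P x 3 initial tracer positions.
#' @param tracer_radius Tracer radius.
#' @return List: `final` (P x 3), `paths` (times x P x 3 array), `vy_samples`
#'   (per-interval y-velocities, P x intervals), `sample_heights`.
#' @export
advect_tracers <- function(traj, tracers0, tracer_radius = 0.01) {
  sys <- traj$sys
  nt <- length(traj$times)
  # forces/torques at each stored state
  snap <- lapply(seq_len(nt), function(kk) {
    X <- trajectory_state(traj, kk)
    sol <- ehd_rhs(sys, X, traj$times[kk], traj$constraints, extras = TRUE)
    list(Y = sphere_positions(sys, X), F = sol$forces, T = sol$torques)
  })
  P <- nrow(tracers0)
  p <- as.matrix(tracers0)
  paths <- array(NA_real_, c(nt, P, 3)); paths[1, , ] <- p
  vy <- matrix(NA_real_, P, nt - 1)
  vel <- function(kk, pts) tracer_velocities(snap[[kk]]$Y, sys$radii,
                                             snap[[kk]]$F, snap[[kk]]$T, pts,
                                             tracer_radius, eta = sys$eta,
                                             overlap_corrected = TRUE)
  for (kk in seq_len(nt - 1)) {
    dt <- traj$times[kk + 1] - traj$times[kk]
    v1 <- vel(kk, p)
    v2 <- vel(kk + 1, p + dt * v1)
    p <- p + dt * (v1 + v2) / 2
    paths[kk + 1, , ] <- p
    vy[, kk] <- (v1[, 2] + v2[, 2]) / 2
  }
  list(final = p, paths = paths, vy_samples = vy,
       sample_heights = tracers0[, 3])
}

# ---- config round-trip -----------------------------------------------------

.scenario_builders <- list(
  "relax" = scenario_relaxation,
  "helix" = scenario_helical,
  "swim" = scenario_swimmer,
  "chlamy" = scenario_chlamydomonas,
  "sperm-egg" = scenario_sperm_egg,
  "cilia" = scenario_cilia_array
)

#' Rebuild a scenario from its id and parameter list
#'
#' Inverse of the `scenario_*()` builders with respect to their `params`
#' field: `scenario_from_config(scn$id, scn$params)` reproduces the scenario.
#'
#' @param id Scenario id (one of `relax`, `helix`, `swim`, `chlamy`,
#'   `sperm-egg`, `cilia`).
#' @param params Named list of builder arguments (missing entries take the
#'   builder defaults; unknown names are an error).
#' @return An `ehd_scenario`.
#' @export
scenario_from_config <- function(id, params = list()) {
  builder <- .scenario_builders[[id]]
  if (is.null(builder)) stop("unknown scenario id: ", id, " (available: ",
                             paste(names(.scenario_builders), collapse = ", "), ")")
  known <- names(formals(builder))
  bad <- setdiff(names(params), known)
  if (length(bad)) stop("unknown parameter(s) for scenario '", id, "': ",
                        paste(bad, collapse = ", "))
  do.call(builder, params)
}
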