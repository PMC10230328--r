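# Governing ODE assembly and time integration:
#   M_F M_H^{-1} Q D_blk Xdot_gen = K   (exponential-map backend)
#   M_F M_H^{-1} Q W = K, Xdot_quat = C_blk W   (quaternion backend)
# with optional kinematic constraints replacing force/torque balance rows.

# shared per-evaluation assembly
.ehd_operators <- function(sys, X, t, quats = NULL) {
  geom <- system_geometry(sys, X, quats)
  groups <- if (sys$coupling == "reduced") sys$groups else NULL
  MH <- rpy_mobility(geom$Y, sys$radii, eta = sys$eta, groups = groups,
                     overlap_corrected = sys$overlap_corrected)
  list(geom = geom, MH = MH,
       Q = assemble_Q(sys, geom),
       MF = assemble_MF(sys, geom),
       K = assemble_K(sys, geom, t))
}

# multiply generator column blocks of Q by 2 D(r): QD = Q %*% D_blk
.apply_dblk <- function(sys, Q, X) {
  for (sl in sys$gen_slices)
    Q[, sl] <- Q[, sl] %*% (2 * dmatrix(X[sl]))
  Q
}

#' Kinematic constraint on a structure's base motion
#'
#' Replaces the structure's force-balance rows with a prescribed base
#' translation rate and/or its torque-balance rows with a prescribed rotation
#' rate. For the exponential-map backend the rotation rate is the generator
#' rate `rdot_b(t)`; the quaternion backend converts it to an angular velocity
#' through `omega = 2 D(r) rdot` at the current orientation.
#'
#' @param structure Index of the constrained structure in the system.
#' @param translation `NULL` or `function(t)` returning the prescribed
#'   `xdot_b` (3-vector).
#' @param rotation `NULL` or `function(t)` returning the prescribed `rdot_b`.
#' @return Object of class `ehd_constraint`.
#' @export
kinematic_constraint <- function(structure = 1, translation = NULL,
                                 rotation = NULL) {
  stopifnot(is.null(translation) || is.function(translation),
            is.null(rotation) || is.function(rotation))
  structure(list(structure = structure, translation = translation,
                 rotation = rotation), class = "ehd_constraint")
}

.check_constraints <- function(sys, constraints) {
  if (inherits(constraints, "ehd_constraint")) constraints <- list(constraints)
  seen <- character(0)
  for (cn in constraints) {
    stopifnot(inherits(cn, "ehd_constraint"))
    info <- sys$struct[[cn$structure]]
    if (info$fixed) stop("cannot constrain a fixed structure")
    for (type in c("translation", "rotation")) {
      if (!is.null(cn[[type]])) {
        key <- paste(cn$structure, type)
        if (key %in% seen) stop("duplicate ", type, " constraint on structure ",
                                cn$structure)
        seen <- c(seen, key)
      }
    }
  }
  constraints
}

# replace constrained rows of the reduced square system L W* = K, where the
# unknown is Xdot_gen (expmap) or W (quaternion); `rot_value` maps the
# prescribed generator rate to the unknown's units.
.apply_constraint_rows <- function(sys, L, K, constraints, t, rot_value) {
  for (cn in constraints) {
    info <- sys$struct[[cn$structure]]
    if (!is.null(cn$translation)) {
      rows <- info$state_x
      L[rows, ] <- 0
      L[cbind(rows, rows)] <- 1
      K[rows] <- cn$translation(t)
    }
    if (!is.null(cn$rotation)) {
      rows <- info$state_rb
      L[rows, ] <- 0
      L[cbind(rows, rows)] <- 1
      K[rows] <- rot_value(cn, t)
    }
  }
  list(L = L, K = K)
}

#' Exponential-map right-hand side
#'
#' One evaluation of the governing system: assembles the operators at state
#' `X` and time `t` and solves `M_F M_H^{-1} Q D_blk Xdot = K` (with
#' constraint rows applied) for `Xdot`.
#'
#' @param sys An [ehd_system()].
#' @param X Exponential-map state vector.
#' @param t Time.
#' @param constraints List of [kinematic_constraint()] objects.
#' @param extras If `TRUE`, also return the reduced velocities `W`, the sphere
#'   force/torque vector `FT` (solving `M_H FT = Q W`), sphere velocities, and
#'   the assembled operators.
#' @return `Xdot`, or a list when `extras = TRUE`.
#' @export
ehd_rhs <- function(sys, X, t = 0, constraints = list(), extras = FALSE) {
  constraints <- .check_constraints(sys, constraints)
  op <- .ehd_operators(sys, X, t)
  QD <- .apply_dblk(sys, op$Q, X)
  B <- apply_inverse_mobility(op$MH, QD)
  L <- op$MF %*% B
  lk <- .apply_constraint_rows(sys, L, op$K, constraints, t,
                               rot_value = function(cn, t) cn$rotation(t))
  Xdot <- tryCatch(solve(lk$L, lk$K), error = function(e) {
    stop("singular reduced system at t = ", format(t),
         " (generator near a coordinate singularity, or degenerate geometry): ",
         conditionMessage(e))
  })
  if (!extras) return(drop(Xdot))
  W <- .apply_dblk(sys, diag(sys$nstate), X) %*% Xdot # W = D_blk Xdot
  FT <- apply_inverse_mobility(op$MH, op$Q %*% W)
  M <- sys$M
  list(Xdot = drop(Xdot), W = drop(W), FT = drop(FT),
       V = drop(op$Q %*% W),
       forces = matrix(FT[1:(3 * M)], ncol = 3, byrow = TRUE),
       torques = matrix(FT[3 * M + 1:(3 * M)], ncol = 3, byrow = TRUE),
       op = op)
}

# ---- quaternion backend ----------------------------------------------------

#' Convert between exponential-map and quaternion state vectors
#'
#' @param sys An [ehd_system()].
#' @param X Exponential-map state.
#' @return Quaternion-backend state vector (positions plus unit quaternions).
#' @export
state_to_quat <- function(sys, X) {
  Xq <- numeric(sys$nqstate)
  for (info in sys$struct) {
    if (!info$fixed) {
      Xq[info$qstate_x] <- X[info$state_x]
      Xq[info$qstate_qb] <- exp_map(X[info$state_rb])
    }
    for (f in info$fil)
      for (i in seq_along(f$state_r))
        Xq[f$qstate_q[[i]]] <- exp_map(X[f$state_r[[i]]])
  }
  Xq
}

#' @rdname state_to_quat
#' @param Xq Quaternion-backend state.
#' @export
quat_to_state <- function(sys, Xq) {
  X <- numeric(sys$nstate)
  for (info in sys$struct) {
    if (!info$fixed) {
      X[info$state_x] <- Xq[info$qstate_x]
      X[info$state_rb] <- log_map(Xq[info$qstate_qb])
    }
    for (f in info$fil)
      for (i in seq_along(f$state_r))
        X[f$state_r[[i]]] <- log_map(Xq[f$qstate_q[[i]]])
  }
  X
}

# unpack a quaternion state into normalized quaternion lists plus a pseudo
# expmap state carrying the positions (generator slices unused)
.quat_unpack <- function(sys, Xq) {
  X <- numeric(sys$nstate)
  body <- vector("list", length(sys$struct))
  fil <- vector("list", length(sys$struct))
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    if (!info$fixed) {
      X[info$state_x] <- Xq[info$qstate_x]
      q <- Xq[info$qstate_qb]
      body[[s]] <- q / sqrt(sum(q^2))
    }
    fil[[s]] <- lapply(info$fil, function(f)
      lapply(f$qstate_q, function(sl) {
        q <- Xq[sl]; q / sqrt(sum(q^2))
      }))
  }
  list(X = X, quats = list(body = body, fil = fil))
}

#' Quaternion-backend right-hand side
#'
#' Solves `M_F M_H^{-1} Q W = K` for the reduced velocities, then propagates
#' the quaternion state through `qdot = C(q) omega`. Used to cross-validate
#' the exponential-map backend.
#'
#' @param sys An [ehd_system()].
#' @param Xq Quaternion state vector (positions + scalar-first quaternions).
#' @param t Time.
#' @param constraints List of [kinematic_constraint()] objects.
#' @return `Xqdot`.
#' @export
ehd_rhs_quat <- function(sys, Xq, t = 0, constraints = list()) {
  constraints <- .check_constraints(sys, constraints)
  up <- .quat_unpack(sys, Xq)
  op <- .ehd_operators(sys, up$X, t, quats = up$quats)
  B <- apply_inverse_mobility(op$MH, op$Q)
  A <- op$MF %*% B
  lk <- .apply_constraint_rows(sys, A, op$K, constraints, t,
    rot_value = function(cn, t) {
      info <- sys$struct[[cn$structure]]
      r <- log_map(up$quats$body[[cn$structure]])
      drop(2 * dmatrix(r) %*% cn$rotation(t))
    })
  W <- tryCatch(solve(lk$L, lk$K), error = function(e) {
    stop("singular reduced system at t = ", format(t), ": ",
         conditionMessage(e))
  })
  Xqdot <- numeric(sys$nqstate)
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    if (!info$fixed) {
      Xqdot[info$qstate_x] <- W[info$state_x]
      Xqdot[info$qstate_qb] <- cmatrix(up$quats$body[[s]]) %*% W[info$state_rb]
    }
    for (f in seq_along(info$fil)) {
      ff <- info$fil[[f]]
      for (i in seq_along(ff$state_r))
        Xqdot[ff$qstate_q[[i]]] <-
          cmatrix(up$quats$fil[[s]][[f]][[i]]) %*% W[ff$state_r[[i]]]
    }
  }
  Xqdot
}

# ---- integration -----------------------------------------------------------

#' Integrate the elastohydrodynamic system
#'
#' Evolves the state with the adaptive BDF integrator [ode_bdf()]. With the
#' exponential-map backend, generator rescaling (`r -> r - pi r/|r|` whenever
#' `|r| >= pi/2`) is applied between accepted steps and restarts the
#' multistep history, keeping every generator away from the `|r| = n pi`
#' coordinate singularities. The quaternion backend integrates positions and
#' unit quaternions directly (renormalized at output).
#'
#' @param sys An [ehd_system()].
#' @param X0 Initial exponential-map state (also for the quaternion backend,
#'   which converts internally).
#' @param times Output times.
#' @param backend `"expmap"` or `"quaternion"`.
#' @param constraints List of [kinematic_constraint()] objects.
#' @param rtol,atol Integration tolerances.
#' @param max_step,max_steps Step-size cap and step budget.
#' @return Object of class `ehd_trajectory`: `times`, `X` (rows = output
#'   states, native to the backend), `sys`, `backend`, `constraints`, `stats`.
#' @export
ehd_integrate <- function(sys, X0, times, backend = c("expmap", "quaternion"),
                          constraints = list(), rtol = 1e-6, atol = 1e-8,
                          max_step = Inf, max_steps = 100000L) {
  backend <- match.arg(backend)
  constraints <- .check_constraints(sys, constraints)
  if (backend == "expmap") {
    stopifnot(length(X0) == sys$nstate)
    f <- function(t, y) ehd_rhs(sys, y, t, constraints)
    event <- function(t, y) {
      changed <- FALSE
      for (sl in sys$gen_slices) {
        r2 <- rescale_generator(y[sl])
        if (!identical(r2, y[sl])) { y[sl] <- r2; changed <- TRUE }
      }
      if (changed) y else NULL
    }
    sol <- ode_bdf(f, X0, times, rtol = rtol, atol = atol,
                   max_step = max_step, max_steps = max_steps, event = event)
  } else {
    Xq0 <- state_to_quat(sys, X0)
    f <- function(t, y) ehd_rhs_quat(sys, y, t, constraints)
    sol <- ode_bdf(f, Xq0, times, rtol = rtol, atol = atol,
                   max_step = max_step, max_steps = max_steps)
  }
  structure(list(times = sol$times, X = sol$y, sys = sys, backend = backend,
                 constraints = constraints, stats = sol$stats),
            class = "ehd_trajectory")
}

#' @export
print.ehd_trajectory <- function(x, ...) {
  cat("ehd_trajectory:", length(x$times), "output times on [",
      x$times[1], ",", x$times[length(x$times)], "], backend", x$backend, "\n")
  cat("  steps:", x$stats["steps"], " rejected:", x$stats["rejected"],
      " fevals:", x$stats["fevals"], " jacobians:", x$stats["jacs"],
      " rescalings:", x$stats["events"], "\n")
  invisible(x)
}

#' Exponential-map state at an output index
#'
#' @param traj An `ehd_trajectory`.
#' @param k Output time index.
#' @return Exponential-map state vector (quaternion-backend states are
#'   converted).
#' @export
trajectory_state <- function(traj, k) {
  X <- traj$X[k, ]
  if (traj$backend == "quaternion") X <- quat_to_state(traj$sys, X)
  X
}

#' Sphere positions along a trajectory
#'
#' @param traj An `ehd_trajectory`.
#' @param k Output time index (default: all times).
#' @return M x 3 matrix for a single index, otherwise a
#'   `length(k) x (3M)` matrix of row-flattened (x1 y1 z1 x2 ...) positions.
#' @export
trajectory_positions <- function(traj, k = NULL) {
  if (!is.null(k) && length(k) == 1)
    return(sphere_positions(traj$sys, trajectory_state(traj, k)))
  if (is.null(k)) k <- seq_along(traj$times)
  t(vapply(k, function(i) {
    Y <- sphere_positions(traj$sys, trajectory_state(traj, i))
    as.numeric(t(Y))
  }, numeric(3 * traj$sys$M)))
}

#' Centre-of-mass positions along a trajectory
#'
#' Mean of all sphere centres (equal weights) at each output time.
#'
#' @param traj An `ehd_trajectory`.
#' @param structure Optional structure index to restrict to.
#' @return length(times) x 3 matrix.
#' @export
com_positions <- function(traj, structure = NULL) {
  ids <- if (is.null(structure)) seq_len(traj$sys$M) else {
    info <- traj$sys$struct[[structure]]
    c(info$body_sph, unlist(lapply(info$fil, `[[`, "sph")))
  }
  t(vapply(seq_along(traj$times), function(i) {
    colMeans(sphere_positions(traj$sys, trajectory_state(traj, i))[ids, , drop = FALSE])
  }, numeric(3)))
}

#' Momentum-balance residual at a state
#'
#' Solves the full system at `(X, t)`, recovers the sphere forces/torques
#' `FT = M_H^{-1} Q W`, and returns the maximum absolute residual of the
#' unconstrained balance rows `M_F FT - K`, relative to the larger of
#' `max |K|` and `max |M_F FT|`.
#'
#' @param sys An [ehd_system()].
#' @param X State vector.
#' @param t Time.
#' @param constraints List of [kinematic_constraint()] objects.
#' @return Scalar relative residual.
#' @export
balance_residual <- function(sys, X, t = 0, constraints = list()) {
  constraints <- .check_constraints(sys, constraints)
  sol <- ehd_rhs(sys, X, t, constraints, extras = TRUE)
  res <- drop(sol$op$MF %*% sol$FT) - sol$op$K
  keep <- rep(TRUE, sys$nstate)
  for (cn in constraints) {
    info <- sys$struct[[cn$structure]]
    if (!is.null(cn$translation)) keep[info$state_x] <- FALSE
    if (!is.null(cn$rotation)) keep[info$state_rb] <- FALSE
  }
  scale <- max(max(abs(sol$op$K)), max(abs(sol$op$MF %*% sol$FT)), 1e-300)
  max(abs(res[keep])) / scale
}

#' Discrete elastic energy
#'
#' `sum_j ds/2 (Eb (kappa1-kappa1_0)^2 + Eb (kappa2-kappa2_0)^2 +
#' Et (kappa3-kappa3_0)^2)` over all filament joints.
#'
#' @param sys An [ehd_system()].
#' @param X State vector.
#' @param t Time (for the preferred-curvature drive).
#' @return Scalar energy.
#' @export
elastic_energy <- function(sys, X, t = 0) {
  geom <- system_geometry(sys, X)
  E <- 0
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    for (f in seq_along(info$fil)) {
      fl <- info$spec$filaments[[f]]
      kap <- curvatures_from_directors(geom$struct[[s]]$fil[[f]]$dirs, fl$ds)
      for (j in 2:fl$N) {
        sj <- (j - 1) * fl$ds
        k0 <- if (is.null(fl$drive_curvature)) c(0, 0, 0)
              else fl$drive_curvature(sj, t)
        dk <- kap[j - 1, ] - k0
        E <- E + fl$ds / 2 * sum(c(fl$Eb, fl$Eb, fl$Et) * dk^2)
      }
    }
  }
  E
}

#' Maximum joint curvature magnitude
#'
#' @param sys An [ehd_system()].
#' @param X State vector.
#' @return Maximum over all joints of `|kappa|` (euclidean norm of the three
#'   curvatures).
#' @export
max_curvature <- function(sys, X) {
  geom <- system_geometry(sys, X)
  mx <- 0
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    for (f in seq_along(info$fil)) {
      fl <- info$spec$filaments[[f]]
      kap <- curvatures_from_directors(geom$struct[[s]]$fil[[f]]$dirs, fl$ds)
      mx <- max(mx, sqrt(max(rowSums(kap^2))))
    }
  }
  mx
}
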