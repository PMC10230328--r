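# Construction of filaments, sphere-built rigid bodies and multi-structure
# systems, and the computation of all sphere positions from the state vector.
#
# A structure is one rigid body (possibly empty, possibly fixed) plus any
# number of filaments clamped to it. All lengths are in units of the filament
# length L; coordinates are lab-frame Cartesian.

#' Kirchhoff filament description
#'
#' A filament of length `L` split into `N` rigid segments of `n` spheres each
#' (segment length `ds = L/N`). Sphere centres sit on the centreline at
#' `x_i + (j - 1/2) (ds/n) d3_i`, `j = 1..n`, with default radius `ds/(2n)`
#' so adjacent spheres touch when the filament is straight.
#'
#' @param N Number of rigid segments (`>= 2`).
#' @param n Spheres per segment (`>= 1`).
#' @param L Filament length (default 1: lengths are measured in units of L).
#' @param Eb,Et Bending and torsional stiffness (dimensionless; `Et = Eb` by
#'   default).
#' @param radius Sphere radius; default `L/(2*N*n)` (touching spheres).
#' @param drive_curvature Preferred-curvature drive: `NULL` or a
#'   `function(s, t)` returning the three preferred curvatures
#'   `(kappa1, kappa2, kappa3)` (components on the local directors, units 1/L)
#'   at arclength `s`.
#' @param active_moment Active internal moment density: `NULL`, a
#'   `function(s, t)` returning three components on the local directors (in
#'   units of `Eb/L^2`), or the closed-form family from
#'   [active_moment_wave()].
#' @param attach_offset Position of the filament base `x_1` relative to the
#'   body frame origin `x_b`, expressed in the body frame.
#' @param clamp Unit quaternion orienting the first segment's directors
#'   relative to the body frame (identity: segment 1 aligned with the body
#'   basis, tangent `d3` along the body `e3`).
#' @return An object of class `ehd_filament`.
#' @export
filament <- function(N, n = 1, L = 1, Eb = 1, Et = Eb, radius = NULL,
                     drive_curvature = NULL, active_moment = NULL,
                     attach_offset = c(0, 0, 0), clamp = c(1, 0, 0, 0)) {
  stopifnot(N >= 2, n >= 1, L > 0, Eb > 0, Et > 0, length(attach_offset) == 3,
            length(clamp) == 4)
  ds <- L / N
  if (is.null(radius)) radius <- ds / (2 * n)
  stopifnot(radius > 0)
  clamp <- clamp / sqrt(sum(clamp^2))
  structure(list(N = as.integer(N), n = as.integer(n), L = L, ds = ds,
                 Eb = Eb, Et = Et, radius = radius,
                 drive_curvature = drive_curvature,
                 active_moment = active_moment,
                 attach_offset = as.numeric(attach_offset),
                 clamp = as.numeric(clamp)),
            class = "ehd_filament")
}

#' Sinusoidal active moment density
#'
#' The travelling-wave active moment density family
#' `m_a(s, t) = amp * cos(k s - t)` acting along director `component`
#' (in units of `Eb/L^2`). Its tail integral used in the moment balance has
#' the closed form `(amp/k) (sin(k s2 - t) - sin(k s1 - t))` per segment.
#'
#' @param amp Amplitude (dimensionless, units `Eb/L^2`).
#' @param k Wavenumber (units 1/L).
#' @param component Which director the moment acts along (1, 2 or 3).
#' @return A function usable as `active_moment` in [filament()], carrying the
#'   closed-form metadata.
#' @export
active_moment_wave <- function(amp, k, component = 2) {
  f <- function(s, t) {
    out <- c(0, 0, 0)
    out[component] <- amp * cos(k * s - t)
    out
  }
  attr(f, "wave") <- list(amp = amp, k = k, component = component)
  class(f) <- c("ehd_moment_wave", "function")
  f
}

#' Rigid body built from spheres
#'
#' @param offsets M x 3 matrix of sphere centres in the body frame (relative
#'   to `x_b`). May have zero rows for a body-less structure.
#' @param radii Sphere radii (recycled to the number of spheres).
#' @return Object of class `ehd_body`.
#' @export
rigid_body <- function(offsets, radii) {
  offsets <- matrix(as.numeric(offsets), ncol = 3)
  radii <- rep_len(as.numeric(radii), nrow(offsets))
  stopifnot(all(radii > 0) || nrow(offsets) == 0)
  structure(list(offsets = offsets, radii = radii), class = "ehd_body")
}

#' Spherical shell body on a Fibonacci lattice
#'
#' Places `N_body` sphere centres on a sphere of radius `R` around the body
#' origin using the deterministic Fibonacci lattice (near-uniform packing).
#' The per-sphere radius defaults to half the minimum nearest-neighbour
#' distance, so neighbours approximately touch without overlapping.
#' `N_body = 1` degenerates to a single sphere of radius `R` at the centre.
#'
#' @param R Shell radius (units L).
#' @param N_body Number of spheres (`>= 1`).
#' @param sphere_radius Optional explicit per-sphere radius.
#' @return Object of class `ehd_body`.
#' @export
build_spherical_body <- function(R, N_body, sphere_radius = NULL) {
  stopifnot(N_body >= 1, R > 0)
  if (N_body == 1) return(rigid_body(matrix(0, 1, 3), R))
  i <- seq_len(N_body) - 0.5
  phi <- pi * (sqrt(5) - 1) # golden angle
  z <- 1 - 2 * i / N_body
  rho <- sqrt(pmax(0, 1 - z^2))
  offsets <- R * cbind(rho * cos(phi * i), rho * sin(phi * i), z)
  if (is.null(sphere_radius)) {
    dmin <- min(stats::dist(offsets))
    sphere_radius <- dmin / 2
  }
  rigid_body(offsets, sphere_radius)
}

#' Planar wall of touching spheres
#'
#' A rectangular monolayer of `nx` by `ny` touching spheres in the plane
#' `z = 0`, centred on the origin of the body frame. Use it as the body of a
#' fixed structure.
#'
#' @param nx,ny Grid dimensions (`>= 1`).
#' @param spacing Centre-to-centre spacing; the sphere radius is `spacing/2`.
#' @return Object of class `ehd_body`.
#' @export
build_wall <- function(nx, ny, spacing = 0.2) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0)
  gx <- (seq_len(nx) - (nx + 1) / 2) * spacing
  gy <- (seq_len(ny) - (ny + 1) / 2) * spacing
  g <- expand.grid(x = gx, y = gy)
  rigid_body(cbind(g$x, g$y, 0), spacing / 2)
}

#' Body-filament structure
#'
#' Combines a rigid body and clamped filaments into one structure. Clamping is
#' rigid: the first segment of every filament rotates with the body
#' (`omega_1 = omega_b`). A body-less structure (`body = NULL`) with a single
#' filament is a free filament: `x_b = x_1` and `r_b = r_1` (the body degrees
#' of freedom are the first segment's).
#'
#' @param body An [rigid_body()] or `NULL`.
#' @param filaments List of [filament()] objects (or a single filament).
#' @param fixed If `TRUE` the body is held fixed (a wall): it has no degrees
#'   of freedom, absorbs momentum, and its force/torque balance rows are
#'   dropped; clamped filament bases stay anchored.
#' @param x_b,q_b Initial (for `fixed`, permanent) body position and
#'   orientation quaternion.
#' @return Object of class `ehd_structure_spec`.
#' @export
ehd_structure <- function(body = NULL, filaments = list(), fixed = FALSE,
                          x_b = c(0, 0, 0), q_b = c(1, 0, 0, 0)) {
  if (inherits(filaments, "ehd_filament")) filaments <- list(filaments)
  stopifnot(all(vapply(filaments, inherits, TRUE, "ehd_filament")))
  if (is.null(body)) {
    if (length(filaments) != 1 && !fixed)
      stop("a body-less structure must contain exactly one filament")
    if (length(filaments) == 1 &&
        any(filaments[[1]]$attach_offset != 0))
      stop("a free filament must have zero attachment offset (x_b = x_1)")
    body <- rigid_body(matrix(0, 0, 3), numeric(0))
  }
  stopifnot(inherits(body, "ehd_body"), length(x_b) == 3, length(q_b) == 4)
  structure(list(body = body, filaments = filaments, fixed = isTRUE(fixed),
                 x_b0 = as.numeric(x_b), q_b0 = q_b / sqrt(sum(q_b^2))),
            class = "ehd_structure_spec")
}

#' Attach a filament to a structure
#'
#' Returns a copy of `struct` with `fil` clamped at `attach_offset` (body
#' frame) with orientation `clamp` relative to the body basis.
#'
#' @param struct An [ehd_structure()].
#' @param fil A [filament()].
#' @param attach_offset,clamp Override the filament's attachment fields.
#' @return Updated `ehd_structure_spec`.
#' @export
attach_filament <- function(struct, fil, attach_offset = NULL, clamp = NULL) {
  stopifnot(inherits(struct, "ehd_structure_spec"), inherits(fil, "ehd_filament"))
  if (!is.null(attach_offset)) fil$attach_offset <- as.numeric(attach_offset)
  if (!is.null(clamp)) fil$clamp <- clamp / sqrt(sum(clamp^2))
  struct$filaments <- c(struct$filaments, list(fil))
  struct
}

#' Assemble a multi-structure system
#'
#' Freezes a list of structures into a simulable system: assigns global sphere
#' indices, hydrodynamic component groups (body and each filament are separate
#' components, used by the reduced-coupling mask), and the state-vector layout
#' of the exponential-map backend. The state per non-fixed structure is
#' `[x_b (3), r_b (3), r_i (3) for i = 2..N of each filament]`; fixed
#' structures contribute only their filaments' segment generators.
#'
#' @param structures List of [ehd_structure()] objects (or a single one).
#' @param eta Fluid viscosity (dimensionless default 1).
#' @param overlap_corrected Use overlap-regularized RPY tensors.
#' @param coupling `"full"` for complete non-local coupling or `"reduced"` to
#'   zero RPY terms between different components (body, each filament).
#' @return Object of class `ehd_system`.
#' @export
ehd_system <- function(structures, eta = 1, overlap_corrected = FALSE,
                       coupling = c("full", "reduced")) {
  if (inherits(structures, "ehd_structure_spec")) structures <- list(structures)
  stopifnot(all(vapply(structures, inherits, TRUE, "ehd_structure_spec")))
  coupling <- match.arg(coupling)
  sph <- 0L; st <- 0L; qst <- 0L; comp <- 0L
  radii <- numeric(0); groups <- integer(0)
  gen_slices <- list()   # every generator block in the state (for D_blk / rescaling)
  struct <- vector("list", length(structures))
  for (s in seq_along(structures)) {
    sp <- structures[[s]]
    nb <- nrow(sp$body$offsets)
    comp <- comp + 1L
    info <- list(spec = sp, fixed = sp$fixed,
                 body_sph = if (nb > 0) sph + seq_len(nb) else integer(0))
    sph <- sph + nb
    radii <- c(radii, sp$body$radii)
    groups <- c(groups, rep(comp, nb))
    if (!sp$fixed) {
      info$state_x <- st + 1:3
      info$state_rb <- st + 4:6
      st <- st + 6L
      gen_slices <- c(gen_slices, list(info$state_rb))
      info$qstate_x <- qst + 1:3
      info$qstate_qb <- qst + 4:7
      qst <- qst + 7L
    }
    info$fil <- vector("list", length(sp$filaments))
    for (f in seq_along(sp$filaments)) {
      fl <- sp$filaments[[f]]
      comp <- comp + 1L
      ids <- sph + seq_len(fl$N * fl$n)
      sph <- sph + fl$N * fl$n
      radii <- c(radii, rep(fl$radius, fl$N * fl$n))
      groups <- c(groups, rep(comp, fl$N * fl$n))
      # generators for segments 2..N
      slices <- lapply(seq_len(fl$N - 1), function(i) st + (i - 1L) * 3L + 1:3)
      st <- st + 3L * (fl$N - 1L)
      qslices <- lapply(seq_len(fl$N - 1), function(i) qst + (i - 1L) * 4L + 1:4)
      qst <- qst + 4L * (fl$N - 1L)
      info$fil[[f]] <- list(sph = ids, state_r = slices, qstate_q = qslices)
      gen_slices <- c(gen_slices, slices)
    }
    struct[[s]] <- info
  }
  structure(list(struct = struct, M = sph, radii = radii, groups = groups,
                 nstate = st, nqstate = qst, gen_slices = gen_slices, eta = eta,
                 overlap_corrected = isTRUE(overlap_corrected),
                 coupling = coupling),
            class = "ehd_system")
}

#' @export
print.ehd_system <- function(x, ...) {
  cat("ehd_system:", length(x$struct), "structure(s),", x$M, "spheres,",
      "state dimension", x$nstate, "\n")
  invisible(x)
}

#' Default (straight-filament) state vector
#'
#' State with every structure at its constructed pose and every filament
#' straight along its clamp direction: `x_b = x_b0`, `r_b = log(q_b0)`, and
#' segment generators `r_i = log(q_b0 * clamp)`.
#'
#' @param sys An [ehd_system()].
#' @return Numeric state vector of length `sys$nstate`.
#' @export
initial_state <- function(sys) {
  X <- numeric(sys$nstate)
  for (info in sys$struct) {
    sp <- info$spec
    if (!info$fixed) {
      X[info$state_x] <- sp$x_b0
      X[info$state_rb] <- log_map(sp$q_b0)
    }
    for (f in seq_along(sp$filaments)) {
      q1 <- quat_multiply(sp$q_b0, sp$filaments[[f]]$clamp)
      for (sl in info$fil[[f]]$state_r) X[sl] <- log_map(q1)
    }
  }
  X
}

#' Segment endpoints from directors
#'
#' `x_i = x_1 + ds * sum_{j < i} d3_j`: exactly inextensible by construction
#' (consecutive endpoint distances are exactly `ds`).
#'
#' @param x1 Base position, 3-vector.
#' @param directors 3 x 3 x N array; `directors[, 3, i]` is the tangent `d3`
#'   of segment i.
#' @param ds Segment length.
#' @return N x 3 matrix of segment start points `x_1 .. x_N`.
#' @export
segment_endpoints <- function(x1, directors, ds) {
  N <- dim(directors)[3]
  d3 <- t(matrix(directors[, 3, ], nrow = 3))
  ends <- matrix(0, N, 3)
  ends[1, ] <- x1
  if (N > 1) ends[2:N, ] <- rep(x1, each = N - 1) + ds * apply(d3[-N, , drop = FALSE], 2, cumsum)
  ends
}

# Segment quaternions of every filament, the body pose, and all sphere
# positions, from an exponential-map state vector (or from quaternion data via
# the `quats` override used by the quaternion backend).
#
# Returns: list(Y = M x 3 sphere centres, struct = per-structure list with
# x_b, R_b and per-filament list(dirs = 3x3xN, ends = N x 3)).
system_geometry <- function(sys, X, quats = NULL) {
  Y <- matrix(0, sys$M, 3)
  out <- vector("list", length(sys$struct))
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    sp <- info$spec
    if (info$fixed) {
      x_b <- sp$x_b0
      q_b <- sp$q_b0
    } else if (is.null(quats)) {
      x_b <- X[info$state_x]
      q_b <- exp_map(X[info$state_rb])
    } else {
      x_b <- X[info$state_x]
      q_b <- quats$body[[s]]
    }
    R_b <- quat_to_matrix(q_b)
    if (length(info$body_sph))
      Y[info$body_sph, ] <- rep(x_b, each = length(info$body_sph)) +
        sp$body$offsets %*% t(R_b)
    fils <- vector("list", length(sp$filaments))
    for (f in seq_along(sp$filaments)) {
      fl <- sp$filaments[[f]]
      dirs <- array(0, c(3, 3, fl$N))
      q1 <- quat_multiply(q_b, fl$clamp)
      dirs[, , 1] <- quat_to_matrix(q1)
      if (fl$N > 1) for (i in 2:fl$N) {
        qi <- if (is.null(quats)) exp_map(X[info$fil[[f]]$state_r[[i - 1]]])
              else quats$fil[[s]][[f]][[i - 1]]
        dirs[, , i] <- quat_to_matrix(qi)
      }
      x1 <- x_b + drop(R_b %*% fl$attach_offset)
      ends <- segment_endpoints(x1, dirs, fl$ds)
      # sphere centres within each segment
      off <- (seq_len(fl$n) - 0.5) * (fl$ds / fl$n)
      ids <- info$fil[[f]]$sph
      for (i in seq_len(fl$N)) {
        seg_ids <- ids[(i - 1) * fl$n + seq_len(fl$n)]
        Y[seg_ids, ] <- rep(ends[i, ], each = fl$n) + outer(off, dirs[, 3, i])
      }
      fils[[f]] <- list(dirs = dirs, ends = ends)
    }
    out[[s]] <- list(x_b = x_b, R_b = R_b, q_b = q_b, fil = fils)
  }
  list(Y = Y, struct = out)
}

#' Sphere positions from a state vector
#'
#' Computes the centres of all M spheres in the system (body spheres at
#' `x_b + R(r_b) offset`, filament spheres on the inextensible segment chain).
#'
#' @param sys An [ehd_system()].
#' @param state Exponential-map state vector.
#' @return M x 3 matrix of sphere centres, with the per-sphere radii in
#'   attribute `radii` and hydrodynamic component ids in attribute `groups`.
#' @export
sphere_positions <- function(sys, state) {
  stopifnot(inherits(sys, "ehd_system"), length(state) == sys$nstate)
  g <- system_geometry(sys, state)
  structure(g$Y, radii = sys$radii, groups = sys$groups)
}

#' Sphere table for plotting/export
#'
#' @param sys An [ehd_system()].
#' @param state State vector.
#' @return `data.frame` with columns x, y, z, radius, structure, component.
#' @export
sphere_table <- function(sys, state) {
  Y <- sphere_positions(sys, state)
  sid <- integer(sys$M)
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    sid[info$body_sph] <- s
    for (f in info$fil) sid[f$sph] <- s
  }
  data.frame(x = Y[, 1], y = Y[, 2], z = Y[, 3], radius = sys$radii,
             structure = sid, component = sys$groups)
}
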