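# Dimensionality reduction: rigid-chain kinematics mapping the reduced
# velocities W = (xdot_b, omega_b, omega_i^seg ...) to all sphere linear and
# angular velocities, [V; Omega] = Q W.

#' Assemble the reduction matrix Q
#'
#' Rigid-body chain kinematics per structure: a body sphere k moves with
#' `v = xdot_b + omega_b x (y_k - x_b)`, `omega = omega_b`; a filament sphere
#' in segment i moves with
#' `v = xdot_b + omega_b x (x_1 - x_b) + sum_{j<i} omega_j x (x_{j+1} - x_j)
#' + omega_i x (y - x_i)`, `omega = omega_i`, with `omega_1 = omega_b`
#' (rigid clamp). Fixed structures have no body columns and their segment-1
#' spheres are immobile. Block-diagonal across structures.
#'
#' @param sys An [ehd_system()].
#' @param geom Geometry from `system_geometry()` (internal) or a state vector.
#' @return `6M x nred` matrix with `nred = sys$nstate` (columns mirror the
#'   state layout: `xdot_b`, `omega_b`, then segment angular velocities).
#' @export
assemble_Q <- function(sys, geom) {
  if (is.numeric(geom)) geom <- system_geometry(sys, geom)
  M <- sys$M
  Q <- matrix(0, 6 * M, sys$nstate)
  I3 <- diag(3)
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    gs <- geom$struct[[s]]
    fixed <- info$fixed
    if (!fixed) {
      cx <- info$state_x; cb <- info$state_rb
      for (k in info$body_sph) {
        vr <- 3 * (k - 1) + 1:3
        Q[vr, cx] <- I3
        Q[vr, cb] <- -cross_matrix(geom$Y[k, ] - gs$x_b)
        Q[3 * M + vr, cb] <- I3
      }
    }
    for (f in seq_along(info$fil)) {
      fl <- info$spec$filaments[[f]]
      ids <- info$fil[[f]]$sph
      ends <- gs$fil[[f]]$ends
      x1 <- ends[1, ]
      for (i in seq_len(fl$N)) {
        # angular-velocity column block of segment i (body block for i = 1)
        ci <- if (i == 1) (if (fixed) NULL else info$state_rb)
              else info$fil[[f]]$state_r[[i - 1]]
        for (jj in seq_len(fl$n)) {
          k <- ids[(i - 1) * fl$n + jj]
          vr <- 3 * (k - 1) + 1:3
          if (!fixed) {
            Q[vr, info$state_x] <- I3
            # omega_b arm: attachment lever plus segment-1 share of the chain
            arm <- if (i == 1) geom$Y[k, ] - gs$x_b else ends[2, ] - gs$x_b
            Q[vr, info$state_rb] <- -cross_matrix(arm)
          }
          if (i > 1) {
            for (j in 2:i) {
              cj <- info$fil[[f]]$state_r[[j - 1]]
              arm <- if (j < i) ends[j + 1, ] - ends[j, ] else geom$Y[k, ] - ends[i, ]
              Q[vr, cj] <- -cross_matrix(arm)
            }
          }
          if (!is.null(ci)) Q[3 * M + vr, ci] <- I3
        }
      }
    }
  }
  Q
}

#' Reduced dimension of a system
#'
#' Number of reduced velocity coordinates: `3 + 3N` for a free filament or a
#' body with one clamped filament of N segments; each additional clamped
#' filament adds `3(N - 1)`; a free body contributes 6; fixed structures
#' contribute only their filaments' `3(N - 1)`.
#'
#' @param sys An [ehd_system()].
#' @return Integer.
#' @export
reduced_dimension <- function(sys) {
  stopifnot(inherits(sys, "ehd_system"))
  sys$nstate
}
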