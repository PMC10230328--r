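# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (Rodrigues rotations, brute-force sums, dense
# solves, finite differences).

# Rodrigues rotation matrix (axis-angle), independent of the quaternion path
rodrigues <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# brute-force coded sums of the integrated momentum balance for a single
# body+filament structure (forces Fm, torques Tm as M x 3 matrices)
brute_MF_apply <- function(sys, X, Fm, Tm) {
  g <- elastocg:::system_geometry(sys, X)
  out <- numeric(sys$nstate)
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    ids_all <- c(info$body_sph, unlist(lapply(info$fil, `[[`, "sph")))
    if (!info$fixed) {
      out[info$state_x] <- colSums(Fm[ids_all, , drop = FALSE])
      tor <- c(0, 0, 0)
      for (k in ids_all)
        tor <- tor + vcross(g$Y[k, ] - g$struct[[s]]$x_b, Fm[k, ]) + Tm[k, ]
      out[info$state_rb] <- tor
    }
    for (f in seq_along(info$fil)) {
      fl <- info$spec$filaments[[f]]
      ids <- info$fil[[f]]$sph
      ends <- g$struct[[s]]$fil[[f]]$ends
      for (j in 2:fl$N) {
        mm <- c(0, 0, 0)
        for (k in ids[((j - 1) * fl$n + 1):(fl$N * fl$n)])
          mm <- mm + vcross(g$Y[k, ] - ends[j, ], Fm[k, ]) + Tm[k, ]
        out[info$fil[[f]]$state_r[[j - 1]]] <- mm
      }
    }
  }
  out
}

# a small random-ish (deterministic given seed) perturbed free-filament system
perturbed_filament_system <- function(N = 5, n = 2, seed = 42, body = FALSE) {
  set.seed(seed)
  fil <- filament(N, n, attach_offset = if (body) c(0, 0, 0.25) else c(0, 0, 0))
  st <- if (body) ehd_structure(build_spherical_body(0.25, 12), fil)
        else ehd_structure(NULL, fil)
  sys <- ehd_system(st, overlap_corrected = TRUE)
  X <- initial_state(sys)
  X[sys$struct[[1]]$state_x] <- rnorm(3) * 0.3
  X[sys$struct[[1]]$state_rb] <- rnorm(3) * 0.3
  for (sl in sys$struct[[1]]$fil[[1]]$state_r) X[sl] <- rnorm(3) * 0.4
  list(sys = sys, X = X)
}
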