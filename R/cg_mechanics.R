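# Coarse-grained momentum balance: the block matrix M_F acting on all sphere
# forces/torques, and the constitutive right-hand side K.
#
# Row blocks per structure: total force balance (3), total torque balance
# about x_b (3), and for every filament joint j = 2..N the integrated moment
# balance over all spheres of that filament from segment j to the tip,
# equal to -m_j minus the tail integral of the active moment density.
# Fixed structures keep only the moment rows (the wall absorbs momentum).

#' Discrete curvatures from segment directors
#'
#' Joint-centred finite differences of the director basis: at interior joint
#' j (between segments j-1 and j),
#' `kappa1 = (d2_j - d2_{j-1})/ds . dbar3`,
#' `kappa2 = (d3_j - d3_{j-1})/ds . dbar1`,
#' `kappa3 = (d1_j - d1_{j-1})/ds . dbar2`,
#' where `dbar` is the normalized average of the two adjacent directors. The
#' scheme is second-order and frame-covariant.
#'
#' @param directors 3 x 3 x N array of segment director bases (columns
#'   d1, d2, d3).
#' @param ds Segment length.
#' @return (N-1) x 3 matrix of `(kappa1, kappa2, kappa3)` at joints
#'   `j = 2..N`, with the (non-normalized per-component) joint-averaged
#'   director bases in attribute `dbar` (3 x 3 x (N-1)).
#' @export
curvatures_from_directors <- function(directors, ds) {
  N <- dim(directors)[3]
  stopifnot(N >= 2)
  kap <- matrix(0, N - 1, 3)
  dbar <- array(0, c(3, 3, N - 1))
  for (j in 2:N) {
    a <- directors[, , j - 1]; b <- directors[, , j]
    m <- a + b
    m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
    dd <- (b - a) / ds
    kap[j - 1, ] <- c(sum(dd[, 2] * m[, 3]),
                      sum(dd[, 3] * m[, 1]),
                      sum(dd[, 1] * m[, 2]))
    dbar[, , j - 1] <- m
  }
  structure(kap, dbar = dbar)
}

#' Constitutive bending moments at the joints
#'
#' `m_j = Eb (kappa1 - kappa1_0) d1 + Eb (kappa2 - kappa2_0) d2 +
#' Et (kappa3 - kappa3_0) d3` evaluated with the joint-averaged directors.
#' At the preferred shape (`kappa = kappa0`) all moments vanish.
#'
#' @param fil A [filament()].
#' @param directors 3 x 3 x N director array for the filament.
#' @param t Time (passed to the preferred-curvature drive).
#' @return (N-1) x 3 matrix of lab-frame moment vectors at joints j = 2..N.
#' @export
bending_moments <- function(fil, directors, t = 0) {
  kap <- curvatures_from_directors(directors, fil$ds)
  dbar <- attr(kap, "dbar")
  N <- fil$N
  m <- matrix(0, N - 1, 3)
  for (j in 2:N) {
    sj <- (j - 1) * fil$ds
    k0 <- if (is.null(fil$drive_curvature)) c(0, 0, 0)
          else fil$drive_curvature(sj, t)
    dk <- kap[j - 1, ] - k0
    m[j - 1, ] <- dbar[, , j - 1] %*% (c(fil$Eb, fil$Eb, fil$Et) * dk)
  }
  m
}

#' Tail integral of the active moment density
#'
#' Computes `integral_{s_j}^{L} m_a(s, t) ds` for every joint `j = 2..N`,
#' with the directors held constant within each rigid segment. For the
#' sinusoidal family built by [active_moment_wave()] the per-segment integral
#' is evaluated in closed form; for a general callable a 4-point
#' Gauss-Legendre rule per segment is used. The result is scaled by `Eb`
#' (the drive is specified in units of `Eb/L^2`).
#'
#' @param fil A [filament()].
#' @param directors 3 x 3 x N director array.
#' @param t Time.
#' @return (N-1) x 3 matrix of lab-frame tail integrals for joints j = 2..N.
#' @export
active_moment_integral <- function(fil, directors, t = 0) {
  N <- fil$N; ds <- fil$ds
  out <- matrix(0, N - 1, 3)
  if (is.null(fil$active_moment)) return(out)
  wave <- attr(fil$active_moment, "wave")
  # per-segment integrals of the local coefficients
  seg <- matrix(0, N, 3)
  for (i in seq_len(N)) {
    s1 <- (i - 1) * ds; s2 <- i * ds
    if (!is.null(wave)) {
      val <- (wave$amp / wave$k) * (sin(wave$k * s2 - t) - sin(wave$k * s1 - t))
      coefs <- c(0, 0, 0); coefs[wave$component] <- val
    } else {
      gx <- c(-0.8611363115940526, -0.3399810435848563,
               0.3399810435848563,  0.8611363115940526)
      gw <- c(0.3478548451374538, 0.6521451548625461,
              0.6521451548625461, 0.3478548451374538)
      coefs <- c(0, 0, 0)
      for (q in seq_along(gx)) {
        sq <- (s1 + s2) / 2 + gx[q] * ds / 2
        coefs <- coefs + gw[q] * (ds / 2) * fil$active_moment(sq, t)
      }
    }
    seg[i, ] <- drop(directors[, , i] %*% coefs)
  }
  # tail sums: joint j at s = (j-1) ds is the start of segment j
  tail <- apply(seg[N:1, , drop = FALSE], 2, cumsum)[N:1, , drop = FALSE]
  fil$Eb * tail[2:N, , drop = FALSE]
}

#' Assemble the coarse-grained momentum-balance matrix
#'
#' Builds the block matrix `M_F` with `[F; T]` stacked as all forces (3M) then
#' all torques (3M): per non-fixed structure a force-balance row block
#' (identities over the structure's force columns), a torque-balance row block
#' (`[y_k - x_b]x` over forces, identities over torques), and per filament
#' joint `j = 2..N` the partial sums `[y_k - x_j]x F_k + T_k` over that
#' filament's spheres in segments `j..N`. Fixed structures contribute only
#' moment rows. Multi-structure systems are block-diagonal.
#'
#' @param sys An [ehd_system()].
#' @param geom Geometry from `system_geometry()` (internal) or a state vector.
#' @return `nrows x 6M` matrix, `nrows = sys$nstate` (rows mirror the reduced
#'   coordinates).
#' @export
assemble_MF <- function(sys, geom) {
  if (is.numeric(geom)) geom <- system_geometry(sys, geom)
  M <- sys$M
  MF <- matrix(0, sys$nstate, 6 * M)
  I3 <- diag(3)
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    gs <- geom$struct[[s]]
    sph_all <- c(info$body_sph, unlist(lapply(info$fil, `[[`, "sph")))
    if (!info$fixed) {
      rF <- info$state_x   # force-balance rows
      rT <- info$state_rb  # torque-balance rows
      for (k in sph_all) {
        MF[rF, 3 * (k - 1) + 1:3] <- I3
        MF[rT, 3 * (k - 1) + 1:3] <- cross_matrix(geom$Y[k, ] - gs$x_b)
        MF[rT, 3 * M + 3 * (k - 1) + 1:3] <- I3
      }
    }
    for (f in seq_along(info$fil)) {
      fl <- info$spec$filaments[[f]]
      ids <- info$fil[[f]]$sph
      ends <- gs$fil[[f]]$ends
      for (j in 2:fl$N) {
        rows <- info$fil[[f]]$state_r[[j - 1]]
        tail_ids <- ids[((j - 1) * fl$n + 1):(fl$N * fl$n)]
        for (k in tail_ids) {
          MF[rows, 3 * (k - 1) + 1:3] <- cross_matrix(geom$Y[k, ] - ends[j, ])
          MF[rows, 3 * M + 3 * (k - 1) + 1:3] <- I3
        }
      }
    }
  }
  MF
}

#' Assemble the constitutive right-hand side
#'
#' Zeros on force/torque-balance rows; `-m_j - integral_{s_j}^L m_a ds` on
#' the moment rows (lab frame).
#'
#' @param sys An [ehd_system()].
#' @param geom Geometry from `system_geometry()` or a state vector.
#' @param t Time.
#' @return Numeric vector of length `sys$nstate`.
#' @export
assemble_K <- function(sys, geom, t = 0) {
  if (is.numeric(geom)) geom <- system_geometry(sys, geom)
  K <- numeric(sys$nstate)
  for (s in seq_along(sys$struct)) {
    info <- sys$struct[[s]]
    for (f in seq_along(info$fil)) {
      fl <- info$spec$filaments[[f]]
      dirs <- geom$struct[[s]]$fil[[f]]$dirs
      m <- bending_moments(fl, dirs, t)
      ma <- active_moment_integral(fl, dirs, t)
      for (j in 2:fl$N)
        K[info$fil[[f]]$state_r[[j - 1]]] <- -m[j - 1, ] - ma[j - 1, ]
    }
  }
  K
}
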