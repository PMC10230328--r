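# Rotne-Prager-Yamakawa grand mobility and its inverse action.

#' RPY grand mobility matrix
#'
#' Builds the dense 6M x 6M Rotne-Prager-Yamakawa mobility matrix `M_H`
#' mapping forces and torques on M spheres to their linear and angular
#' velocities, `[V; Omega] = M_H [F; T]` (velocities stacked first). Supports
#' unequal radii. With `overlap_corrected = TRUE` the overlap-regularized
#' variant is used, which coincides with the standard tensors for
#' non-overlapping pairs and remains positive-definite as the separation of a
#' pair goes to zero; with `FALSE`, overlapping spheres are an error naming
#' the offending pair.
#'
#' @param positions M x 3 matrix of sphere centres.
#' @param radii Length-M vector of sphere radii (all positive).
#' @param eta Fluid viscosity (default 1: dimensionless units).
#' @param groups Optional length-M integer vector of hydrodynamic groups;
#'   when given, pair terms between spheres in different groups are set to
#'   zero (the "reduced coupling" mask). Self terms are always kept.
#' @param overlap_corrected Use the overlap-regularized tensors.
#' @return Object of class `rpy_mobility`: the matrix with attributes
#'   `eta`, `radii`, `overlap_corrected`.
#' @export
rpy_mobility <- function(positions, radii, eta = 1, groups = NULL,
                         overlap_corrected = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(radii) == nrow(positions),
            all(radii > 0), eta > 0)
  mask <- !is.null(groups)
  if (!mask) groups <- integer(nrow(positions))
  stopifnot(length(groups) == nrow(positions))
  MH <- .rpy_mobility_cpp(positions, as.numeric(radii), eta,
                          isTRUE(overlap_corrected), as.integer(groups), mask)
  structure(MH, class = c("rpy_mobility", "matrix"),
            eta = eta, radii = as.numeric(radii),
            overlap_corrected = isTRUE(overlap_corrected))
}

#' Solve against the mobility matrix
#'
#' Computes `M_H^{-1} %*% rhs` through a Cholesky factorization (no explicit
#' inverse). Failure of the factorization signals a non-positive-definite
#' mobility, which for the standard tensors means overlapping spheres.
#'
#' @param MH Mobility matrix from [rpy_mobility()] (any symmetric
#'   positive-definite matrix works).
#' @param rhs Vector or matrix with `nrow(MH)` rows.
#' @return Solution of `MH x = rhs`, same shape as `rhs`.
#' @export
apply_inverse_mobility <- function(MH, rhs) {
  R <- tryCatch(chol(MH), error = function(e) {
    stop("mobility matrix is not positive-definite (overlapping spheres ",
         "without overlap correction?): ", conditionMessage(e))
  })
  backsolve(R, forwardsolve(R, rhs, upper.tri = TRUE, transpose = TRUE))
}

#' Velocities of passive tracer spheres
#'
#' One-way RPY coupling: a force- and torque-free tracer sphere is advected by
#' the flow of the forced system spheres without altering their dynamics. The
#' tracer velocity is the sum over system spheres of the translation-translation
#' coupling acting on their forces plus the translation-rotation coupling
#' acting on their torques.
#'
#' @param positions M x 3 system sphere centres.
#' @param radii Length-M system sphere radii.
#' @param forces,torques M x 3 matrices of forces and torques on the system
#'   spheres.
#' @param tracer_positions P x 3 tracer centres.
#' @param tracer_radius Tracer radius (single value).
#' @param eta Viscosity.
#' @param overlap_corrected Use overlap-regularized pair tensors.
#' @return P x 3 matrix of tracer velocities.
#' @export
tracer_velocities <- function(positions, radii, forces, torques,
                              tracer_positions, tracer_radius = 0.01,
                              eta = 1, overlap_corrected = TRUE) {
  positions <- as.matrix(positions); tracer_positions <- as.matrix(tracer_positions)
  forces <- as.matrix(forces); torques <- as.matrix(torques)
  stopifnot(ncol(positions) == 3, ncol(tracer_positions) == 3,
            nrow(forces) == nrow(positions), nrow(torques) == nrow(positions))
  .tracer_velocities_cpp(positions, as.numeric(radii), forces, torques,
                         tracer_positions, tracer_radius, eta,
                         isTRUE(overlap_corrected))
}
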