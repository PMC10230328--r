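# Adaptive implicit BDF integrator (orders 1-3) for small stiff systems.
#
# Variable-step, variable-order BDF with modified-Newton iterations,
# finite-difference Jacobians reused across steps, and a weighted-RMS
# solution-difference error controller.
# Written for the coarse-grained elastohydrodynamic ODEs (dense, stiff,
# dimension up to a few hundred); not a general replacement for production
# solvers, but validated by convergence and cross-backend tests.

.wrms <- function(v, y, rtol, atol) sqrt(mean((v / (atol + rtol * abs(y)))^2))

.fd_jacobian <- function(f, t, y, f0) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    dk <- 1e-7 * max(abs(y[k]), 1e-3)
    yp <- y; yp[k] <- yp[k] + dk
    J[, k] <- (f(t, yp) - f0) / dk
  }
  J
}

#' Stiff ODE integration (adaptive BDF)
#'
#' Integrates `dy/dt = f(t, y)` with an adaptive variable-step,
#' variable-order BDF (orders 1-3), Newton iterations on each implicit step,
#' and finite-difference Jacobians that are reused until Newton convergence
#' degrades. Dense output at `times` by cubic Hermite interpolation. An
#' optional `event` callback runs after every accepted step and may modify
#' the state (used for generator rescaling); a modification restarts the
#' multistep history at order 1.
#'
#' @param f `function(t, y)` returning `dy/dt`.
#' @param y0 Initial state.
#' @param times Output times (increasing; `times[1]` is the initial time).
#' @param rtol,atol Relative/absolute local error tolerances.
#' @param h0 Initial step (default: conservative guess).
#' @param max_step Maximum step size.
#' @param max_steps Step budget before aborting with an error.
#' @param max_order Highest BDF order used (1-3; default 3).
#' @param event Optional `function(t, y)` returning `NULL` (no change) or the
#'   modified state vector.
#' @return List: `times`, `y` (length(times) x n matrix), `stats` (named
#'   vector: steps, rejected, fevals, jacs, events).
#' @export
ode_bdf <- function(f, y0, times, rtol = 1e-6, atol = 1e-8, h0 = NULL,
                    max_step = Inf, max_steps = 100000L, event = NULL,
                    max_order = 3L) {
  stopifnot(max_order %in% 1:3)
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  t0 <- times[1]; tend <- times[length(times)]
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0
  iout <- 2L

  t <- t0; y <- y0
  fcur <- f(t, y)
  nfe <- 1L; njac <- 0L; nacc <- 0L; nrej <- 0L; nev <- 0L
  if (is.null(h0)) {
    scale <- .wrms(fcur, y, rtol, atol)
    h0 <- if (is.finite(scale) && scale > 0) 0.01 / scale else (tend - t0) / 1000
  }
  # floor the initial guess: the controller grows h geometrically anyway
  h <- min(max(h0, 1e-9 * (tend - t0)), max_step, (tend - t0) / 10)

  # history for the multistep formulas + error estimation (newest first)
  ht <- c(t); hy <- list(y)

  # derivative of the Lagrange interpolant through nodes xs, evaluated at
  # xs[1]: coefficients cj with dp/dx at xs[1] = sum_j cj * y(xs[j])
  lagrange_deriv <- function(xs) {
    m <- length(xs)
    cj <- numeric(m)
    cj[1] <- sum(1 / (xs[1] - xs[-1]))
    for (j in 2:m) {
      others <- xs[-c(1, j)]
      cj[j] <- prod(xs[1] - others) / prod(xs[j] - xs[-j])
    }
    cj
  }
  # value of the Lagrange interpolant through (xs, ys) at x
  lagrange_eval <- function(xs, ys, x) {
    out <- 0
    for (j in seq_along(xs))
      out <- out + ys[[j]] * prod((x - xs[-j]) / (xs[j] - xs[-j]))
    out
  }

  J <- NULL; Jfresh <- FALSE
  ord_cap <- 3L # temporarily lowered after rejections (BDF3 step-ratio stability)
  # Newton must resolve the implicit equations well below the local-error
  # tolerance: leftovers act as noise on the stored nodes and, amplified by
  # stiff eigenvalues, would poison the solution-difference error estimates.
  newton_tol <- 0.01

  # one implicit-Euler solve (used for order-1 steps and their step-doubling
  # error estimate); returns NULL on Newton failure
  be_solve <- function(t1, h1, ystart, ypred, W) {
    z <- ypred
    dprev <- NULL
    for (it in 1:7) {
      fz <- tryCatch(f(t1, z), error = function(e) NULL)
      nfe <<- nfe + 1L
      if (is.null(fz) || !all(is.finite(fz))) return(NULL)
      G <- z - h1 * fz - ystart
      delta <- tryCatch(solve(W, -G), error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) return(NULL)
      z <- z + delta
      dn <- .wrms(delta, z, rtol, atol)
      rate <- if (!is.null(dprev) && dprev > 0) dn / dprev else 1
      if (dn < newton_tol || (rate < 0.5 && dn * rate / (1 - rate) < newton_tol))
        return(z)
      dprev <- dn
    }
    NULL
  }

  while (t < tend - 1e-14 * max(1, abs(tend))) {
    if (nacc + nrej > max_steps)
      stop("ode_bdf: step budget exceeded at t = ", format(t),
           " (h = ", format(h), "); the system may be too stiff for the ",
           "requested tolerances")
    if (h < 1e-13 * abs(tend - t0))
      stop("ode_bdf: step size collapsed at t = ", format(t),
           " (h = ", format(h), "); the right-hand side may be singular or ",
           "discontinuous there")
    h <- min(h, max_step, tend - t)
    ord <- min(max_order, length(ht), ord_cap)
    tn <- t + h

    if (ord == 1L) {
      heff <- h; ystart <- y
      ypred <- y + h * fcur
    } else {
      # BDF-ord from the derivative of the interpolant through the new node
      # and the last ord history nodes: c1 z + sum_j c_{j+1} y_{n+1-j} = f
      cj <- lagrange_deriv(c(tn, ht[1:ord]))
      heff <- 1 / cj[1]
      acc <- 0
      for (j in 1:ord) acc <- acc + cj[j + 1] * hy[[j]]
      ystart <- -heff * acc
      ypred <- lagrange_eval(ht[1:ord], hy[1:ord], tn) # extrapolation predictor
    }

    if (is.null(J)) {
      J <- .fd_jacobian(f, t, y, fcur)
      nfe <- nfe + n; njac <- njac + 1L; Jfresh <- TRUE
    }
    W <- diag(n) - heff * J

    # implicit solve for the step (Newton; a diverging iterate can push the
    # state into unphysical territory where the RHS itself fails -- treated
    # as a convergence failure, not a fatal error)
    z <- be_solve(tn, heff, ystart, ypred, W)
    if (is.null(z)) {
      if (!Jfresh) { J <- NULL; next }      # retry with a fresh Jacobian
      h <- h * 0.3; nrej <- nrej + 1L; next # fresh Jacobian already: cut step
    }

    # local error estimate
    if (ord == 1L) {
      # step doubling: both solutions damp stiff transients, so the estimate
      # stays clean even when the state carries fast-mode noise
      Wh <- diag(n) - (h / 2) * J
      zh <- be_solve(t + h / 2, h / 2, y, (y + z) / 2, Wh)
      zh2 <- if (is.null(zh)) NULL else be_solve(tn, h / 2, zh, z, Wh)
      if (is.null(zh2)) {
        if (!Jfresh) { J <- NULL; next }
        h <- h * 0.3; nrej <- nrej + 1L; next
      }
      err <- 2 * .wrms(zh2 - z, z, rtol, atol)
      fnew_half <- (zh2 - zh) / (h / 2) # implicit slope of the composite
      z <- zh2 # keep the more accurate composite
    } else if (length(ht) >= ord + 1) {
      # degree-ord extrapolation through the last ord+1 nodes measures the
      # (ord+1)-th solution difference, a proxy for the local error
      yext <- lagrange_eval(ht[1:(ord + 1)], hy[1:(ord + 1)], tn)
      err <- .wrms(z - yext, z, rtol, atol) / (ord + 1)
    } else {
      err <- .wrms(z - ypred, z, rtol, atol) / 2
    }

    if (err > 1) {
      nrej <- nrej + 1L
      h <- h * max(0.1, min(0.5, 0.85 * err^(-1 / (ord + 1))))
      ord_cap <- 2L # retry at lower order: variable-step BDF3 tolerates only
                    # mild step-ratio variation
      next
    }

    # accept
    nacc <- nacc + 1L
    fnew <- if (ord == 1L) fnew_half
            else (z - ystart) / heff # implicit slope at the new node
    # dense output on (t, tn]
    while (iout <= length(times) && times[iout] <= tn + 1e-12 * max(1, abs(tn))) {
      s <- (times[iout] - t) / h
      hh00 <- (1 + 2 * s) * (1 - s)^2; hh10 <- s * (1 - s)^2
      hh01 <- s^2 * (3 - 2 * s);       hh11 <- s^2 * (s - 1)
      out[iout, ] <- hh00 * y + hh10 * h * fcur + hh01 * z + hh11 * h * fnew
      iout <- iout + 1L
    }

    t <- tn; y <- z; fcur <- fnew
    keep <- min(max_order + 1L, length(ht) + 1L)
    ht <- c(t, ht)[1:keep]
    hy <- c(list(y), hy)[1:keep]
    Jfresh <- FALSE

    if (!is.null(event)) {
      ymod <- event(t, y)
      if (!is.null(ymod)) {
        nev <- nev + 1L
        y <- ymod
        fcur <- f(t, y); nfe <- nfe + 1L
        ht <- c(t); hy <- list(y)  # restart the multistep history
        J <- NULL
      }
    }
    ord_cap <- 3L
    growth_cap <- if (ord >= 3) 1.3 else 3 # variable-step BDF3 stability
    h <- h * max(0.2, min(growth_cap, 0.85 * err^(-1 / (ord + 1))))
  }
  if (iout <= length(times)) out[iout:length(times), ] <- rep(y, each = length(times) - iout + 1)
  list(times = times, y = out,
       stats = c(steps = nacc, rejected = nrej, fevals = nfe, jacs = njac,
                 events = nev))
}
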