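test_that("quat_from_axis_angle matches its closed form", {
  expect_equal(quat_from_axis_angle(c(0, 1, 0), 0), c(1, 0, 0, 0))
  expect_equal(quat_from_axis_angle(c(0, 1, 0), pi), c(0, 0, 1, 0))
  expect_equal(quat_from_axis_angle(c(0, 0, 1), pi / 2),
               c(sqrt(2) / 2, 0, 0, sqrt(2) / 2))
  expect_warning(q <- quat_from_axis_angle(c(0, 2, 0), 1), "normalizing")
  expect_equal(q, quat_from_axis_angle(c(0, 1, 0), 1))
  expect_error(quat_from_axis_angle(c(0, 2, 0), 1, strict = TRUE), "unit norm")
})

test_that("quat_rotate agrees with the Rodrigues rotation-matrix oracle", {
  expect_equal(quat_rotate(c(1, 0, 0, 0), c(0.3, -1, 2)), c(0.3, -1, 2))
  expect_equal(quat_rotate(quat_from_axis_angle(c(0, 0, 1), pi), c(1, 0, 0)),
               c(-1, 0, 0))
  set.seed(7)
  for (i in 1:50) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, -2 * pi, 2 * pi)
    v <- rnorm(3)
    expect_equal(quat_rotate(quat_from_axis_angle(ax, th), v),
                 drop(rodrigues(ax, th) %*% v), tolerance = 1e-12)
  }
})

test_that("quaternion composition acts as sequential rotation", {
  set.seed(8)
  for (i in 1:100) {
    q1 <- exp_map(rnorm(3)); q2 <- exp_map(rnorm(3)); v <- rnorm(3)
    expect_equal(quat_rotate(quat_multiply(q1, q2), v),
                 quat_rotate(q1, quat_rotate(q2, v)), tolerance = 1e-12)
    # norm preservation
    expect_equal(sum(quat_rotate(q1, v)^2), sum(v^2), tolerance = 1e-12)
  }
})

test_that("exp_map produces unit quaternions and matches axis-angle", {
  expect_equal(exp_map(c(0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(exp_map(c(0, pi / 2, 0)), c(0, 0, 1, 0), tolerance = 1e-15)
  set.seed(9)
  for (i in 1:100) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, 2 * pi)
    # generator r = (theta/2) axis encodes rotation by theta about axis
    expect_equal(exp_map(th / 2 * ax), quat_from_axis_angle(ax, th),
                 tolerance = 1e-12)
  }
  # unit norm far out and through the small-|r| series branch
  for (r in list(c(10, 0, 0), runif(3) * 5, c(1e-6, -2e-6, 5e-7), c(1e-12, 0, 0)))
    expect_equal(sum(exp_map(r)^2), 1, tolerance = 1e-12)
})

test_that("log_map inverts exp_map on the principal branch", {
  set.seed(10)
  for (i in 1:50) {
    r <- rnorm(3); r <- r / sqrt(sum(r^2)) * runif(1, 0, pi / 2 - 1e-3)
    expect_equal(log_map(exp_map(r)), r, tolerance = 1e-10)
  }
  expect_equal(log_map(c(1, 0, 0, 0)), c(0, 0, 0))
  expect_equal(log_map(-exp_map(c(0.2, 0.1, -0.3))), c(0.2, 0.1, -0.3),
               tolerance = 1e-12)
})

test_that("dmatrix: identity at zero, det = sinc^2|r|, singularity guard", {
  expect_equal(dmatrix(c(0, 0, 0)), diag(3))
  expect_equal(det(dmatrix(c(1, 0, 0))), (sin(1) / 1)^2, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:1000) {
    r <- rnorm(3); r <- r / sqrt(sum(r^2)) * runif(1, 0, pi - 1e-3)
    expect_equal(det(dmatrix(r)), (sin(sqrt(sum(r^2))) / sqrt(sum(r^2)))^2,
                 tolerance = 1e-10)
  }
  expect_error(dmatrix(c(pi, 0, 0)), "singularity")
})

test_that("omega = 2 D rdot matches the finite-difference of exp_map", {
  # central difference of q(t) = exp_map(r + t rdot); omega from qdot = C omega
  set.seed(12)
  for (i in 1:30) {
    r <- rnorm(3) * 0.8; rdot <- rnorm(3)
    h <- 1e-6
    qp <- exp_map(r + h * rdot); qm <- exp_map(r - h * rdot)
    qdot <- (qp - qm) / (2 * h)
    q <- exp_map(r)
    # invert qdot = 1/2 (0, omega) * q  =>  (0, omega) = 2 qdot * q^-1
    w <- 2 * quat_multiply(qdot, quat_conjugate(q))
    expect_equal(w[1], 0, tolerance = 1e-6)
    expect_equal(drop(2 * dmatrix(r) %*% rdot), w[2:4], tolerance = 1e-6)
  }
})

test_that("small-|r| series branch of dmatrix is continuous", {
  r <- c(1.0001e-4, -0.3e-4, 0.2e-4)
  rs <- r * (0.9998 / 1.0001) # just below the switch
  expect_equal(dmatrix(r), dmatrix(rs), tolerance = 1e-7)
})

test_that("cmatrix: identity case, norm conservation, constant-omega rotation", {
  expect_equal(cmatrix(c(1, 0, 0, 0)),
               0.5 * rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  set.seed(13)
  for (i in 1:100) {
    q <- exp_map(rnorm(3)); w <- rnorm(3)
    expect_equal(sum(q * (cmatrix(q) %*% w)), 0, tolerance = 1e-14)
  }
  # integrate qdot = C(q) omega for constant omega: closed-form rotation
  w <- c(0.3, -0.5, 0.8); tend <- 1.3
  sol <- ode_bdf(function(t, q) drop(cmatrix(q) %*% w),
                 c(1, 0, 0, 0), c(0, tend), rtol = 1e-10, atol = 1e-12)
  qT <- sol$y[2, ]
  expect_equal(qT, quat_from_axis_angle(w / sqrt(sum(w^2)),
                                        sqrt(sum(w^2)) * tend),
               tolerance = 1e-7)
})

test_that("rescale_generator preserves the rotation", {
  expect_equal(rescale_generator(c(0.1, 0, 0)), c(0.1, 0, 0))
  expect_equal(rescale_generator(c(0, 2, 0)), c(0, 2 - pi, 0))
  set.seed(14)
  for (i in 1:100) {
    r <- rnorm(3); r <- r / sqrt(sum(r^2)) * runif(1, pi / 2, 3)
    r2 <- rescale_generator(r)
    expect_lt(sqrt(sum(r2^2)), pi / 2 + 1e-12)
    v <- rnorm(3)
    expect_equal(quat_rotate(exp_map(r), v), quat_rotate(exp_map(r2), v),
                 tolerance = 1e-10)
  }
})

test_that("directors_from_generator gives right-handed orthonormal bases", {
  expect_equal(directors_from_generator(c(0, 0, 0)), diag(3))
  # rotation by pi/2 about z maps e1 to e2
  expect_equal(directors_from_generator(c(0, 0, pi / 4))[, 1], c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(15)
  for (i in 1:200) {
    D <- directors_from_generator(rnorm(3) * 2)
    expect_equal(crossprod(D), diag(3), tolerance = 1e-9)
    expect_equal(vcross(D[, 1], D[, 2]), D[, 3], tolerance = 1e-9)
  }
})

test_that("cross_matrix implements the cross product", {
  expect_equal(cross_matrix(c(1, 0, 0)),
               rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  set.seed(16)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(drop(cross_matrix(a) %*% b), vcross(a, b))
    expect_equal(drop(cross_matrix(a) %*% a), c(0, 0, 0))
    expect_equal(cross_matrix(a) + t(cross_matrix(a)), matrix(0, 3, 3))
  }
})
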