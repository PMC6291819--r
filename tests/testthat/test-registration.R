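# Closed-form rigid registration and its error measures.

test_that("identity and exact rigid motions are recovered to numerical precision", {
  m <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(1, 1, 2))
  same <- fitRigid(m, m)
  expect_equal(same@transform@rotation, diag(3), tolerance = 1e-12)
  expect_equal(same@transform@translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(same@freMm, 0, tolerance = 1e-12)

  t0 <- RigidTransform(rotationMatrix(c(0, 0, 1), 90), c(1, 2, 3))
  fit <- fitRigid(m, applyTransform(t0, m))
  expect_lt(max(abs(fit@transform@rotation - t0@rotation)), 1e-9)
  expect_lt(max(abs(fit@transform@translation - t0@translation)), 1e-9)
  expect_lt(fit@freMm, 1e-9)
  # bookkeeping invariant: FRE^2 is the mean squared residual
  expect_equal(fit@freMm^2, mean(fit@perFiducialResidualsMm^2),
               tolerance = 1e-15)
})

test_that("degenerate inputs are rejected", {
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(fitRigid(line, line + 1),
               class = "lasernav_degenerate_error")
  expect_error(fitRigid(line[1:2, ], line[1:2, ]),
               class = "lasernav_insufficient_fiducials")
})

test_that("noisy-fit FRE matches an independent numerical-optimization oracle", {
  # oracle: direct minimization of the rigid objective over Euler angles
  # and translation, independent of the closed form under test
  oracleFre <- function(m, f) {
    obj <- function(p) {
      R <- rotationMatrix(c(1, 0, 0), p[1]) %*%
        rotationMatrix(c(0, 1, 0), p[2]) %*%
        rotationMatrix(c(0, 0, 1), p[3])
      sum((m %*% t(R) + matrix(p[4:6], nrow(m), 3, byrow = TRUE) - f)^2)
    }
    best <- optim(rep(0, 6), obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-14))
    sqrt(best$value / nrow(m))
  }
  set.seed(5)
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(2, 2, 1))
  fres <- matrix(NA_real_, 200, 2)
  for (i in seq_len(nrow(fres))) {
    m <- base + matrix(rnorm(12, 0, 0.1), 4, 3)
    f <- base + matrix(rnorm(12, 0, 0.1), 4, 3)
    fres[i, 1] <- fitRigid(m, f)@freMm
    fres[i, 2] <- oracleFre(m, f)
  }
  expect_lt(abs(mean(fres[, 1]) - mean(fres[, 2])) / mean(fres[, 2]), 0.02)
  # the closed form is the global optimum: never worse than the oracle
  expect_true(all(fres[, 1] <= fres[, 2] + 1e-8))
})

test_that("FRE is invariant under a common rigid motion of both point sets", {
  set.seed(8)
  m <- matrix(runif(12, 0, 10), 4, 3)
  f <- m + matrix(rnorm(12, 0, 0.2), 4, 3)
  base <- fitRigid(m, f)@freMm
  for (rep in 1:10) {
    g <- RigidTransform(rotationMatrix(rnorm(3), runif(1, 0, 180)),
                        rnorm(3, 0, 15))
    moved <- fitRigid(applyTransform(g, m), applyTransform(g, f))@freMm
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("reflections are excluded even for noisy near-planar configurations", {
  set.seed(21)
  for (rep in 1:200) {
    m <- cbind(matrix(runif(8, 0, 5), 4, 2), rnorm(4, 0, 1e-4))
    f <- applyTransform(
      RigidTransform(rotationMatrix(rnorm(3), runif(1, 0, 180)), rnorm(3)),
      m) + matrix(rnorm(12, 0, 0.05), 4, 3)
    fit <- fitRigid(m, f)
    expect_gt(det(fit@transform@rotation), 0)
  }
})

test_that("recovered transform converges to truth as fiducial noise vanishes", {
  set.seed(12)
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(2, 2, 1.5))
  t0 <- RigidTransform(rotationMatrix(c(1, 1, 0), 25), c(4, -2, 1))
  targets <- rbind(c(5, 5, 0), c(-2, 3, 4))
  errAt <- vapply(c(0.1, 0.01, 0.001), function(sd) {
    mean(vapply(1:50, function(i) {
      f <- applyTransform(t0, base) + matrix(rnorm(12, 0, sd), 4, 3)
      mean(targetRegistrationError(fitRigid(base, f)@transform, t0, targets))
    }, numeric(1)))
  }, numeric(1))
  # error is O(sigma): one decade of noise buys about a decade of accuracy
  expect_gt(errAt[1] / errAt[2], 3)
  expect_gt(errAt[2] / errAt[3], 3)
  expect_lt(errAt[3], 0.01)
})

test_that("target registration error follows the closed rotation-geometry form", {
  t0 <- identityTransform()
  expect_equal(targetRegistrationError(t0, t0, rbind(c(1, 2, 3))), 0)
  # a pure translation displaces every target by exactly its magnitude
  shift <- RigidTransform(diag(3), c(0.1, 0, 0))
  errs <- targetRegistrationError(shift, t0,
                                  rbind(c(0, 0, 0), c(5, -3, 2), c(9, 9, 9)))
  expect_equal(errs, rep(0.1, 3), tolerance = 1e-12)
  # a pure rotation about z displaces a target by 2 sin(theta/2) * d,
  # with d its distance from the rotation axis
  theta <- 17
  rot <- RigidTransform(rotationMatrix(c(0, 0, 1), theta), c(0, 0, 0))
  targets <- rbind(c(1, 0, 0), c(0, 2.5, 4), c(3, 4, -2), c(0, 0, 7))
  d <- sqrt(rowSums(targets[, 1:2]^2))
  expect_equal(targetRegistrationError(rot, t0, targets),
               2 * sin(theta * pi / 360) * d, tolerance = 1e-12)
})

test_that("transform algebra composes and inverts consistently", {
  a <- RigidTransform(rotationMatrix(c(1, 2, 3), 40), c(1, -1, 2))
  b <- RigidTransform(rotationMatrix(c(-1, 1, 0), 65), c(0, 3, -2))
  p <- matrix(rnorm(9), 3, 3)
  expect_equal(applyTransform(composeTransforms(a, b), p),
               applyTransform(a, applyTransform(b, p)), tolerance = 1e-12)
  expect_equal(applyTransform(composeTransforms(invertTransform(a), a), p),
               p, tolerance = 1e-12)
})
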