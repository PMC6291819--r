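# Rigid point-set registration (Kabsch) and registration error measures.

#' Closed-form least-squares rigid fit (Kabsch)
#'
#' Estimates the rigid transform mapping `moving` onto `fixed` by centroid
#' alignment plus SVD of the cross-covariance, with the determinant-sign
#' correction that excludes reflections. Deterministic and
#' initialization-free.
#'
#' @param moving,fixed n x 3 matrices of paired points, mm (n >= 3,
#'   `moving` non-collinear).
#' @return A [RegistrationResult-class]: the transform, the fiducial
#'   registration error (FRE, RMS of residual norms), the plain mean
#'   residual, and the per-fiducial residuals.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' t0 <- RigidTransform(rotationMatrix(c(0, 0, 1), 30), c(1, 2, 3))
#' fitRigid(m, applyTransform(t0, m))
fitRigid <- function(moving, fixed) {
  m <- asPointMatrix(moving)
  f <- asPointMatrix(fixed)
  if (nrow(m) != nrow(f)) configError("point sets must be paired")
  if (nrow(m) < 3L)
    insufficientError("rigid fit requires at least 3 point pairs")
  mc <- colMeans(m); fc <- colMeans(f)
  m0 <- sweep(m, 2, mc); f0 <- sweep(f, 2, fc)
  sv <- svd(m0)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12) + 1e-12)
    degenerateError("moving points are collinear; rotation is unconstrained")
  H <- crossprod(m0, f0)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- fc - drop(R %*% mc)
  transform <- RigidTransform(R, tr)
  res <- rowNorms(applyTransform(transform, m) - f)
  new("RegistrationResult", transform = transform,
      freMm = sqrt(mean(res^2)), meanResidualMm = mean(res),
      perFiducialResidualsMm = res, nFiducials = nrow(m))
}

#' Target registration error
#'
#' Per-target Euclidean distance between a target mapped by the estimated
#' transform and by the true one: the clinically meaningful error measure,
#' evaluated at the marking targets rather than at the fiducials.
#'
#' @param est,true [RigidTransform-class] objects.
#' @param targets n x 3 matrix of target points, mm (non-empty).
#' @return Numeric vector of per-target errors, mm.
#' @export
targetRegistrationError <- function(est, true, targets) {
  targets <- asPointMatrix(targets)
  if (nrow(targets) == 0L) configError("targets must be non-empty")
  rowNorms(applyTransform(est, targets) - applyTransform(true, targets))
}
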