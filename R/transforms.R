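# Rigid transform algebra.

#' @describeIn applyTransform Map an n x 3 matrix of points (mm).
setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, x) {
    x %*% t(transform@rotation) +
      matrix(transform@translation, nrow(x), 3, byrow = TRUE)
  })

#' @describeIn applyTransform Map a single 3-vector.
setMethod("applyTransform", signature("RigidTransform", "numeric"),
  function(transform, x) {
    drop(transform@rotation %*% x) + transform@translation
  })

#' @describeIn applyTransform Map a [TargetPlan-class]: points are moved,
#'   normals and the view direction are rotated.
setMethod("applyTransform", signature("RigidTransform", "TargetPlan"),
  function(transform, x) {
    new("TargetPlan",
        points = applyTransform(transform, x@points),
        normals = x@normals %*% t(transform@rotation),
        viewDir = drop(transform@rotation %*% x@viewDir),
        label = x@label)
  })

#' Identity, composition and inverse of rigid transforms
#'
#' `composeTransforms(a, b)` returns the transform applying `b` first,
#' then `a` (i.e. `a o b`); `invertTransform(t)` its inverse;
#' `identityTransform()` the neutral element.
#'
#' @param a,b,transform [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  RigidTransform(rotation = a@rotation %*% b@rotation,
                 translation = drop(a@rotation %*% b@translation) +
                   a@translation)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(rotation = Rt, translation = -drop(Rt %*%
                                                      transform@translation))
}

#' @rdname composeTransforms
#' @export
identityTransform <- function() RigidTransform()

# Small random proper rotation: uniform axis, angle in [minDeg, maxDeg].
randomSmallRotation <- function(minDeg, maxDeg) {
  axis <- stats::rnorm(3)
  rotationMatrix(axis, stats::runif(1, minDeg, maxDeg))
}
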