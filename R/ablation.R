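# Target transfer into the laser frame, workspace/incidence constraint
# checking, and the crater-depth ablation model.

#' Transfer planned targets into the laser frame
#'
#' Maps each point by the rigid transform, preserving order. For a
#' [TargetPlan-class] use [applyTransform()] directly, which also rotates
#' the normals.
#'
#' @param points n x 3 matrix of points, mm.
#' @param transform a [RigidTransform-class].
#' @return n x 3 matrix of transferred points, mm.
#' @export
transferTargets <- function(points, transform) {
  applyTransform(transform, asPointMatrix(points))
}

#' Check laser workspace and incidence constraints
#'
#' A point is marked `out_of_workspace` when any coordinate falls outside
#' the addressable cube (side `workspaceSideMm`, centered on the device
#' origin), and `bad_incidence` when the angle between the surface plane
#' and the beam falls outside the usable range (the head is tilted until
#' the petrous surface sits at roughly 45-90 degrees to the beam; shallower
#' incidence ablates poorly).
#'
#' @param points n x 3 matrix, laser frame, mm.
#' @param normals n x 3 matrix of unit surface normals (laser frame).
#' @param cfg a [LaserConfig-class].
#' @param beamDir unit 3-vector of beam propagation (default straight
#'   down).
#' @return Character vector of flags: `"ok"`, `"out_of_workspace"` or
#'   `"bad_incidence"`.
#' @export
checkConstraints <- function(points, normals, cfg = LaserConfig(),
                             beamDir = c(0, 0, -1)) {
  points <- asPointMatrix(points)
  normals <- asPointMatrix(normals)
  if (nrow(points) != nrow(normals))
    configError("points and normals must align")
  beamDir <- unitVector(beamDir)
  half <- cfg@workspaceSideMm / 2
  outWs <- apply(abs(points) > half, 1, any)
  # angle between surface PLANE and beam = 90 deg - angle(normal, beam)
  cosNb <- abs(drop(normals %*% beamDir)) / rowNorms(normals)
  planeAngle <- 90 - acos(clip(cosNb, -1, 1)) * 180 / pi
  badInc <- planeAngle < cfg@incidenceRangeDeg[1] |
    planeAngle > cfg@incidenceRangeDeg[2]
  flags <- rep("ok", nrow(points))
  flags[badInc] <- "bad_incidence"
  flags[outWs] <- "out_of_workspace"
  flags
}

#' Simulate the marking ablation
#'
#' The crater model is empirical: each ablation cycle removes a fixed
#' depth of bone (`depthPerCycleMm`, default 0.3 mm), so an ok-flagged
#' target receives `nCycles * depthPerCycleMm`. Mark positions equal the
#' target positions plus an optional isotropic execution-noise draw
#' (beam-pointing jitter, default off). Path time is the polyline length
#' through the executed (ok) marks divided by the focus-spot speed.
#' Non-ok points are skipped with depth 0.
#'
#' @param points n x 3 matrix of transferred targets, laser frame, mm.
#' @param flags flags from [checkConstraints()] (recycled `"ok"` if
#'   missing).
#' @param cfg a [LaserConfig-class].
#' @param nCycles number of ablation cycles (>= 0).
#' @return An [AblationResult-class].
#' @export
simulateAblation <- function(points, flags = NULL, cfg = LaserConfig(),
                             nCycles = 1L) {
  points <- asPointMatrix(points)
  n <- nrow(points)
  if (is.null(flags)) flags <- rep("ok", n)
  if (length(flags) != n) configError("flags must align with points")
  if (nCycles < 0) configError("nCycles must be >= 0")
  marks <- points
  if (cfg@execNoiseSdMm > 0)
    marks <- marks + matrix(stats::rnorm(3 * n, 0, cfg@execNoiseSdMm), n, 3)
  ok <- flags == "ok"
  depths <- ifelse(ok, nCycles * cfg@depthPerCycleMm, 0)
  okPts <- marks[ok, , drop = FALSE]
  pathLen <- if (nrow(okPts) >= 2L)
    sum(rowNorms(diff(okPts))) else 0
  new("AblationResult", marksMm = marks, depthsMm = as.numeric(depths),
      flags = flags, pathTimeS = pathLen / cfg@focusSpeedMmS)
}
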