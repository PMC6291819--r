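# Synthetic phantom generator: paired CBCT and OCT volumes of a bone slab
# with a buried canal (internal auditory canal surrogate) and spherical
# titanium fiducial markers, plus the exact ground truth behind them.

#' Bone surface height-field
#'
#' The bone surface is the graph `z = h(x, y)` of a low-order polynomial
#' plus an optional Gaussian bump, so heights, gradients and outward unit
#' normals are analytic. The parameter list has entries `center` (c(cx, cy)),
#' `coef` (c(z0, ax, ay, axx, axy, ayy) for
#' `z0 + ax*u + ay*v + axx*u^2 + axy*u*v + ayy*v^2`, `u = x - cx`,
#' `v = y - cy`) and `bump` (c(amplitude, bx, by, sigma)).
#'
#' @param surface height-field parameter list.
#' @param x,y world coordinates, mm (vectorized).
#' @return `heightfieldHeight`: heights `z` (mm); `heightfieldGradient`: a
#'   list with elements `dx`, `dy`; `heightfieldNormal`: an n x 3 matrix of
#'   outward (+z) unit normals.
#' @export
heightfieldHeight <- function(surface, x, y) {
  u <- x - surface$center[1]; v <- y - surface$center[2]
  cf <- surface$coef
  z <- cf[1] + cf[2] * u + cf[3] * v + cf[4] * u^2 + cf[5] * u * v +
    cf[6] * v^2
  b <- surface$bump
  if (!is.null(b) && b[1] != 0)
    z <- z + b[1] * exp(-((x - b[2])^2 + (y - b[3])^2) / (2 * b[4]^2))
  z
}

#' @rdname heightfieldHeight
#' @export
heightfieldGradient <- function(surface, x, y) {
  u <- x - surface$center[1]; v <- y - surface$center[2]
  cf <- surface$coef
  dx <- cf[2] + 2 * cf[4] * u + cf[5] * v
  dy <- cf[3] + cf[5] * u + 2 * cf[6] * v
  b <- surface$bump
  if (!is.null(b) && b[1] != 0) {
    g <- b[1] * exp(-((x - b[2])^2 + (y - b[3])^2) / (2 * b[4]^2))
    dx <- dx - g * (x - b[2]) / b[4]^2
    dy <- dy - g * (y - b[3]) / b[4]^2
  }
  list(dx = dx, dy = dy)
}

#' @rdname heightfieldHeight
#' @export
heightfieldNormal <- function(surface, x, y) {
  g <- heightfieldGradient(surface, x, y)
  n <- cbind(-g$dx, -g$dy, rep(1, length(g$dx)))
  n / rowNorms(n)
}

#' @rdname heightfieldHeight
#' @export
defaultBoneSurface <- function() {
  list(center = c(8.4, 8.4),
       coef = c(9, 0.06, -0.10, -0.004, 0, -0.004),
       bump = c(0.3, 8.4, 8.4, 3.0))
}

#' Default canal geometry
#'
#' A V-shaped tube: two straight arms meeting at a medial apex (apex on the
#' +y side), running at constant depth below the bone surface.
#'
#' @return Canal parameter list (`apexXY`, `armAngleDeg`, `armLengthMm`,
#'   `radiusMm`, `depthMm`).
#' @export
defaultCanal <- function() {
  list(apexXY = c(8.4, 10.8), armAngleDeg = 65, armLengthMm = 4,
       radiusMm = 0.7, depthMm = 1.0)
}

#' Canal axis polyline
#'
#' Samples the canal center line (mm, CBCT frame): both arms from their
#' lateral ends to the apex, with `z = h(x, y) - depthMm - radiusMm`.
#'
#' @param spec a [PhantomSpec-class].
#' @param stepMm sampling step along each arm, mm.
#' @return m x 3 matrix of axis points ordered arm 1 -> apex -> arm 2.
#' @export
canalAxis <- function(spec, stepMm = 0.25) {
  cn <- spec@canal
  a <- cn$armAngleDeg * pi / 180
  dirs <- list(c(-sin(a), -cos(a)), c(sin(a), -cos(a)))
  t1 <- rev(seq(0, cn$armLengthMm, by = stepMm))
  t2 <- seq(stepMm, cn$armLengthMm, by = stepMm)
  xy <- rbind(cbind(cn$apexXY[1] + t1 * dirs[[1]][1],
                    cn$apexXY[2] + t1 * dirs[[1]][2]),
              cbind(cn$apexXY[1] + t2 * dirs[[2]][1],
                    cn$apexXY[2] + t2 * dirs[[2]][2]))
  z <- heightfieldHeight(spec@boneSurface, xy[, 1], xy[, 2]) -
    cn$depthMm - cn$radiusMm
  cbind(xy, z)
}

# Minimum distance from each point (n x 3) to a polyline (m x 3).
pointPolylineDistance <- function(points, polyline) {
  points <- asPointMatrix(points)
  dmin <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[s, ]; b <- polyline[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(points, 2, a)
    t <- if (len2 > 0) clip(drop(ap %*% ab) / len2, 0, 1) else 0
    foot <- outer(t, ab)
    dmin <- pmin(dmin, rowNorms(ap - foot))
  }
  dmin
}

#' Partial-volume occupancy of a sphere on a voxel grid
#'
#' For each voxel, the fraction of its volume inside the sphere, estimated
#' by supersampling (`supersample^3` sub-cells per voxel, sub-cell centers).
#' This is the renderer used for fiducials; summing the result times the
#' voxel volume conserves the analytic sphere volume to well under 1% at
#' supersampling >= 4.
#'
#' @param dims integer 3-vector of grid size.
#' @param spacing,origin grid geometry (mm; voxel-center convention).
#' @param center,radius sphere definition (mm).
#' @param supersample per-axis supersampling factor.
#' @return Array of occupancy fractions in `[0, 1]` with dimension `dims`.
#' @export
sphereOccupancy <- function(dims, spacing, origin, center, radius,
                            supersample = 8L) {
  occ <- array(0, dims)
  box <- sphereOccupancyBox(dims, spacing, origin, center, radius,
                            supersample)
  if (is.null(box)) return(occ)
  occ[box$ix, box$iy, box$iz] <- box$occ
  occ
}

# Occupancy restricted to the sphere's bounding box; returns NULL when the
# sphere misses the grid entirely.
sphereOccupancyBox <- function(dims, spacing, origin, center, radius,
                               supersample = 8L) {
  s <- as.integer(supersample)
  rng <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(0L, as.integer(floor((center[a] - radius - origin[a]) /
                                     spacing[a])) - 1L)
    hi <- min(dims[a] - 1L, as.integer(ceiling((center[a] + radius -
                                                  origin[a]) / spacing[a])) +
                1L)
    if (lo > hi) return(NULL)
    rng[[a]] <- lo:hi
  }
  off <- lapply(1:3, function(a) (((1:s) - 0.5) / s - 0.5) * spacing[a])
  sq <- lapply(1:3, function(a) {
    centers <- origin[a] + rng[[a]] * spacing[a]
    (as.vector(outer(off[[a]], centers, "+")) - center[a])^2
  })
  inside <- outer(outer(sq[[1]], sq[[2]], "+"), sq[[3]], "+") < radius^2
  nb <- lengths(rng)
  dim(inside) <- c(s, nb[1], s, nb[2], s, nb[3])
  occ <- apply(inside, c(2L, 4L, 6L), mean)
  list(ix = rng[[1]] + 1L, iy = rng[[2]] + 1L, iz = rng[[3]] + 1L, occ = occ)
}

# --- phantom geometry -------------------------------------------------------

# Draw the fiducial arrangement and (if unspecified) the true transform.
# All draws come from the phantom seed.
phantomGeometry <- function(spec) {
  withSeed(spec@seed, {
    centers <- placeFiducials(spec)
    trueT <- spec@trueTransform
    if (is.null(trueT)) trueT <- drawTrueTransform(spec, centers)
    list(fiducialCenters = centers, trueTransform = trueT)
  })
}

# Fiducials sit along the (curved) craniotomy edge: an arc below the canal,
# consecutive surface-to-surface gaps uniform within the permitted interval,
# spheres mounted proud of the surface by the standoff. Arc curvature
# guarantees non-collinearity; the bounded arc span keeps the arrangement
# (plus the canal) inside the OCT workspace.
placeFiducials <- function(spec) {
  n <- spec@nFiducials
  r <- spec@fiducialDiameterMm / 2
  cxy <- spec@cbctFovMm / 2
  axis <- canalAxis(spec)
  lo <- spec@fiducialSpacingMm[1]
  hi <- spec@fiducialSpacingMm[2]
  # draw gaps off the interval ends so radial jitter cannot push them out
  pad <- min(0.15, (hi - lo) / 4)
  for (try in seq_len(100L)) {
    rho <- 4.5 + stats::runif(1, -0.3, 0.3)
    gaps <- if (n > 1L) stats::runif(n - 1L, lo + pad, hi - pad) else numeric(0)
    chords <- 2 * r + gaps
    dphi <- 2 * asin(clip(chords / (2 * rho), 0, 1))
    phi <- -pi / 2 - sum(dphi) / 2 + cumsum(c(0, dphi)) +
      stats::runif(1, -0.08, 0.08)
    rad <- rho + stats::runif(n, -0.1, 0.1)
    xy <- cbind(cxy + rad * cos(phi),
                cxy + 1.0 + rad * sin(phi))
    z <- heightfieldHeight(spec@boneSurface, xy[, 1], xy[, 2]) + r +
      spec@fiducialStandoffMm
    centers <- cbind(xy, z)
    if (!fiducialArrangementOk(spec, centers, axis)) next
    return(centers)
  }
  configError("could not place a valid fiducial arrangement; check the spec")
}

fiducialArrangementOk <- function(spec, centers, axis) {
  n <- nrow(centers)
  r <- spec@fiducialDiameterMm / 2
  margin <- 1.2
  if (any(centers[, 1:2] < margin) ||
      any(centers[, 1:2] > spec@cbctFovMm - margin))
    return(FALSE)
  if (any(centers[, 3] + r > spec@cbctFovMm - 0.6)) return(FALSE)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(centers))
    diag(d) <- Inf
    if (min(d) < 2 * r + 0.1) return(FALSE)   # sphere overlap
    gaps <- d[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] - 2 * r
    if (any(gaps < spec@fiducialSpacingMm[1] |
              gaps > spec@fiducialSpacingMm[2]))
      return(FALSE)                           # side-to-side gap out of band
  }
  if (n >= 3L) {
    sv <- svd(scale(centers, scale = FALSE))$d
    if (sv[2] < 0.15) return(FALSE)           # collinear within tolerance
  }
  # clearance to the canal tube (3-D)
  if (min(pointPolylineDistance(centers, axis)) <
      r + spec@canal$radiusMm + 0.1)
    return(FALSE)
  TRUE
}

# Draw the hidden CBCT -> laser/OCT transform: a small random rotation plus
# the translation that centers the region of interest (fiducials + canal
# projection on the surface) laterally in the OCT cube with the bone surface
# in its lower half, as the device would be aimed in practice.
drawTrueTransform <- function(spec, fiducialCenters) {
  axis <- canalAxis(spec, stepMm = 0.5)
  surfacePts <- cbind(axis[, 1:2],
                      heightfieldHeight(spec@boneSurface, axis[, 1],
                                        axis[, 2]))
  roi <- rbind(fiducialCenters, surfacePts)
  half <- spec@fovOctMm / 2
  angles <- c(6, 4, 2, 0)
  for (maxDeg in angles) {
    for (k in seq_len(10L)) {
      R <- if (maxDeg > 0) randomSmallRotation(maxDeg / 3, maxDeg) else diag(3)
      m <- roi %*% t(R)
      rCapTop <- spec@fiducialDiameterMm / 2
      # aim: surface around z = -2, but never let a marker cap cross the
      # FOV mid-plane (markers stay in the lower part of the spectral view)
      tz <- min(-2 - mean(surfacePts %*% t(R)[, 3, drop = FALSE]),
                -0.3 - max((fiducialCenters %*% t(R))[, 3] + rCapTop))
      tr <- c(-mean(range(m[, 1])), -mean(range(m[, 2])), tz)
      mm <- sweep(m, 2, -tr)
      fid <- sweep(fiducialCenters %*% t(R), 2, -tr)
      rCap <- spec@fiducialDiameterMm / 2
      ok <- all(abs(mm[, 1:2]) < half - 0.25) &&
        all(abs(fid[, 1:2]) < half - rCap - 0.25) &&
        all(fid[, 3] + rCap <= 0) &&
        all(mm[, 3] > -half + spec@noise@octPenetrationBoneMm + 0.25)
      if (ok) return(RigidTransform(R, tr))
      if (maxDeg == 0) break
    }
  }
  configError("could not fit the specimen into the OCT field of view")
}

# --- CBCT rendering ---------------------------------------------------------

cbctGrid <- function(spec) {
  n <- max(8L, as.integer(round(spec@cbctFovMm / spec@cbctVoxelMm)))
  list(dims = rep(n, 3L), spacing = rep(spec@cbctVoxelMm, 3L),
       origin = rep(spec@cbctVoxelMm / 2, 3L))
}

# Logical canal mask on the CBCT grid (voxel centers inside the tube).
canalMaskArray <- function(spec, grid = cbctGrid(spec)) {
  axis <- canalAxis(spec)
  mask <- array(FALSE, grid$dims)
  r <- spec@canal$radiusMm
  co <- lapply(1:3, function(a) grid$origin[a] +
                 (seq_len(grid$dims[a]) - 1L) * grid$spacing[a])
  idx <- lapply(1:3, function(a) {
    which(co[[a]] >= min(axis[, a]) - r - grid$spacing[a] &
            co[[a]] <= max(axis[, a]) + r + grid$spacing[a])
  })
  if (any(lengths(idx) == 0L)) return(mask)
  pts <- as.matrix(expand.grid(co[[1]][idx[[1]]], co[[2]][idx[[2]]],
                               co[[3]][idx[[3]]]))
  inside <- pointPolylineDistance(pts, axis) <= r
  mask[idx[[1]], idx[[2]], idx[[3]]] <-
    array(inside, lengths(idx))
  mask
}

# Render a CBCT volume: bone slab below the height-field, canal tube at
# soft-tissue intensity, spheres by partial-volume occupancy, optional
# additive Gaussian noise (drawn from the current RNG stream).
renderCbctVolume <- function(spec, sphereCenters, noiseSd = 0,
                             sphereRadius = spec@fiducialDiameterMm / 2,
                             canalMask = NULL, grid = cbctGrid(spec)) {
  iv <- spec@intensities
  co <- lapply(1:3, function(a) grid$origin[a] +
                 (seq_len(grid$dims[a]) - 1L) * grid$spacing[a])
  H <- outer(co[[1]], co[[2]],
             function(x, y) heightfieldHeight(spec@boneSurface, x, y))
  vol <- array(iv[["air"]], grid$dims)
  for (k in seq_len(grid$dims[3])) {
    zk <- co[[3]][k]
    vol[, , k] <- ifelse(H >= zk & zk >= spec@boneZMinMm, iv[["bone"]],
                         iv[["air"]])
  }
  if (is.null(canalMask)) canalMask <- canalMaskArray(spec, grid)
  vol[canalMask] <- iv[["soft"]]
  if (!is.null(sphereCenters) && nrow(sphereCenters) > 0) {
    for (i in seq_len(nrow(sphereCenters))) {
      box <- sphereOccupancyBox(grid$dims, grid$spacing, grid$origin,
                                sphereCenters[i, ], sphereRadius,
                                spec@supersample)
      if (is.null(box)) next
      bg <- vol[box$ix, box$iy, box$iz]
      vol[box$ix, box$iy, box$iz] <-
        bg * (1 - box$occ) + iv[["titanium"]] * box$occ
    }
  }
  if (noiseSd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, noiseSd), dim(vol))
  Volume3D(vol, grid$spacing, grid$origin, "CBCT")
}

#' Generate the CBCT phantom
#'
#' Builds one synthetic specimen: draws the fiducial arrangement (gaps in
#' the permitted interval, non-collinear, clear of the canal) and the
#' hidden CBCT-to-laser/OCT transform from the spec seed, then renders the
#' CBCT volume. Fiducials are rendered by supersampled partial-volume
#' occupancy so their intensity-weighted centroids are sub-voxel accurate;
#' bone, canal and air are nominal-intensity regions; Gaussian noise is
#' added per the [NoiseSpec-class].
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `volume` ([Volume3D-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
#' @examples
#' ph <- makeCbctPhantom(studyPhantomSpec(seed = 1))
#' ph$volume
makeCbctPhantom <- function(spec) {
  methods::validObject(spec)
  geom <- phantomGeometry(spec)
  grid <- cbctGrid(spec)
  canal <- canalMaskArray(spec, grid)
  # reject configurations where spheres intersect the canal or each other
  axis <- canalAxis(spec)
  r <- spec@fiducialDiameterMm / 2
  if (min(pointPolylineDistance(geom$fiducialCenters, axis)) <
      r + spec@canal$radiusMm)
    configError("fiducial sphere overlaps the canal")
  if (nrow(geom$fiducialCenters) >= 2L) {
    d <- as.matrix(stats::dist(geom$fiducialCenters)); diag(d) <- Inf
    if (min(d) < 2 * r) configError("fiducial spheres overlap each other")
  }
  vol <- withSeed(deriveSeed(spec@seed, 1L),
                  renderCbctVolume(spec, geom$fiducialCenters,
                                   noiseSd = spec@noise@cbctGaussianSd,
                                   canalMask = canal, grid = grid))
  truth <- new("GroundTruth",
               fiducialCentersCbct = geom$fiducialCenters,
               fiducialCentersOct = applyTransform(geom$trueTransform,
                                                   geom$fiducialCenters),
               canalMask = canal, surface = spec@boneSurface,
               trueTransform = geom$trueTransform)
  list(volume = vol, truth = truth)
}

# --- OCT rendering ----------------------------------------------------------

# Vectorized Newton solve for the bone surface height (laser/OCT frame)
# above each lateral position: finds z with qz(z) = h(qx(z), qy(z)) where
# q = Tinv (x, y, z).
octSurfaceHeight <- function(surface, tinv, x, y, zInit = -2,
                             iterations = 15L) {
  n <- length(x)
  Rt <- tinv@rotation
  tt <- tinv@translation
  z <- rep(zInit, n)
  for (it in seq_len(iterations)) {
    qx <- Rt[1, 1] * x + Rt[1, 2] * y + Rt[1, 3] * z + tt[1]
    qy <- Rt[2, 1] * x + Rt[2, 2] * y + Rt[2, 3] * z + tt[2]
    qz <- Rt[3, 1] * x + Rt[3, 2] * y + Rt[3, 3] * z + tt[3]
    f <- qz - heightfieldHeight(surface, qx, qy)
    g <- heightfieldGradient(surface, qx, qy)
    fp <- Rt[3, 3] - g$dx * Rt[1, 3] - g$dy * Rt[2, 3]
    fp[abs(fp) < 0.2] <- sign(fp[abs(fp) < 0.2] + 1e-12) * 0.2
    z <- clip(z - f / fp, -50, 50)
  }
  z
}

#' Render the OCT volume of a phantom
#'
#' Simulates the spectral-domain OCT view of the specimen in the laser/OCT
#' frame: signal exists only from the outer surface down to the bone
#' penetration depth, with exponential attenuation; each titanium sphere
#' appears only as its upper cap (strong reflectance) with a shadow beneath
#' (infrared light does not penetrate titanium); multiplicative mean-one
#' log-normal speckle is applied. The field of view is a cube of side
#' `fovOctMm` centered on the device origin.
#'
#' @param spec a [PhantomSpec-class].
#' @param truth the [GroundTruth-class] from [makeCbctPhantom()].
#' @return A [Volume3D-class] with modality `"OCT"`.
#' @export
makeOctVolume <- function(spec, truth) {
  half <- spec@fovOctMm / 2
  r <- spec@fiducialDiameterMm / 2
  fid <- truth@fiducialCentersOct
  for (i in seq_len(nrow(fid))) {
    if (any(abs(fid[i, 1:2]) > half - 1e-9) ||
        fid[i, 3] - r < -half || fid[i, 3] + r > half)
      fovError(sprintf("fiducial %d lies outside the OCT field of view", i))
    if (fid[i, 3] + r > 0)
      fovError(sprintf(
        "fiducial %d is not in the lower part of the OCT field", i))
  }
  nl <- max(8L, as.integer(round(spec@fovOctMm / spec@octLateralMm)))
  na <- max(8L, as.integer(round(spec@fovOctMm / spec@octAxialMm)))
  sl <- spec@fovOctMm / nl
  sa <- spec@fovOctMm / na
  xs <- -half + sl / 2 + (0:(nl - 1L)) * sl
  zs <- -half + sa / 2 + (0:(na - 1L)) * sa
  tinv <- invertTransform(truth@trueTransform)
  gx <- rep(xs, times = nl)
  gy <- rep(xs, each = nl)
  Hb <- matrix(octSurfaceHeight(truth@surface, tinv, gx, gy), nl, nl)
  # fiducial caps: height of the upper spherical cap over each column
  Hcap <- matrix(-Inf, nl, nl)
  for (i in seq_len(nrow(fid))) {
    rho2 <- outer((xs - fid[i, 1])^2, (xs - fid[i, 2])^2, "+")
    inside <- rho2 < (0.998 * r)^2
    capz <- fid[i, 3] + sqrt(pmax(r^2 - rho2, 0))
    Hcap[inside] <- pmax(Hcap[inside], capz[inside])
  }
  isCap <- Hcap > Hb
  S <- pmax(Hb, Hcap)
  boneRefl <- 1.0
  capRefl <- 3.0
  pen <- spec@noise@octPenetrationBoneMm
  att <- spec@noise@octAttenuationPerMm
  vol <- array(0, c(nl, nl, na))
  for (k in seq_len(na)) {
    depth <- S - zs[k]
    wtop <- clip(depth / sa + 0.5, 0, 1)
    bone <- boneRefl * wtop * exp(-att * pmax(depth, 0)) * (depth <= pen)
    cap <- capRefl * pmax(0, 1 - abs(depth) / (2 * sa))
    vol[, , k] <- ifelse(isCap, cap, bone)
  }
  if (spec@noise@octSpeckleScale > 0) {
    s <- spec@noise@octSpeckleScale
    vol <- withSeed(deriveSeed(spec@seed, 2L), {
      vol * exp(array(stats::rnorm(length(vol), -s^2 / 2, s), dim(vol)))
    })
  }
  Volume3D(vol, c(sl, sl, sa), c(-half + sl / 2, -half + sl / 2,
                                 -half + sa / 2), "OCT")
}

#' Phantom spec at Monte-Carlo study scale
#'
#' The accuracy study renders hundreds of paired volumes, so it uses a
#' 0.08 mm OCT grid (a 125^3 cube over the 10 mm workspace) instead of the
#' full-resolution 0.03 mm default; all physical parameters (0.3 mm CBCT
#' voxels, four 1 mm spheres 1-2 mm apart, noise levels) are unchanged.
#'
#' @param ... overrides passed to [PhantomSpec()].
#' @return A [PhantomSpec-class].
#' @export
studyPhantomSpec <- function(...) {
  args <- list(...)
  defaults <- list(octLateralMm = 0.08, octAxialMm = 0.08)
  do.call(PhantomSpec, utils::modifyList(defaults, args))
}
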