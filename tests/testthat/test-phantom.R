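# Phantom generator: geometry invariants, partial-volume rendering,
# determinism of the paired CBCT/OCT volumes.

test_that("default phantom renders exactly four titanium components with valid geometry", {
  spec <- noisySpec(seed = 1)
  ph <- makeCbctPhantom(spec)
  v <- volData(ph$volume)
  thr <- mean(spec@intensities[c("bone", "titanium")])
  coords <- which(v > thr, arr.ind = TRUE)
  memb <- lasernav:::gridComponents(coords)
  expect_equal(max(memb), 4L)

  # consecutive surface-to-surface gaps inside the permitted interval
  ctr <- ph$truth@fiducialCentersCbct
  gaps <- sqrt(rowSums(diff(ctr)^2)) - spec@fiducialDiameterMm
  expect_true(all(gaps >= spec@fiducialSpacingMm[1] - 1e-9))
  expect_true(all(gaps <= spec@fiducialSpacingMm[2] + 1e-9))

  # non-collinear arrangement (second singular value above tolerance)
  sv <- svd(scale(ctr, scale = FALSE))$d
  expect_gt(sv[2], 0.15)

  # ground-truth frames agree to machine precision
  expect_equal(ph$truth@fiducialCentersOct,
               applyTransform(ph$truth@trueTransform,
                              ph$truth@fiducialCentersCbct),
               tolerance = 1e-14)

  # canal lies entirely below the bone surface
  idx <- which(ph$truth@canalMask, arr.ind = TRUE)
  pts <- sweep((idx - 1) %*% diag(volSpacing(ph$volume)), 2,
               -volOrigin(ph$volume))
  h <- heightfieldHeight(ph$truth@surface, pts[, 1], pts[, 2])
  expect_true(all(pts[, 3] < h))
})

test_that("sphere occupancy is symmetric for a sphere centered on a voxel center", {
  dims <- c(15L, 15L, 15L)
  sp <- rep(0.3, 3)
  org <- rep(0.15, 3)
  center <- org + 7 * sp   # voxel index (7,7,7), exactly a voxel center
  occ <- sphereOccupancy(dims, sp, org, center, 0.5, supersample = 6L)
  expect_equal(occ, occ[15:1, , ], tolerance = 0)
  expect_equal(occ, occ[, 15:1, ], tolerance = 0)
  expect_equal(occ, occ[, , 15:1], tolerance = 0)
})

test_that("partial-volume mass matches the analytic sphere volume within 1%", {
  dims <- c(16L, 16L, 16L)
  sp <- rep(0.3, 3)
  org <- rep(0.15, 3)
  r <- 0.5
  analytic <- 4 * pi / 3 * r^3 / prod(sp)   # sphere volume in voxel units
  for (center in list(c(2.4, 2.4, 2.4), c(2.33, 2.51, 2.47))) {
    occ <- sphereOccupancy(dims, sp, org, center, r, supersample = 8L)
    expect_lt(abs(sum(occ) - analytic) / analytic, 0.01)
  }
  # the invariant also holds at the minimum recommended supersampling
  occ4 <- sphereOccupancy(dims, sp, org, c(2.41, 2.48, 2.52), r,
                          supersample = 4L)
  expect_lt(abs(sum(occ4) - analytic) / analytic, 0.01)
})

test_that("phantom generation is deterministic given (spec, seed)", {
  a <- makeCbctPhantom(noisySpec(seed = 42))
  b <- makeCbctPhantom(noisySpec(seed = 42))
  expect_identical(volData(a$volume), volData(b$volume))
  expect_identical(a$truth@fiducialCentersCbct, b$truth@fiducialCentersCbct)
  octA <- makeOctVolume(noisySpec(seed = 42), a$truth)
  octB <- makeOctVolume(noisySpec(seed = 42), b$truth)
  expect_identical(volData(octA), volData(octB))
  # different seed gives a different arrangement
  c <- makeCbctPhantom(noisySpec(seed = 43))
  expect_false(identical(a$truth@fiducialCentersCbct,
                         c$truth@fiducialCentersCbct))
})

test_that("OCT render puts the brightest voxels on the upper hemispheres only", {
  spec <- cleanSpec(seed = 2)
  ph <- makeCbctPhantom(spec)
  oct <- makeOctVolume(spec, ph$truth)
  v <- volData(oct)
  bright <- which(v > 0.9 * max(v), arr.ind = TRUE)
  pts <- sweep((bright - 1) %*% diag(volSpacing(oct)), 2, -volOrigin(oct))
  r <- spec@fiducialDiameterMm / 2
  centers <- ph$truth@fiducialCentersOct
  for (i in seq_len(nrow(pts))) {
    d <- sqrt(rowSums((centers - matrix(pts[i, ], nrow(centers), 3,
                                        byrow = TRUE))^2))
    j <- which.min(d)
    # on the sphere surface to within half an axial voxel...
    expect_lt(abs(d[j] - r), volSpacing(oct)[3] / 2 + 1e-9)
    # ...and on the UPPER hemisphere
    expect_gt(pts[i, 3], centers[j, 3])
  }
})

test_that("OCT signal vanishes below the bone penetration depth", {
  spec <- cleanSpec(seed = 2)
  ph <- makeCbctPhantom(spec)
  oct <- makeOctVolume(spec, ph$truth)
  v <- volData(oct)
  dims <- dim(v)
  sp <- volSpacing(oct)
  org <- volOrigin(oct)
  tinv <- invertTransform(ph$truth@trueTransform)
  pen <- spec@noise@octPenetrationBoneMm
  set.seed(7)
  cols <- cbind(sample(dims[1], 200, replace = TRUE),
                sample(dims[2], 200, replace = TRUE))
  for (i in seq_len(nrow(cols))) {
    x <- org[1] + (cols[i, 1] - 1) * sp[1]
    y <- org[2] + (cols[i, 2] - 1) * sp[2]
    # independent surface solve by bisection on the mapped height-field
    f <- function(z) {
      q <- applyTransform(tinv, c(x, y, z))
      q[3] - heightfieldHeight(ph$truth@surface, q[1], q[2])
    }
    lo <- org[3]; hi <- org[3] + (dims[3] - 1) * sp[3]
    if (f(lo) > 0 || f(hi) < 0) next    # surface outside the FOV column
    s <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    deep <- which(org[3] + (seq_len(dims[3]) - 1) * sp[3] <
                    s - pen - sp[3])
    if (length(deep))
      expect_identical(unique(v[cols[i, 1], cols[i, 2], deep]), 0)
  }
})

test_that("fiducials outside the OCT field of view are rejected by marker name", {
  spec <- cleanSpec(seed = 1)
  ph <- makeCbctPhantom(spec)
  truth <- ph$truth
  # push marker 2 outside laterally
  bad <- truth@fiducialCentersOct
  bad[2, 1] <- spec@fovOctMm    # far outside the half-width
  truthBad <- truth
  truthBad@fiducialCentersOct <- bad
  expect_error(makeOctVolume(spec, truthBad), "fiducial 2",
               class = "lasernav_fov_error")
})

test_that("infeasible configurations are rejected with a configuration error", {
  # an OCT field of view far smaller than the specimen cannot hold the
  # markers and the marking region together
  expect_error(makeCbctPhantom(studyPhantomSpec(seed = 1, fovOctMm = 4)),
               class = "lasernav_config_error")
  # nor can the markers be arranged inside a tiny CBCT field of view
  expect_error(makeCbctPhantom(studyPhantomSpec(seed = 1, cbctFovMm = 6)),
               class = "lasernav_config_error")
})
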