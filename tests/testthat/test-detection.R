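# Sphere detection in both modalities and correspondence matching.

test_that("noise-free CBCT detection finds all spheres with sub-voxel accuracy", {
  spec <- cleanSpec(seed = 1)
  ph <- makeCbctPhantom(spec)
  fid <- detectSpheresCbct(ph$volume, spec@fiducialDiameterMm,
                           spec@nFiducials)
  expect_equal(nrow(fiducialCenters(fid)), 4L)
  err <- sqrt(rowSums((sortByX(fiducialCenters(fid)) -
                         sortByX(ph$truth@fiducialCentersCbct))^2))
  expect_lt(max(err), 0.03)                       # 0.1 x the 0.3 mm voxel
  expect_lt(max(err), volSpacing(ph$volume)[1] / 3)  # sub-voxel property
})

test_that("empty and degenerate CBCT volumes raise insufficient-fiducial errors", {
  zero <- Volume3D(array(0, c(20, 20, 20)), 0.3, modality = "CBCT")
  expect_error(detectSpheresCbct(zero, 1, 4),
               "fewer than 3", class = "lasernav_insufficient_fiducials")
})

test_that("spheres centered on voxel centers are localized essentially exactly", {
  dims <- c(40L, 40L, 20L)
  sp <- rep(0.3, 3)
  org <- rep(0.15, 3)
  # three isolated spheres, each centered exactly on a voxel center
  idx <- rbind(c(8, 8, 10), c(25, 9, 10), c(15, 28, 10))
  v <- array(0, dims)
  for (i in 1:3)
    v <- v + 1200 * sphereOccupancy(dims, sp, org, org + idx[i, ] * sp, 0.5)
  fid <- detectSpheresCbct(Volume3D(v, sp, org, "CBCT"), 1.0, 3L)
  got <- sortByX(fiducialCenters(fid))
  want <- sortByX(sweep(idx %*% diag(sp), 2, -org))
  expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("noise-free OCT detection recovers centers within 0.05 mm", {
  spec <- cleanSpec(seed = 1)
  ph <- makeCbctPhantom(spec)
  oct <- makeOctVolume(spec, ph$truth)
  fid <- detectSpheresOct(oct, spec@fiducialDiameterMm, spec@nFiducials)
  expect_equal(nrow(fiducialCenters(fid)), 4L)
  err <- sqrt(rowSums((sortByX(fiducialCenters(fid)) -
                         sortByX(ph$truth@fiducialCentersOct))^2))
  expect_lt(max(err), 0.05)
  expect_true(all(fiducialQuality(fid) > 0.5))
})

test_that("free-radius cap fit recovers the 1 mm marker diameter", {
  spec <- cleanSpec(seed = 1)
  ph <- makeCbctPhantom(spec)
  oct <- makeOctVolume(spec, ph$truth)
  fid <- detectSpheresOct(oct, 1.0, 4L, fitRadius = "free")
  expect_equal(2 * fiducialRadii(fid), rep(1.0, 4), tolerance = 0.05)
})

test_that("sphere fits are exact on analytic hemisphere point clouds", {
  center <- c(1.2, -0.7, 3.4)
  pts <- hemispherePoints(center, 0.5, n = 300)
  free <- fitSphere(pts)
  expect_equal(free$center, center, tolerance = 1e-9)
  expect_equal(free$radius, 0.5, tolerance = 1e-9)
  known <- fitSphere(pts, radius = 0.5)
  expect_equal(known$center, center, tolerance = 1e-9)
  expect_lt(known$rms, 1e-10)
})

test_that("matching recovers a known permutation under rigid motion", {
  set.seed(31)
  for (rep in 1:10) {
    a <- matrix(runif(12, 0, 10), 4, 3)
    if (svd(scale(a, scale = FALSE))$d[2] < 0.5) next
    perm <- sample(4)
    t0 <- RigidTransform(rotationMatrix(rnorm(3), runif(1, 5, 170)),
                         rnorm(3, 0, 20))
    b <- applyTransform(t0, a)[perm, ]
    fa <- FiducialSet(a, rep(0.5, 4), frame = "CBCT")
    fb <- FiducialSet(b, rep(0.5, 4), frame = "OCT")
    corr <- matchFiducials(fa, fb)
    # pairs map a's index i to b's row holding the same physical marker
    expect_equal(order(perm), corr@pairs[, 2][corr@pairs[, 1]])
    expect_lt(corr@residualMm, 1e-9)
  }
})

test_that("matching agrees with independent brute-force enumeration", {
  skip_if_not_installed("e1071")
  set.seed(77)
  nOk <- 0
  while (nOk < 50) {
    a <- matrix(runif(12, 0, 8), 4, 3)
    b <- matrix(runif(12, 0, 8), 4, 3)
    # independent oracle: enumerate all 4! labelings via e1071
    perms <- e1071::permutations(4)
    Da <- as.matrix(dist(a)); Db <- as.matrix(dist(b))
    oracleCosts <- apply(perms, 1, function(p) sum((Da - Db[p, p])^2) / 2)
    o <- sort(oracleCosts)
    if (o[2] - o[1] < 1e-5) next   # skip near-ambiguous draws
    nOk <- nOk + 1
    oracleBest <- perms[which.min(oracleCosts), ]
    corr <- matchFiducials(FiducialSet(a, rep(0.5, 4)),
                           FiducialSet(b, rep(0.5, 4)))
    expect_equal(as.integer(corr@pairs[, 2]), as.integer(oracleBest))
    expect_equal(corr@residualMm, sqrt(min(oracleCosts) / 6),
                 tolerance = 1e-12)
  }
})

test_that("symmetric configurations raise an ambiguity error", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  fa <- FiducialSet(sq, rep(0.5, 4))
  fb <- FiducialSet(sq + 5, rep(0.5, 4))
  expect_error(matchFiducials(fa, fb), class = "lasernav_ambiguity_error")
})

test_that("matching is invariant under rigid motion of either set", {
  set.seed(13)
  a <- matrix(runif(12, 0, 10), 4, 3)
  b <- a[c(3, 1, 4, 2), ]
  base <- matchFiducials(FiducialSet(a, rep(0.5, 4)),
                         FiducialSet(b, rep(0.5, 4)))
  for (rep in 1:5) {
    t0 <- RigidTransform(rotationMatrix(rnorm(3), runif(1, 0, 180)),
                         rnorm(3, 0, 10))
    moved <- matchFiducials(
      FiducialSet(applyTransform(t0, a), rep(0.5, 4)),
      FiducialSet(b, rep(0.5, 4)))
    expect_identical(moved@pairs, base@pairs)
    expect_equal(moved@residualMm, base@residualMm, tolerance = 1e-9)
  }
})

test_that("CBCT localization error grows with imaging noise", {
  sds <- c(0, 10, 20, 40, 80)
  meanErr <- vapply(sds, function(sd) {
    errs <- vapply(1:10, function(i) {
      spec <- studyPhantomSpec(seed = 100 + i,
                               noise = NoiseSpec(cbctGaussianSd = sd,
                                                 octSpeckleScale = 0))
      ph <- makeCbctPhantom(spec)
      fid <- detectSpheresCbct(ph$volume, 1.0, 4L)
      mean(sqrt(rowSums((sortByX(fiducialCenters(fid)) -
                           sortByX(ph$truth@fiducialCentersCbct))^2)))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_gte(cor(sds, meanErr, method = "spearman"), 0)
})
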