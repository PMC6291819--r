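# Canal segmentation and V-shaped target placement.

test_that("segmentation overlaps the ground-truth canal at Dice >= 0.90", {
  ph <- makeCbctPhantom(noisySpec(seed = 4))
  mask <- segmentCanal(ph$volume)
  expect_gte(diceOverlap(mask@mask, ph$truth@canalMask), 0.90)
})

test_that("segmentation of a uniform volume fails loudly", {
  flat <- Volume3D(array(500, c(20, 20, 20)), 0.3, modality = "CBCT")
  expect_error(segmentCanal(flat), class = "lasernav_segmentation_error")
})

test_that("segmented volume scales with canal radius as the analytic volume", {
  # straight canal (collinear arms) so there is no V-junction overlap; the
  # generated tube is a capsule, so the analytic oracle is
  # pi r^2 L + 4/3 pi r^3 and the dominant r^2 term drives the ~4x growth
  straight <- defaultCanal()
  straight$armAngleDeg <- 90
  wide <- straight
  wide$radiusMm <- 2 * straight$radiusMm
  v1 <- sum(segmentCanal(makeCbctPhantom(
    noisySpec(seed = 6, canal = straight))$volume)@mask)
  v2 <- sum(segmentCanal(makeCbctPhantom(
    noisySpec(seed = 6, canal = wide))$volume)@mask)
  capsule <- function(r, L) pi * r^2 * L + 4 / 3 * pi * r^3
  L <- 2 * straight$armLengthMm
  want <- capsule(wide$radiusMm, L) / capsule(straight$radiusMm, L)
  expect_gt(want, 4)               # r^2 scaling plus the end caps
  expect_lt(abs(v2 / v1 / want - 1), 0.10)
})

test_that("a straight tube under a flat surface yields two parallel edge lines", {
  dims <- c(40L, 40L, 40L)
  sp <- rep(0.3, 3)
  org <- rep(0.15, 3)
  flat <- list(center = c(6, 6), coef = c(9, 0, 0, 0, 0, 0), bump = NULL)
  r <- 0.7
  x0 <- 6.15   # a voxel center, so the silhouette edges sit on the grid
  # tube spans past the grid so no rounded tube end lies inside the mask
  axis <- cbind(x0, seq(-2, 14, by = 0.25), 7)
  mask <- array(FALSE, dims)
  idx <- which(!mask, arr.ind = TRUE)
  pts <- sweep((idx - 1) %*% diag(sp), 2, -org)
  d <- lasernav:::pointPolylineDistance(pts, axis)
  mask[idx[d <= r, , drop = FALSE]] <- TRUE
  sm <- new("SegmentationMask", mask = mask, spacing = sp, origin = org,
            structure = "IAC")
  plan <- placeTargets(sm, flat, viewDir = c(0, 0, 1), spacingMm = 0.5,
                       medialDir = c(0, 1, 0))
  p <- planPoints(plan)
  # two lines at x = x0 - r and x = x0 + r, one CBCT voxel of slack
  expect_true(all(abs(abs(p[, 1] - x0) - r) <= sp[1] + 1e-9))
  sides <- split(p[, 1], p[, 1] > x0)
  expect_length(sides, 2L)
  expect_equal(abs(mean(sides[[1]]) - mean(sides[[2]])), 2 * r,
               tolerance = sp[1])
  # every point lies on the surface, normals are vertical
  expect_equal(p[, 3], rep(9, nrow(p)), tolerance = 1e-9)
  expect_equal(planNormals(plan)[, 3], rep(1, nrow(p)), tolerance = 1e-12)
})

test_that("the ordered plan has exactly one apex (a V, not a zig-zag)", {
  ph <- makeCbctPhantom(noisySpec(seed = 4))
  mask <- segmentCanal(ph$volume)
  plan <- placeTargets(mask, ph$truth@surface)
  u <- planPoints(plan)[, 2]          # medial coordinate
  s <- sign(diff(u))
  s <- s[s != 0]
  expect_equal(sum(diff(s) != 0), 1L)
  # the apex sits at the medial end
  expect_gt(u[which.max(u)], mean(u))
})

test_that("plan matches an independent per-voxel silhouette projection", {
  ph <- makeCbctPhantom(noisySpec(seed = 4))
  mask <- segmentCanal(ph$volume)
  spacing <- 0.5
  plan <- placeTargets(mask, ph$truth@surface, spacingMm = spacing)
  # oracle: project every mask voxel to (u, v) = (y, -x), take the extreme
  # v per u-bin, lift vertically to the surface
  idx <- which(mask@mask, arr.ind = TRUE)
  pts <- sweep((idx - 1) %*% diag(mask@spacing), 2, -mask@origin)
  u <- pts[, 2]; v <- -pts[, 1]
  bins <- floor(u / max(mask@spacing))
  oracle <- do.call(rbind, lapply(split(seq_along(u), bins), function(sel) {
    lo <- sel[which.min(v[sel])]
    hi <- sel[which.max(v[sel])]
    rbind(pts[lo, ], pts[hi, ])
  }))
  oracle[, 3] <- heightfieldHeight(ph$truth@surface, oracle[, 1],
                                   oracle[, 2])
  # every oracle edge point is near the resampled plan: half the plan
  # spacing plus the projection bin quantization
  expect_lt(maxNNDist(oracle, planPoints(plan)),
            spacing / 2 + max(mask@spacing))
})

test_that("planned points avoid the canal and its silhouette is invariant to in-plane rotation", {
  ph <- makeCbctPhantom(noisySpec(seed = 4))
  mask <- segmentCanal(ph$volume)
  plan <- placeTargets(mask, ph$truth@surface)
  idx <- round(sweep(planPoints(plan), 2, mask@origin) %*%
                 diag(1 / mask@spacing)) + 1
  expect_false(any(mask@mask[idx]))

  # 90-degree in-plane rotation of mask and medial direction together,
  # under a flat (rotation-invariant) surface
  dims <- dim(mask@mask)
  flat <- list(center = c(0, 0), coef = c(9, 0, 0, 0, 0, 0), bump = NULL)
  rot <- aperm(mask@mask, c(2, 1, 3))[, dims[1]:1, ]   # (x,y) -> (y, W - x)
  smA <- new("SegmentationMask", mask = mask@mask, spacing = mask@spacing,
             origin = mask@origin, structure = "IAC")
  smB <- new("SegmentationMask", mask = rot, spacing = mask@spacing,
             origin = mask@origin, structure = "IAC")
  pA <- planPoints(placeTargets(smA, flat, medialDir = c(0, 1, 0)))
  pB <- planPoints(placeTargets(smB, flat, medialDir = c(1, 0, 0)))
  W <- dims[1] * mask@spacing[1]
  pBback <- cbind(W - pB[, 2], pB[, 1], pB[, 3])     # undo the rotation
  expect_lt(max(maxNNDist(pA, pBback), maxNNDist(pBback, pA)), 1e-6)
})

test_that("an empty canal projection raises a planning error", {
  sm <- new("SegmentationMask", mask = array(FALSE, c(5, 5, 5)),
            spacing = rep(0.3, 3), origin = rep(0.15, 3), structure = "IAC")
  expect_error(placeTargets(sm, defaultBoneSurface()),
               class = "lasernav_planning_error")
})
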