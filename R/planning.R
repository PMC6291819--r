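# Planning: canal segmentation in the CBCT volume and placement of the
# V-shaped target points on the bone surface above the canal edge.

# 6-neighbour binary dilation / erosion by array shifts (one step).
dilate6 <- function(mask) {
  out <- mask
  d <- dim(mask)
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

erode6 <- function(mask) !dilate6(!mask)

#' Segment the canal in a CBCT volume
#'
#' Band thresholding (`low < I < high` selects the canal's soft-tissue
#' intensity between air and bone), morphological closing (6-neighbour
#' dilation then erosion) to fill noise holes, then the largest connected
#' component. Re-implements interactive workstation segmentation as a
#' reproducible rule.
#'
#' @param vol a CBCT [Volume3D-class].
#' @param low,high intensity band limits.
#' @param structure label for the mask (`"IAC"` or `"inner_ear"`).
#' @return A [SegmentationMask-class] aligned to `vol`.
#' @export
segmentCanal <- function(vol, low = 75, high = 275, structure = "IAC") {
  stopifnot(modality(vol) == "CBCT")
  v <- volData(vol)
  band <- v > low & v < high
  band <- erode6(dilate6(band))                     # closing
  coords <- which(band, arr.ind = TRUE)
  if (nrow(coords) == 0L)
    segmentationError("segmentation failed: no voxels in the intensity band")
  memb <- gridComponents(coords)
  sizes <- tabulate(memb)
  keep <- memb == which.max(sizes)
  mask <- array(FALSE, dim(v))
  mask[coords[keep, , drop = FALSE]] <- TRUE
  new("SegmentationMask", mask = mask, spacing = volSpacing(vol),
      origin = volOrigin(vol), structure = structure)
}

#' Dice overlap between two masks
#'
#' @param a,b logical arrays of identical shape (or
#'   [SegmentationMask-class] objects).
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceOverlap <- function(a, b) {
  if (methods::is(a, "SegmentationMask")) a <- a@mask
  if (methods::is(b, "SegmentationMask")) b <- b@mask
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Resample a 2-D polyline at fixed arclength spacing (keeps both ends).
resamplePolyline <- function(p, spacing) {
  if (nrow(p) < 2L) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < spacing) return(p[c(1L, nrow(p)), , drop = FALSE])
  at <- seq(0, total, by = spacing)
  if (total - at[length(at)] > spacing / 2) at <- c(at, total)
  cbind(stats::approx(s, p[, 1], xout = at)$y,
        stats::approx(s, p[, 2], xout = at)$y)
}

# Solve for the surface intersection of lines base + s * dir (vectorized
# Newton on the height-field).
surfaceIntersect <- function(surface, base, dir, iterations = 20L) {
  base <- asPointMatrix(base)
  dir <- unitVector(dir)
  s <- rep(0, nrow(base))
  for (it in seq_len(iterations)) {
    p <- base + outer(s, dir)
    f <- p[, 3] - heightfieldHeight(surface, p[, 1], p[, 2])
    g <- heightfieldGradient(surface, p[, 1], p[, 2])
    fp <- dir[3] - g$dx * dir[1] - g$dy * dir[2]
    fp[abs(fp) < 0.2] <- sign(fp[abs(fp) < 0.2] + 1e-12) * 0.2
    s <- s - f / fp
  }
  base + outer(s, dir)
}

#' Place target points above the canal edge
#'
#' Operationalizes marking "directly above the canal edge in the surgeon's
#' line of sight": the canal mask is projected along the view direction,
#' the two silhouette edges (minimum and maximum transverse coordinate per
#' station along the medial axis) are extracted, lifted to the bone surface
#' along the view direction, and ordered as a single path - one arm from
#' lateral to the medial apex, the other arm back out (the V).
#'
#' @param mask a [SegmentationMask-class] of the canal.
#' @param surface bone-surface height-field parameter list.
#' @param viewDir unit 3-vector, outward line of sight; must be within 60
#'   degrees of the mean surface normal.
#' @param spacingMm target spacing along each arm, mm.
#' @param medialDir direction (3-vector, need not be unit) pointing toward
#'   the medial apex; its projection into the view plane orders the
#'   stations.
#' @param label plan label.
#' @return A [TargetPlan-class].
#' @export
placeTargets <- function(mask, surface, viewDir = c(0, 0, 1),
                         spacingMm = 0.5, medialDir = c(0, 1, 0),
                         label = "IAC-edge-V") {
  viewDir <- unitVector(viewDir)
  coords <- which(mask@mask, arr.ind = TRUE)
  if (nrow(coords) == 0L)
    planningError("planning failed: canal mask is empty")
  pts <- sweep((coords - 1) %*% diag(mask@spacing), 2, -mask@origin)
  # mean surface normal over the canal footprint
  nbar <- colMeans(heightfieldNormal(surface, pts[, 1], pts[, 2]))
  nbar <- unitVector(nbar)
  if (sum(nbar * viewDir) < cos(60 * pi / 180))
    planningError("view direction is more than 60 degrees off the surface")
  e1 <- medialDir - sum(medialDir * viewDir) * viewDir
  if (sqrt(sum(e1^2)) < 1e-6)
    planningError("medialDir is parallel to the view direction")
  e1 <- unitVector(e1)
  e2 <- c(viewDir[2] * e1[3] - viewDir[3] * e1[2],
          viewDir[3] * e1[1] - viewDir[1] * e1[3],
          viewDir[1] * e1[2] - viewDir[2] * e1[1])
  u <- drop(pts %*% e1)
  v <- drop(pts %*% e2)
  binW <- max(mask@spacing)
  bins <- round(u / binW)
  ub <- sort(unique(bins))
  edges <- t(vapply(ub, function(b) {
    sel <- bins == b
    c(mean(u[sel]), min(v[sel]), max(v[sel]))
  }, numeric(3)))
  # two silhouette edges, resampled at spacingMm along their arclength:
  # min-edge lateral -> medial, then max-edge medial -> lateral (the V)
  armA <- resamplePolyline(edges[, c(1, 2)], spacingMm)
  armB <- resamplePolyline(edges[rev(seq_len(nrow(edges))), c(1, 3),
                                 drop = FALSE], spacingMm)
  uv <- rbind(armA, armB)
  base <- outer(uv[, 1], e1) + outer(uv[, 2], e2)
  onSurface <- surfaceIntersect(surface, base, viewDir)
  normals <- heightfieldNormal(surface, onSurface[, 1], onSurface[, 2])
  new("TargetPlan", points = onSurface, normals = normals,
      viewDir = viewDir, label = label)
}
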