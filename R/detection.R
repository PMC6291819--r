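# Fiducial detection: sub-voxel sphere localization in CBCT and OCT
# volumes, and exhaustive distance-pattern correspondence matching.

# Connected components of integer grid coordinates (n x 2 or n x 3 matrix)
# under Chebyshev-1 adjacency, via igraph on the voxel adjacency graph.
gridComponents <- function(coords) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  nd <- ncol(coords)
  span <- apply(coords, 2, max) + 1L
  mult <- cumprod(c(1, span[-nd]))
  lin <- as.numeric(coords %*% mult)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  keep <- rowSums(abs(offs)) > 0
  offs <- offs[keep, , drop = FALSE]
  # half the offsets suffice for an undirected graph
  first <- apply(offs, 1, function(o) o[which(o != 0)[1]] > 0)
  offs <- offs[first, , drop = FALSE]
  ord <- order(lin)
  sortedLin <- lin[ord]
  edges <- NULL
  for (i in seq_len(nrow(offs))) {
    nlin <- lin + as.numeric(offs[i, ] %*% mult)
    j <- findInterval(nlin, sortedLin)
    hit <- j > 0 & sortedLin[pmax(j, 1L)] == nlin
    if (any(hit))
      edges <- rbind(edges, cbind(which(hit), ord[j[hit]]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' Detect spherical fiducials in a CBCT volume
#'
#' Thresholds at the titanium level (two-stage Otsu: air/bone first, then
#' bone/titanium on the upper tail), labels connected components, discards
#' components whose equivalent-sphere diameter deviates from the expected
#' diameter by more than 50%, and localizes each survivor by the
#' intensity-weighted centroid over the component dilated by two voxels.
#' Because fiducials are rendered (and physically mounted) clear of the
#' bone, the centroid of the partial-volume intensity profile is an
#' unbiased sub-voxel estimate of the sphere center.
#'
#' @param vol a CBCT [Volume3D-class].
#' @param expectedDiameterMm nominal marker diameter, mm.
#' @param nExpected number of markers the caller expects; detection never
#'   pads, but surplus detections are trimmed to the best-quality
#'   `nExpected` with a warning.
#' @param weightFloorFrac centroid weights are `max(I - floor, 0)` with
#'   `floor = weightFloorFrac *` the titanium threshold; suppresses noise
#'   in the dilated window.
#' @return A [FiducialSet-class] (frame `"CBCT"`); `quality` reflects how
#'   close each component's equivalent diameter is to the expected one.
#' @export
detectSpheresCbct <- function(vol, expectedDiameterMm = 1.0, nExpected = 4L,
                              weightFloorFrac = 0.05) {
  stopifnot(modality(vol) == "CBCT")
  v <- volData(vol)
  t1 <- otsuThreshold(v)
  upper <- v[v > t1]
  if (length(upper) < 2L)
    insufficientError("fewer than 3 fiducials found (no titanium-level voxels)")
  t2 <- otsuThreshold(upper)
  mask <- v > t2
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L)
    insufficientError("fewer than 3 fiducials found (no titanium-level voxels)")
  memb <- gridComponents(coords)
  voxVol <- prod(volSpacing(vol))
  wf <- weightFloorFrac * t2
  dims <- dim(v)
  res <- lapply(seq_len(max(memb)), function(ci) {
    cc <- coords[memb == ci, , drop = FALSE]
    dEq <- 2 * (3 * nrow(cc) * voxVol / (4 * pi))^(1 / 3)
    if (abs(dEq - expectedDiameterMm) > 0.5 * expectedDiameterMm)
      return(NULL)
    # dilate by 2 voxels (Chebyshev) to recover sub-threshold partial voxels
    offs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
    win <- unique(cc[rep(seq_len(nrow(cc)), each = nrow(offs)), , drop = FALSE] +
                    offs[rep(seq_len(nrow(offs)), times = nrow(cc)), ])
    ok <- win[, 1] >= 1 & win[, 2] >= 1 & win[, 3] >= 1 &
      win[, 1] <= dims[1] & win[, 2] <= dims[2] & win[, 3] <= dims[3]
    win <- win[ok, , drop = FALSE]
    w <- pmax(v[win] - wf, 0)
    world <- sweep((win - 1) %*% diag(volSpacing(vol)), 2, -volOrigin(vol))
    list(center = colSums(world * w) / sum(w), dEq = dEq,
         quality = 1 - min(1, abs(dEq - expectedDiameterMm) /
                             expectedDiameterMm))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) < 3L)
    insufficientError(sprintf(
      "fewer than 3 fiducials found (%d plausible component(s))",
      length(res)))
  qual <- vapply(res, `[[`, numeric(1), "quality")
  if (length(res) > nExpected) {
    warning(sprintf("found %d candidate fiducials, keeping the %d best",
                    length(res), nExpected))
    res <- res[order(qual, decreasing = TRUE)[seq_len(nExpected)]]
    qual <- vapply(res, `[[`, numeric(1), "quality")
  }
  centers <- do.call(rbind, lapply(res, `[[`, "center"))
  FiducialSet(centers, radii = rep(expectedDiameterMm / 2, nrow(centers)),
              quality = qual, frame = "CBCT")
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud. With `radius = NULL` the radius is free:
#' an algebraic (linear) fit followed by Gauss-Newton refinement of the
#' geometric residuals. With a known radius only the center is estimated,
#' which is the stable choice when only a partial cap of the surface is
#' visible.
#'
#' @param points n x 3 matrix, mm.
#' @param radius known sphere radius (mm) or `NULL` for a free-radius fit.
#' @return List with `center`, `radius` and `rms` (RMS of
#'   `| ||p - c|| - r |`, mm).
#' @export
fitSphere <- function(points, radius = NULL) {
  p <- asPointMatrix(points)
  if (nrow(p) < 4L) degenerateError("sphere fit needs at least 4 points")
  if (is.null(radius)) {
    A <- cbind(2 * p, 1)
    b <- rowSums(p^2)
    sol <- qr.solve(A, b)
    ctr <- sol[1:3]
    r <- sqrt(max(sol[4] + sum(ctr^2), 1e-12))
    for (it in seq_len(60L)) {
      d <- sweep(p, 2, ctr)
      nd <- rowNorms(d)
      res <- nd - r
      U <- cbind(-d / nd, -1)
      step <- tryCatch(qr.solve(crossprod(U), crossprod(U, res)),
                       error = function(e) NULL)
      if (is.null(step)) break
      ctr <- ctr - step[1:3]
      r <- r - step[4]
      if (max(abs(step)) < 1e-13) break
    }
  } else {
    r <- radius
    ctr <- c(mean(p[, 1]), mean(p[, 2]), max(p[, 3]) - r)
    for (it in seq_len(80L)) {
      d <- sweep(p, 2, ctr)
      nd <- pmax(rowNorms(d), 1e-9)
      res <- nd - r
      U <- -d / nd
      step <- tryCatch(qr.solve(crossprod(U), crossprod(U, res)),
                       error = function(e) NULL)
      if (is.null(step)) break
      ctr <- ctr - step
      if (max(abs(step)) < 1e-13) break
    }
  }
  d <- sweep(p, 2, ctr)
  list(center = as.numeric(ctr), radius = r,
       rms = sqrt(mean((rowNorms(d) - r)^2)))
}

#' Detect spherical fiducials in an OCT volume
#'
#' Titanium spheres appear in OCT only as their upper caps. The detector
#' extracts a sub-voxel surface height per A-scan column (intensity-weighted
#' centroid around the topmost above-threshold voxel), separates
#' strong-reflectance (cap) columns from bone columns by Otsu on the peak
#' intensities, clusters cap columns laterally, and fits a sphere of known
#' radius to each cluster's cap points by least squares. Clusters that
#' subtend too small a lateral extent for a stable fit are dropped with a
#' warning.
#'
#' @param vol an OCT [Volume3D-class].
#' @param expectedDiameterMm nominal marker diameter, mm.
#' @param nExpected expected marker count (surplus trimmed with a warning).
#' @param fitRadius `"known"` (default; radius fixed at
#'   `expectedDiameterMm / 2`) or `"free"` (radius estimated too).
#' @param minClusterSize minimum cap columns per cluster; smaller clusters
#'   are speckle and are ignored.
#' @return A [FiducialSet-class] (frame `"OCT"`); `quality` is
#'   `max(0, 1 - 2 * rms / r)` from the fit residual.
#' @export
detectSpheresOct <- function(vol, expectedDiameterMm = 1.0, nExpected = 4L,
                             fitRadius = c("known", "free"),
                             minClusterSize = 8L) {
  stopifnot(modality(vol) == "OCT")
  fitRadius <- match.arg(fitRadius)
  r <- expectedDiameterMm / 2
  v <- volData(vol)
  dims <- dim(v)
  nl1 <- dims[1]; nl2 <- dims[2]; na <- dims[3]
  M <- matrix(v, nl1 * nl2, na)
  colmax <- do.call(pmax, as.data.frame(M))
  if (max(colmax) <= 0)
    insufficientError("no signal in OCT volume")
  thrSurf <- 0.25 * stats::median(colmax[colmax > 1e-6 * max(colmax)])
  valid <- colmax > thrSurf
  L <- M > thrSurf
  km <- na + 1L - max.col(L[, na:1, drop = FALSE], ties.method = "first")
  # peak measure robust to the sampling phase of the surface: the maximum
  # adjacent-pair sum along the column (constant for the cap band)
  M2 <- M[, -na, drop = FALSE] + M[, -1, drop = FALSE]
  P <- ifelse(valid, do.call(pmax, as.data.frame(M2)), NA_real_)
  pv <- P[valid]
  # bone and cap columns are bimodal in peak intensity; a cap-only view
  # (e.g. a close-up of a single marker with no bone in range) is unimodal
  # and every valid column belongs to a cap
  if (max(pv) / max(stats::median(pv), 1e-12) >= 1.8) {
    bright <- valid & P > otsuThreshold(pv)
  } else {
    bright <- valid
  }
  idx <- which(bright)
  if (length(idx) == 0L)
    insufficientError("no strong-reflectance cap columns found")
  ij <- cbind((idx - 1L) %% nl1 + 1L, (idx - 1L) %/% nl1 + 1L)
  # sub-voxel surface height: intensity-weighted centroid over the band
  # below the topmost above-threshold voxel
  zs <- volOrigin(vol)[3] + (0:(na - 1L)) * volSpacing(vol)[3]
  ki <- km[idx]
  sw <- numeric(length(idx)); swz <- numeric(length(idx))
  for (o in 0:4) {
    k <- pmax(ki - o, 1L)
    w <- M[cbind(idx, k)]
    sw <- sw + w
    swz <- swz + w * zs[k]
  }
  zhat <- swz / sw
  pts <- cbind(volOrigin(vol)[1] + (ij[, 1] - 1L) * volSpacing(vol)[1],
               volOrigin(vol)[2] + (ij[, 2] - 1L) * volSpacing(vol)[2],
               zhat)
  memb <- gridComponents(ij)
  fits <- list()
  for (ci in seq_len(max(memb))) {
    sel <- memb == ci
    if (sum(sel) < minClusterSize) next
    cp <- pts[sel, , drop = FALSE]
    extent <- max(diff(range(cp[, 1])), diff(range(cp[, 2])))
    if (extent < 0.6 * r) {
      warning("dropping a cap cluster with too small a lateral extent ",
              "for a stable sphere fit")
      next
    }
    fit <- fitSphere(cp, radius = if (fitRadius == "known") r else NULL)
    fits[[length(fits) + 1L]] <-
      list(center = fit$center, radius = fit$radius,
           quality = max(0, 1 - 2 * fit$rms / r))
  }
  if (length(fits) == 0L)
    insufficientError("no stable cap fits in OCT volume")
  qual <- vapply(fits, `[[`, numeric(1), "quality")
  if (length(fits) > nExpected) {
    warning(sprintf("found %d candidate fiducials, keeping the %d best",
                    length(fits), nExpected))
    keep <- order(qual, decreasing = TRUE)[seq_len(nExpected)]
    fits <- fits[keep]; qual <- qual[keep]
  }
  FiducialSet(do.call(rbind, lapply(fits, `[[`, "center")),
              radii = vapply(fits, `[[`, numeric(1), "radius"),
              quality = qual, frame = "OCT")
}

#' Match fiducials between two frames by their distance pattern
#'
#' Inter-marker distances are invariant under rigid motion, so the correct
#' labeling is the injective assignment whose inter-point distance matrix
#' best matches. With at most 6 markers the exhaustive search over all
#' assignments is exact. Two assignments within 1e-6 mm^2 of the same cost
#' mean the arrangement is (near-)symmetric and the labeling is ambiguous;
#' this raises an error rather than guessing, because a navigation system
#' must never silently pick a wrong labeling.
#'
#' @param a,b [FiducialSet-class] objects with the same number (3-6) of
#'   markers.
#' @return A [Correspondence-class]; `pairs[, 1]` indexes `a`, `pairs[, 2]`
#'   indexes `b`, and `residualMm` is the RMS discrepancy of corresponding
#'   inter-point distances.
#' @export
matchFiducials <- function(a, b) {
  pa <- fiducialCenters(a); pb <- fiducialCenters(b)
  n <- nrow(pa)
  if (n < 3L || nrow(pb) < 3L)
    insufficientError("matching requires at least 3 fiducials in each set")
  if (nrow(pb) != n)
    insufficientError("fiducial sets have different sizes")
  if (n > 6L)
    configError("exhaustive matching supports at most 6 fiducials")
  Da <- as.matrix(stats::dist(pa))
  Db <- as.matrix(stats::dist(pb))
  perms <- allPermutations(n)
  costs <- vapply(seq_len(nrow(perms)), function(i) {
    p <- perms[i, ]
    sum((Da - Db[p, p])^2) / 2
  }, numeric(1))
  o <- order(costs)
  if (nrow(perms) > 1L && costs[o[2]] - costs[o[1]] < 1e-6)
    ambiguityError(
      "ambiguous correspondence: two labelings fit the distance pattern")
  best <- perms[o[1], ]
  nPairs <- n * (n - 1) / 2
  new("Correspondence", pairs = unname(cbind(seq_len(n), unname(best))),
      residualMm = sqrt(costs[o[1]] / nPairs))
}
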