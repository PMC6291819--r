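# Generics, accessors and show methods.

#' Apply a transform to points or objects
#'
#' @param transform a [RigidTransform-class].
#' @param x an n x 3 point matrix (mm), a numeric 3-vector, or an object
#'   with a point-set method (e.g. [TargetPlan-class]).
#' @return Transformed object of the same shape/class.
#' @export
setGeneric("applyTransform", function(transform, x)
  standardGeneric("applyTransform"))

#' Volume accessors
#'
#' `volData()`, `volSpacing()`, `volOrigin()` and `modality()` read the
#' image array and its world geometry; `indexToWorldMatrix()` returns the
#' 4 x 4 homogeneous affine mapping 0-based voxel indices (voxel-center
#' convention) to world mm.
#'
#' @param object a [Volume3D-class].
#' @return The requested component.
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname volData
#' @export
setGeneric("volSpacing", function(object) standardGeneric("volSpacing"))
#' @rdname volData
#' @export
setGeneric("volOrigin", function(object) standardGeneric("volOrigin"))
#' @rdname volData
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname volData
#' @export
setGeneric("indexToWorldMatrix", function(object)
  standardGeneric("indexToWorldMatrix"))

#' Point-set accessors
#'
#' @param object a [FiducialSet-class] or [TargetPlan-class].
#' @return `fiducialCenters()`/`planPoints()` return n x 3 matrices (mm);
#'   `fiducialRadii()` and `fiducialQuality()` numeric vectors;
#'   `planNormals()` an n x 3 matrix of unit normals.
#' @export
setGeneric("fiducialCenters", function(object)
  standardGeneric("fiducialCenters"))
#' @rdname fiducialCenters
#' @export
setGeneric("fiducialRadii", function(object)
  standardGeneric("fiducialRadii"))
#' @rdname fiducialCenters
#' @export
setGeneric("fiducialQuality", function(object)
  standardGeneric("fiducialQuality"))
#' @rdname fiducialCenters
#' @export
setGeneric("planPoints", function(object) standardGeneric("planPoints"))
#' @rdname fiducialCenters
#' @export
setGeneric("planNormals", function(object) standardGeneric("planNormals"))

setMethod("volData", "Volume3D", function(object) object@data)
setMethod("volSpacing", "Volume3D", function(object) object@spacing)
setMethod("volOrigin", "Volume3D", function(object) object@origin)
setMethod("modality", "Volume3D", function(object) object@modality)
setMethod("indexToWorldMatrix", "Volume3D", function(object) {
  m <- diag(4)
  diag(m)[1:3] <- object@spacing
  m[1:3, 4] <- object@origin
  m
})

setMethod("fiducialCenters", "FiducialSet", function(object) object@centers)
setMethod("fiducialRadii", "FiducialSet", function(object) object@radii)
setMethod("fiducialQuality", "FiducialSet", function(object) object@quality)
setMethod("planPoints", "TargetPlan", function(object) object@points)
setMethod("planNormals", "TargetPlan", function(object) object@normals)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D [%s] %d x %d x %d voxels, spacing %s mm\n",
              object@modality, d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, intensity range [%.3g, %.3g]\n",
              paste(signif(object@origin, 4), collapse = ", "),
              min(object@data), max(object@data)))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (world mm)\n  rotation:\n")
  print(signif(object@rotation, 6))
  cat("  translation:", paste(signif(object@translation, 6), collapse = ", "),
      "\n")
})

setMethod("show", "FiducialSet", function(object) {
  cat(sprintf("FiducialSet [%s]: %d marker(s)\n", object@frame,
              nrow(object@centers)))
  if (nrow(object@centers)) {
    df <- data.frame(signif(object@centers, 6),
                     r_mm = signif(object@radii, 4),
                     quality = signif(object@quality, 3))
    names(df)[1:3] <- c("x_mm", "y_mm", "z_mm")
    print(df)
  }
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf(
    "RegistrationResult: %d fiducials, FRE %.4g mm (mean residual %.4g mm)\n",
    object@nFiducials, object@freMm, object@meanResidualMm))
})

setMethod("show", "TargetPlan", function(object) {
  cat(sprintf("TargetPlan '%s': %d point(s), view (%s)\n", object@label,
              nrow(object@points),
              paste(signif(object@viewDir, 3), collapse = ", ")))
})

setMethod("show", "AccuracyReport", function(object) {
  nerr <- length(unlist(object@perTargetErrorsMm))
  cat(sprintf(
    paste0("AccuracyReport: %d replicate(s), %d failed, %d pooled target",
           " error(s)\n  mean %.4g mm | RMS %.4g mm | max %.4g mm\n"),
    object@nReplicates, object@nFailed, nerr,
    object@meanMm, object@rmsMm, object@maxMm))
})
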