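# S4 class definitions. Conventions used throughout the package:
#  * world coordinates are right-handed, in mm;
#  * voxel indices are 0-based and index_to_world maps an index to the
#    CENTER of its voxel;
#  * volumes are axis-aligned (index_to_world = diag(spacing) + origin).

#' RigidTransform: rotation + translation in mm
#'
#' A proper rigid transform `x -> R x + t` between two world frames
#' (CBCT and laser/OCT). The rotation must be orthonormal with
#' determinant +1; reflections are rejected.
#'
#' @slot rotation 3 x 3 orthonormal matrix, det +1.
#' @slot translation numeric 3-vector, mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
    if (length(object@translation) != 3L) return("translation must have length 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-10)
      return("rotation is not orthonormal (||R'R - I|| > 1e-10)")
    if (det(R) <= 0) return("rotation has non-positive determinant (reflection)")
    TRUE
  })

setClassUnion("RigidTransformOrNULL", c("RigidTransform", "NULL"))

#' @describeIn RigidTransform-class Constructor.
#' @param rotation 3 x 3 orthonormal matrix.
#' @param translation numeric 3-vector (mm).
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Volume3D: a 3-D scalar image with world geometry
#'
#' Carries both CBCT and OCT data. The index-to-world mapping is
#' axis-aligned: `world = origin + index * spacing` with 0-based indices
#' addressing voxel centers.
#'
#' @slot data 3-D numeric array.
#' @slot spacing numeric 3-vector, voxel edge lengths in mm (all > 0).
#' @slot origin numeric 3-vector, world position (mm) of voxel (0,0,0).
#' @slot modality `"CBCT"` or `"OCT"`.
#' @export
setClass("Volume3D",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 modality = "character"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 strictly positive values")
    if (length(object@origin) != 3L) return("origin must have length 3")
    if (!object@modality %in% c("CBCT", "OCT"))
      return("modality must be 'CBCT' or 'OCT'")
    TRUE
  })

#' @describeIn Volume3D-class Constructor.
#' @param data 3-D numeric array.
#' @param spacing numeric 3-vector (mm).
#' @param origin numeric 3-vector (mm); default places voxel (0,0,0) at 0.
#' @param modality `"CBCT"` or `"OCT"`.
#' @export
Volume3D <- function(data, spacing, origin = c(0, 0, 0), modality = "CBCT") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality)
}

#' NoiseSpec: imaging-noise parameters for the phantom generator
#'
#' @slot cbctGaussianSd additive Gaussian noise SD, CBCT intensity units.
#' @slot octSpeckleScale dimensionless log-scale of multiplicative
#'   (log-normal, mean-one) OCT speckle.
#' @slot octPenetrationBoneMm imaging depth below the bone surface (mm);
#'   deeper voxels carry no signal.
#' @slot octAttenuationPerMm exponential signal attenuation per mm of bone.
#' @export
setClass("NoiseSpec",
  representation(cbctGaussianSd = "numeric", octSpeckleScale = "numeric",
                 octPenetrationBoneMm = "numeric",
                 octAttenuationPerMm = "numeric"),
  prototype(cbctGaussianSd = 20, octSpeckleScale = 0.2,
            octPenetrationBoneMm = 1.0, octAttenuationPerMm = 2.0),
  validity = function(object) {
    vals <- c(object@cbctGaussianSd, object@octSpeckleScale,
              object@octPenetrationBoneMm, object@octAttenuationPerMm)
    if (any(vals < 0)) return("all noise parameters must be >= 0")
    if (object@octPenetrationBoneMm <= 0)
      return("octPenetrationBoneMm must be > 0")
    TRUE
  })

#' @describeIn NoiseSpec-class Constructor with study defaults.
#' @param cbctGaussianSd,octSpeckleScale,octPenetrationBoneMm,octAttenuationPerMm
#'   see slot documentation.
#' @export
NoiseSpec <- function(cbctGaussianSd = 20, octSpeckleScale = 0.2,
                      octPenetrationBoneMm = 1.0, octAttenuationPerMm = 2.0) {
  new("NoiseSpec", cbctGaussianSd = cbctGaussianSd,
      octSpeckleScale = octSpeckleScale,
      octPenetrationBoneMm = octPenetrationBoneMm,
      octAttenuationPerMm = octAttenuationPerMm)
}

#' PhantomSpec: geometry and imaging parameters of the synthetic specimen
#'
#' Describes one simulated middle-fossa specimen: a bone slab bounded above
#' by a smooth height-field surface, a buried canal (the internal auditory
#' canal surrogate) running as a V-shaped tube at fixed depth below the
#' surface, and spherical titanium fiducial markers mounted proud of the
#' surface near the craniotomy edge.
#'
#' @slot cbctVoxelMm isotropic CBCT voxel size, mm (default 0.3).
#' @slot cbctFovMm CBCT field-of-view cube side, mm.
#' @slot octLateralMm,octAxialMm OCT voxel sizes, mm.
#' @slot fovOctMm OCT field-of-view cube side, mm (default 10).
#' @slot nFiducials number of fiducial spheres.
#' @slot fiducialDiameterMm sphere diameter, mm (default 1).
#' @slot fiducialSpacingMm permitted surface-to-surface gap between
#'   consecutive spheres, mm interval (default `c(1, 2)`).
#' @slot fiducialStandoffMm gap between the bone surface and the lowest
#'   point of each mounted sphere, mm.
#' @slot boneSurface height-field parameter list (see [heightfieldHeight()]).
#' @slot canal canal parameter list: `apexXY`, `armAngleDeg`, `armLengthMm`,
#'   `radiusMm`, `depthMm` (top of the tube below the surface).
#' @slot boneZMinMm bottom of the bone slab, mm.
#' @slot intensities named CBCT intensity levels
#'   (`air`, `soft`, `bone`, `titanium`).
#' @slot supersample per-axis supersampling factor for partial-volume
#'   sphere rendering (>= 4 recommended).
#' @slot trueTransform the hidden CBCT-to-laser/OCT [RigidTransform-class],
#'   or `NULL` to draw one from the seed.
#' @slot noise a [NoiseSpec-class].
#' @slot seed integer seed; all stochastic draws for one phantom flow from it.
#' @export
setClass("PhantomSpec",
  representation(cbctVoxelMm = "numeric", cbctFovMm = "numeric",
                 octLateralMm = "numeric", octAxialMm = "numeric",
                 fovOctMm = "numeric", nFiducials = "integer",
                 fiducialDiameterMm = "numeric", fiducialSpacingMm = "numeric",
                 fiducialStandoffMm = "numeric", boneSurface = "list",
                 canal = "list", boneZMinMm = "numeric",
                 intensities = "numeric", supersample = "integer",
                 trueTransform = "RigidTransformOrNULL", noise = "NoiseSpec",
                 seed = "integer"),
  validity = function(object) {
    if (object@cbctVoxelMm <= 0 || object@octLateralMm <= 0 ||
        object@octAxialMm <= 0) return("voxel sizes must be > 0")
    if (object@fovOctMm <= 0 || object@cbctFovMm <= 0)
      return("fields of view must be > 0")
    if (object@nFiducials < 1L) return("nFiducials must be >= 1")
    if (object@fiducialDiameterMm <= 0) return("fiducial diameter must be > 0")
    if (length(object@fiducialSpacingMm) != 2L ||
        object@fiducialSpacingMm[1] <= 0 ||
        diff(object@fiducialSpacingMm) < 0)
      return("fiducialSpacingMm must be an increasing positive interval")
    if (object@fiducialStandoffMm < 0) return("standoff must be >= 0")
    need <- c("air", "soft", "bone", "titanium")
    if (!all(need %in% names(object@intensities)))
      return("intensities must name air, soft, bone, titanium")
    iv <- object@intensities
    if (iv["titanium"] <= iv["bone"] + 6 * object@noise@cbctGaussianSd)
      return("titanium intensity must exceed bone by > 6 noise SDs")
    if (object@supersample < 1L) return("supersample must be >= 1")
    cn <- object@canal
    needc <- c("apexXY", "armAngleDeg", "armLengthMm", "radiusMm", "depthMm")
    if (!all(needc %in% names(cn))) return("canal parameters incomplete")
    if (cn$radiusMm <= 0 || cn$armLengthMm <= 0)
      return("canal radius and arm length must be > 0")
    if (cn$depthMm <= 0)
      return("canal must lie below the bone surface (depthMm > 0)")
    TRUE
  })

#' @describeIn PhantomSpec-class Constructor with defaults mirroring the
#'   study conditions (0.3 mm CBCT voxels, four 1 mm spheres 1-2 mm apart,
#'   10 mm OCT cube).
#' @param cbctVoxelMm,cbctFovMm,octLateralMm,octAxialMm,fovOctMm see slots.
#' @param nFiducials,fiducialDiameterMm,fiducialSpacingMm,fiducialStandoffMm
#'   see slots.
#' @param boneSurface,canal,boneZMinMm,intensities,supersample see slots.
#' @param trueTransform,noise,seed see slots.
#' @export
PhantomSpec <- function(cbctVoxelMm = 0.3,
                        cbctFovMm = 16.8,
                        octLateralMm = 0.03,
                        octAxialMm = 0.03,
                        fovOctMm = 10,
                        nFiducials = 4L,
                        fiducialDiameterMm = 1.0,
                        fiducialSpacingMm = c(1, 2),
                        fiducialStandoffMm = 0.75,
                        boneSurface = defaultBoneSurface(),
                        canal = defaultCanal(),
                        boneZMinMm = 3,
                        intensities = c(air = 0, soft = 150, bone = 400,
                                        titanium = 1200),
                        supersample = 8L,
                        trueTransform = NULL,
                        noise = NoiseSpec(),
                        seed = 1L) {
  new("PhantomSpec", cbctVoxelMm = cbctVoxelMm, cbctFovMm = cbctFovMm,
      octLateralMm = octLateralMm, octAxialMm = octAxialMm,
      fovOctMm = fovOctMm, nFiducials = as.integer(nFiducials),
      fiducialDiameterMm = fiducialDiameterMm,
      fiducialSpacingMm = as.numeric(fiducialSpacingMm),
      fiducialStandoffMm = fiducialStandoffMm, boneSurface = boneSurface,
      canal = canal, boneZMinMm = boneZMinMm, intensities = intensities,
      supersample = as.integer(supersample), trueTransform = trueTransform,
      noise = noise, seed = as.integer(seed))
}

#' GroundTruth: hidden truth behind one phantom
#'
#' Holds the analytic quantities the cadaver study could not observe:
#' exact fiducial centers in both frames, the canal voxel mask, the bone
#' surface model, and the true CBCT-to-laser/OCT transform. By
#' construction `fiducialCentersOct == trueTransform(fiducialCentersCbct)`
#' to machine precision.
#'
#' @slot fiducialCentersCbct n x 3 matrix, mm (CBCT frame).
#' @slot fiducialCentersOct n x 3 matrix, mm (laser/OCT frame).
#' @slot canalMask logical array aligned to the CBCT volume.
#' @slot surface height-field parameter list.
#' @slot trueTransform a [RigidTransform-class].
#' @export
setClass("GroundTruth",
  representation(fiducialCentersCbct = "matrix",
                 fiducialCentersOct = "matrix", canalMask = "array",
                 surface = "list", trueTransform = "RigidTransform"),
  validity = function(object) {
    if (!identical(dim(object@fiducialCentersCbct),
                   dim(object@fiducialCentersOct)))
      return("fiducial center matrices must have identical shape")
    TRUE
  })

#' FiducialSet: localized sphere markers in one frame
#'
#' @slot centers n x 3 matrix of sub-voxel center estimates, mm.
#' @slot radii fitted or assumed sphere radii, mm.
#' @slot quality per-marker quality scores in `[0, 1]`.
#' @slot frame `"CBCT"` or `"OCT"`.
#' @export
setClass("FiducialSet",
  representation(centers = "matrix", radii = "numeric", quality = "numeric",
                 frame = "character"),
  validity = function(object) {
    n <- nrow(object@centers)
    if (ncol(object@centers) != 3L) return("centers must be n x 3")
    if (length(object@radii) != n || length(object@quality) != n)
      return("centers, radii and quality must have equal length")
    if (any(object@radii <= 0)) return("radii must be > 0")
    if (any(object@quality < 0 | object@quality > 1))
      return("quality scores must lie in [0, 1]")
    if (!object@frame %in% c("CBCT", "OCT"))
      return("frame must be 'CBCT' or 'OCT'")
    TRUE
  })

#' @describeIn FiducialSet-class Constructor.
#' @param centers n x 3 matrix (mm).
#' @param radii,quality numeric vectors of length n.
#' @param frame `"CBCT"` or `"OCT"`.
#' @export
FiducialSet <- function(centers, radii, quality = rep(1, nrow(centers)),
                        frame = "CBCT") {
  new("FiducialSet", centers = asPointMatrix(centers),
      radii = as.numeric(radii), quality = as.numeric(quality), frame = frame)
}

#' Correspondence: injective pairing between two fiducial sets
#'
#' @slot pairs m x 2 integer matrix of (index in set A, index in set B).
#' @slot residualMm RMS discrepancy between corresponding inter-point
#'   distances, mm.
#' @export
setClass("Correspondence",
  representation(pairs = "matrix", residualMm = "numeric"),
  validity = function(object) {
    p <- object@pairs
    if (ncol(p) != 2L) return("pairs must be m x 2")
    if (anyDuplicated(p[, 1]) || anyDuplicated(p[, 2]))
      return("pairing must be injective on both sides")
    if (object@residualMm < 0) return("residual must be >= 0")
    TRUE
  })

#' RegistrationResult: rigid fit plus error bookkeeping
#'
#' @slot transform estimated [RigidTransform-class] (moving to fixed).
#' @slot freMm fiducial registration error: RMS of residual norms, mm.
#' @slot meanResidualMm plain mean of residual norms, mm (reported because
#'   the field's headline "mean error" figures rarely state which summary
#'   they use).
#' @slot perFiducialResidualsMm residual norms, mm.
#' @slot nFiducials number of point pairs used.
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", freMm = "numeric",
                 meanResidualMm = "numeric",
                 perFiducialResidualsMm = "numeric", nFiducials = "integer"),
  validity = function(object) {
    r <- object@perFiducialResidualsMm
    if (length(r) != object@nFiducials) return("residual count mismatch")
    if (abs(object@freMm^2 - mean(r^2)) > 1e-12)
      return("freMm^2 must equal mean squared residual")
    TRUE
  })

#' SegmentationMask: labeled voxel mask aligned to a CBCT volume
#'
#' @slot mask logical 3-D array, same shape as the source volume.
#' @slot spacing,origin geometry copied from the source volume.
#' @slot structure `"IAC"` or `"inner_ear"`.
#' @export
setClass("SegmentationMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric",
                 structure = "character"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(dim(object@mask)) != 3L) return("mask must be 3-D")
    if (!object@structure %in% c("IAC", "inner_ear"))
      return("structure must be 'IAC' or 'inner_ear'")
    TRUE
  })

#' TargetPlan: ordered marking points on the bone surface
#'
#' The V-shaped path outlining the canal edge as seen along the surgeon's
#' line of sight: one arm from lateral to the medial apex, the second arm
#' back out.
#'
#' @slot points n x 3 matrix of surface points, mm.
#' @slot normals n x 3 matrix of outward unit surface normals.
#' @slot viewDir unit 3-vector, the line of sight (outward, toward viewer).
#' @slot label free-text label, e.g. `"IAC-edge-V"`.
#' @export
setClass("TargetPlan",
  representation(points = "matrix", normals = "matrix", viewDir = "numeric",
                 label = "character"),
  validity = function(object) {
    if (ncol(object@points) != 3L || ncol(object@normals) != 3L)
      return("points and normals must be n x 3")
    if (nrow(object@points) != nrow(object@normals))
      return("points and normals must align")
    if (nrow(object@points) > 0 &&
        max(abs(rowNorms(object@normals) - 1)) > 1e-9)
      return("normals must be unit length (tol 1e-9)")
    if (abs(sqrt(sum(object@viewDir^2)) - 1) > 1e-9)
      return("viewDir must be a unit vector")
    TRUE
  })

#' LaserConfig: workspace and marking parameters of the cutting laser
#'
#' Defaults follow the reported device behaviour: a 10 mm addressable cube
#' shared with the OCT view, about 0.3 mm of bone removed per ablation
#' cycle, a 4 mm/s focus-spot speed, a 45-90 degree usable incidence
#' range, 15 W at 500 Hz with 50-200 microsecond pulses, and a 60 mm
#' working distance (extendable to 100 mm).
#'
#' @slot workspaceSideMm addressable cube side, mm.
#' @slot workingDistanceMm nominal working distance, mm.
#' @slot maxWorkingDistanceMm extended working distance, mm.
#' @slot depthPerCycleMm bone depth removed per ablation cycle, mm.
#' @slot focusSpeedMmS focus-spot speed, mm/s.
#' @slot incidenceRangeDeg usable angle between surface plane and beam,
#'   degrees.
#' @slot powerW,pulseHz,pulseUs nominal source parameters (bookkeeping
#'   only; the crater model is calibrated by `depthPerCycleMm`).
#' @slot execNoiseSdMm isotropic SD of beam-pointing execution noise, mm
#'   (0 disables).
#' @export
setClass("LaserConfig",
  representation(workspaceSideMm = "numeric", workingDistanceMm = "numeric",
                 maxWorkingDistanceMm = "numeric", depthPerCycleMm = "numeric",
                 focusSpeedMmS = "numeric", incidenceRangeDeg = "numeric",
                 powerW = "numeric", pulseHz = "numeric", pulseUs = "numeric",
                 execNoiseSdMm = "numeric"),
  validity = function(object) {
    pos <- c(object@workspaceSideMm, object@workingDistanceMm,
             object@maxWorkingDistanceMm, object@depthPerCycleMm,
             object@focusSpeedMmS, object@powerW, object@pulseHz)
    if (any(pos <= 0)) return("laser parameters must be positive")
    r <- object@incidenceRangeDeg
    if (length(r) != 2L || r[1] <= 0 || r[2] > 90 || r[1] > r[2])
      return("incidenceRangeDeg must be an interval within (0, 90]")
    if (object@execNoiseSdMm < 0) return("execNoiseSdMm must be >= 0")
    TRUE
  })

#' @describeIn LaserConfig-class Constructor with device defaults.
#' @param workspaceSideMm,workingDistanceMm,maxWorkingDistanceMm see slots.
#' @param depthPerCycleMm,focusSpeedMmS,incidenceRangeDeg see slots.
#' @param powerW,pulseHz,pulseUs,execNoiseSdMm see slots.
#' @export
LaserConfig <- function(workspaceSideMm = 10, workingDistanceMm = 60,
                        maxWorkingDistanceMm = 100, depthPerCycleMm = 0.3,
                        focusSpeedMmS = 4, incidenceRangeDeg = c(45, 90),
                        powerW = 15, pulseHz = 500, pulseUs = c(50, 200),
                        execNoiseSdMm = 0) {
  new("LaserConfig", workspaceSideMm = workspaceSideMm,
      workingDistanceMm = workingDistanceMm,
      maxWorkingDistanceMm = maxWorkingDistanceMm,
      depthPerCycleMm = depthPerCycleMm, focusSpeedMmS = focusSpeedMmS,
      incidenceRangeDeg = incidenceRangeDeg, powerW = powerW,
      pulseHz = pulseHz, pulseUs = pulseUs, execNoiseSdMm = execNoiseSdMm)
}

#' AblationResult: executed marks and kinematics
#'
#' @slot marksMm n x 3 matrix of achieved crater centers, laser frame, mm.
#' @slot depthsMm crater depths, mm (0 for skipped points).
#' @slot flags per-point `"ok"`, `"out_of_workspace"` or `"bad_incidence"`.
#' @slot pathTimeS traversal time of the executed polyline, s.
#' @export
setClass("AblationResult",
  representation(marksMm = "matrix", depthsMm = "numeric", flags = "character",
                 pathTimeS = "numeric"),
  validity = function(object) {
    n <- nrow(object@marksMm)
    if (length(object@depthsMm) != n || length(object@flags) != n)
      return("marks, depths and flags must align")
    if (any(object@depthsMm < 0)) return("depths must be >= 0")
    if (object@pathTimeS < 0) return("pathTimeS must be >= 0")
    TRUE
  })

#' StudyConfig: Monte-Carlo accuracy study configuration
#'
#' @slot nReplicates number of simulated specimens (default 200).
#' @slot phantom a [PhantomSpec-class]; its seed is re-derived per replicate.
#' @slot laser a [LaserConfig-class].
#' @slot errorSources named logical toggles `cbct_noise`, `oct_noise`,
#'   `detection`, `execution`. With `detection` off, ground-truth centers
#'   stand in for detected ones (isolates imaging noise from localization).
#' @slot execNoiseSdMm execution-noise SD applied when the `execution`
#'   source is on, mm.
#' @slot nCycles ablation cycles per mark.
#' @slot verifySeparationMm minimum spacing between verification spheres,
#'   mm (they must not merge in the verification scan).
#' @slot seed master seed; every stochastic stage derives from it.
#' @export
setClass("StudyConfig",
  representation(nReplicates = "integer", phantom = "PhantomSpec",
                 laser = "LaserConfig", errorSources = "logical",
                 execNoiseSdMm = "numeric", nCycles = "integer",
                 verifySeparationMm = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nReplicates < 1L) return("nReplicates must be >= 1")
    need <- c("cbct_noise", "oct_noise", "detection", "execution")
    if (!all(need %in% names(object@errorSources)))
      return(paste("errorSources must name:", paste(need, collapse = ", ")))
    if (object@verifySeparationMm <= 0)
      return("verifySeparationMm must be > 0")
    TRUE
  })

#' @describeIn StudyConfig-class Constructor; defaults reproduce the full
#'   accuracy-verification loop at study scale.
#' @param nReplicates,phantom,laser,errorSources see slots.
#' @param execNoiseSdMm,nCycles,verifySeparationMm,seed see slots.
#' @export
StudyConfig <- function(nReplicates = 200L,
                        phantom = studyPhantomSpec(),
                        laser = LaserConfig(),
                        errorSources = c(cbct_noise = TRUE, oct_noise = TRUE,
                                         detection = TRUE, execution = TRUE),
                        execNoiseSdMm = 0.05,
                        nCycles = 1L,
                        verifySeparationMm = 2.0,
                        seed = 1L) {
  new("StudyConfig", nReplicates = as.integer(nReplicates), phantom = phantom,
      laser = laser, errorSources = errorSources,
      execNoiseSdMm = execNoiseSdMm, nCycles = as.integer(nCycles),
      verifySeparationMm = verifySeparationMm, seed = as.integer(seed))
}

#' AccuracyReport: pooled desired-vs-applied errors from the study
#'
#' @slot perTargetErrorsMm list (one numeric vector per successful
#'   replicate) of desired-vs-applied Euclidean errors, mm.
#' @slot meanMm,rmsMm,maxMm pooled summaries, mm.
#' @slot perReplicateFreMm fiducial registration error per replicate, mm.
#' @slot nReplicates,nFailed replicate bookkeeping; failures are counted,
#'   never dropped silently.
#' @slot failureMessages messages of failed replicates.
#' @slot configDigest human-readable parameter digest for provenance.
#' @export
setClass("AccuracyReport",
  representation(perTargetErrorsMm = "list", meanMm = "numeric",
                 rmsMm = "numeric", maxMm = "numeric",
                 perReplicateFreMm = "numeric", nReplicates = "integer",
                 nFailed = "integer", failureMessages = "character",
                 configDigest = "character"),
  validity = function(object) {
    errs <- unlist(object@perTargetErrorsMm)
    if (length(errs)) {
      if (any(errs < 0)) return("errors must be >= 0")
      if (abs(object@meanMm - mean(errs)) > 1e-9 ||
          abs(object@rmsMm - sqrt(mean(errs^2))) > 1e-9 ||
          abs(object@maxMm - max(errs)) > 1e-9)
        return("summary statistics must be recomputable from stored errors")
      if (object@meanMm > object@maxMm + 1e-12)
        return("meanMm must not exceed maxMm")
    }
    TRUE
  })
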