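# Readers and writers: NIfTI / MetaImage volumes, JSON point sets and
# transforms, CSV exports, YAML configuration.

#' Read and write volumes
#'
#' Volumes round-trip through NIfTI (`.nii`, `.nii.gz`, via RNifti) or
#' MetaImage (`.mha`, uncompressed, local raw data), preserving the data
#' and the index-to-world mapping to better than 1e-6 mm.
#'
#' @param vol a [Volume3D-class].
#' @param path file path; the extension selects the format.
#' @param modality modality tag to attach on read (the formats do not
#'   carry it).
#' @return `readVolume` returns a [Volume3D-class]; `writeVolume` returns
#'   `path` invisibly.
#' @export
writeVolume <- function(vol, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volData(vol))
    RNifti::pixdim(img) <- volSpacing(vol)
    m <- diag(c(volSpacing(vol), 1))
    m[1:3, 4] <- volOrigin(vol)
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    writeMetaImage(vol, path)
  } else {
    ioError(sprintf("unrecognized volume extension: %s", path))
  }
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, modality = "CBCT") {
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    x <- RNifti::xform(img)
    spacing <- RNifti::pixdim(img)[1:3]
    # our volumes are axis-aligned; recover the origin from the xform
    origin <- unname(x[1:3, 4])
    data <- array(as.vector(as.array(img)), dim(img))
    Volume3D(data, unname(spacing), origin, modality)
  } else if (grepl("\\.mha$", path)) {
    readMetaImage(path, modality)
  } else {
    ioError(sprintf("unrecognized volume extension: %s", path))
  }
}

# Minimal MetaImage (.mha) support: text header + local uncompressed
# little-endian raw data, MET_DOUBLE.
writeMetaImage <- function(vol, path) {
  d <- dim(volData(vol))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    sprintf("Offset = %.9g %.9g %.9g\n", volOrigin(vol)[1],
            volOrigin(vol)[2], volOrigin(vol)[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g\n", volSpacing(vol)[1],
            volSpacing(vol)[2], volSpacing(vol)[3]),
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    "ElementType = MET_DOUBLE\n",
    "ElementDataFile = LOCAL\n")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(volData(vol)), con, size = 8, endian = "little")
  invisible(path)
}

readMetaImage <- function(path, modality = "CBCT") {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) ioError(sprintf("malformed MetaImage header: %s",
                                            path))
      if (ch == "\n") break
      line <- c(line, ch)
    }
    line <- paste(line, collapse = "")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) ioError(sprintf("malformed MetaImage header: %s",
                                          path))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(fields[["ElementType"]], "MET_DOUBLE") ||
      !identical(fields[["ElementDataFile"]], "LOCAL"))
    ioError(sprintf("unsupported MetaImage variant: %s", path))
  dims <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields[["ElementSpacing"]], "\\s+")[[1]])
  origin <- as.numeric(strsplit(fields[["Offset"]], "\\s+")[[1]])
  data <- readBin(con, "double", n = prod(dims), size = 8,
                  endian = "little")
  if (length(data) != prod(dims))
    ioError(sprintf("truncated MetaImage data: %s", path))
  Volume3D(array(data, dims), spacing, origin, modality)
}

#' Serialize point sets, transforms, plans and reports
#'
#' JSON is the primary interchange format (centers in world mm, rotation
#' as a row-major 3 x 3 matrix); fiducial sets and plans also export to
#' CSV, and transforms to a plain-text 4 x 4 homogeneous matrix. All
#' writers return the path invisibly; readers reconstruct the S4 object
#' and re-validate it.
#'
#' @param x object to write.
#' @param path file path.
#' @param modality,frame tags attached on read where the format lacks
#'   them.
#' @name lasernav-io
NULL

#' @rdname lasernav-io
#' @export
writeFiducialSet <- function(x, path) {
  if (grepl("\\.csv$", path)) {
    df <- data.frame(label = seq_len(nrow(x@centers)),
                     x_mm = x@centers[, 1], y_mm = x@centers[, 2],
                     z_mm = x@centers[, 3], r_mm = x@radii,
                     quality = x@quality)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(frame = x@frame,
                              centers_mm = x@centers,
                              radii_mm = x@radii,
                              quality = x@quality),
                         path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname lasernav-io
#' @export
readFiducialSet <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  FiducialSet(j$centers_mm, j$radii_mm, j$quality, j$frame)
}

#' @rdname lasernav-io
#' @export
writeRigidTransform <- function(x, path) {
  if (grepl("\\.txt$", path)) {
    m <- diag(4)
    m[1:3, 1:3] <- x@rotation
    m[1:3, 4] <- x@translation
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  } else {
    jsonlite::write_json(list(rotation_row_major = as.numeric(t(x@rotation)),
                              translation_mm = x@translation),
                         path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname lasernav-io
#' @export
readRigidTransform <- function(path) {
  if (grepl("\\.txt$", path)) {
    m <- unname(as.matrix(utils::read.table(path)))
    RigidTransform(m[1:3, 1:3], m[1:3, 4])
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    RigidTransform(matrix(j$rotation_row_major, 3, 3, byrow = TRUE),
                   j$translation_mm)
  }
}

#' @rdname lasernav-io
#' @export
writeTargetPlan <- function(x, path) {
  if (grepl("\\.csv$", path)) {
    df <- data.frame(label = x@label, x_mm = x@points[, 1],
                     y_mm = x@points[, 2], z_mm = x@points[, 3],
                     nx = x@normals[, 1], ny = x@normals[, 2],
                     nz = x@normals[, 3])
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(label = x@label, points_mm = x@points,
                              normals = x@normals, view_dir = x@viewDir),
                         path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname lasernav-io
#' @export
readTargetPlan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TargetPlan", points = asPointMatrix(j$points_mm),
      normals = asPointMatrix(j$normals), viewDir = as.numeric(j$view_dir),
      label = j$label)
}

#' @rdname lasernav-io
#' @export
writeAblationResult <- function(x, path) {
  jsonlite::write_json(list(marks_mm = x@marksMm, depths_mm = x@depthsMm,
                            flags = x@flags, path_time_s = x@pathTimeS),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname lasernav-io
#' @export
writeAccuracyReport <- function(x, path) {
  if (grepl("\\.csv$", path)) {
    rows <- do.call(rbind, lapply(seq_along(x@perTargetErrorsMm),
      function(i) {
        e <- x@perTargetErrorsMm[[i]]
        if (length(e) == 0L) return(NULL)
        data.frame(replicate = i, target = seq_along(e), error_mm = e)
      }))
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(mean_mm = x@meanMm, rms_mm = x@rmsMm, max_mm = x@maxMm,
           n_replicates = x@nReplicates, n_failed = x@nFailed,
           per_replicate_fre_mm = x@perReplicateFreMm,
           per_target_errors_mm = x@perTargetErrorsMm,
           failures = x@failureMessages,
           config = x@configDigest),
      path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
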