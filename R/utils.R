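# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generators never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific 31-bit seed from a master seed. Arithmetic is done
# in doubles (exact below 2^53) and reduced mod a prime below 2^31.
deriveSeed <- function(seed, stream) {
  p <- 2147483587
  s <- (as.numeric(seed) %% p) * 48271 + as.numeric(stream) * 7919 + 12345
  as.integer(s %% p) + 1L
}

rowNorms <- function(m) sqrt(rowSums(m * m))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

asPointMatrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("points must be an n x 3 matrix of mm coordinates")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  points
}

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length direction vector")
  v / n
}

# Condition constructors -----------------------------------------------------

lasernavError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lasernav_error")))
}

configError        <- function(msg) lasernavError(msg, "lasernav_config_error")
fovError           <- function(msg) lasernavError(msg, "lasernav_fov_error")
insufficientError  <- function(msg) lasernavError(msg, "lasernav_insufficient_fiducials")
ambiguityError     <- function(msg) lasernavError(msg, "lasernav_ambiguity_error")
degenerateError    <- function(msg) lasernavError(msg, "lasernav_degenerate_error")
segmentationError  <- function(msg) lasernavError(msg, "lasernav_segmentation_error")
planningError      <- function(msg) lasernavError(msg, "lasernav_planning_error")
ioError            <- function(msg) lasernavError(msg, "lasernav_io_error")

# Otsu threshold on a numeric vector, delegated to EBImage on a rescaled copy.
otsuThreshold <- function(values, levels = 1024L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) <= 0) return(rng[1])
  v01 <- (values - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1L)),
                         range = c(0, 1), levels = levels)
  rng[1] + thr01 * diff(rng)
}

# All permutations of seq_len(n) as an n! x n matrix (n small).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    shifted <- sub + (sub >= i)
    cbind(rep.int(i, nrow(sub)), shifted)
  }))
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angleDeg` degrees about a (not necessarily unit)
#' axis through the origin, right-handed.
#'
#' @param axis numeric 3-vector.
#' @param angleDeg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
#' @examples
#' rotationMatrix(c(0, 0, 1), 90)
rotationMatrix <- function(axis, angleDeg) {
  a <- unitVector(as.numeric(axis))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
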