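# Shared fixtures: small, fast phantom specs built in code.

# Study-scale spec with all imaging noise switched off.
cleanSpec <- function(seed = 1, ...) {
  studyPhantomSpec(seed = seed,
                   noise = NoiseSpec(cbctGaussianSd = 0,
                                     octSpeckleScale = 0),
                   ...)
}

# Noisy study-scale spec (defaults).
noisySpec <- function(seed = 1, ...) studyPhantomSpec(seed = seed, ...)

# Sorted-by-x comparison of two point sets (order-free).
sortByX <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]

# Largest nearest-neighbour distance from each row of a to rows of b.
maxNNDist <- function(a, b) {
  max(vapply(seq_len(nrow(a)), function(i) {
    min(sqrt(rowSums((b - matrix(a[i, ], nrow(b), ncol(b),
                                 byrow = TRUE))^2)))
  }, numeric(1)))
}

# Analytic points on the upper hemisphere of a sphere (exact model data).
hemispherePoints <- function(center, radius, n = 200) {
  i <- seq_len(n)
  phi <- acos(1 - i / (n + 1))            # polar angle in (0, pi/2)
  th <- 2 * pi * i * (sqrt(5) - 1) / 2    # golden-angle azimuth
  cbind(center[1] + radius * sin(phi) * cos(th),
        center[2] + radius * sin(phi) * sin(th),
        center[3] + radius * cos(phi))
}
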