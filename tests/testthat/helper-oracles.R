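# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by naive enumeration (plain R loops) so they share no
# code with the implementation under test.

# Naive per-voxel minimum-chord thickness: walk every axis voxel by voxel.
oracle_thickness <- function(mask, gens, cap, s) {
  d <- dim(mask)
  walk <- function(x, y, z, g) {
    r <- 0L
    for (k in seq_len(cap)) {
      x <- x + g[1]; y <- y + g[2]; z <- z + g[3]
      if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) break
      if (mask[x, y, z] == 0) break
      r <- r + 1L
    }
    r
  }
  norms <- sqrt(rowSums(gens^2))
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (mask[x, y, z] == 0) next
    best <- Inf
    for (a in seq_len(nrow(gens))) {
      g <- gens[a, ]
      chord <- (walk(x, y, z, g) + walk(x, y, z, -g) + 1) * norms[a] * s
      if (chord < best) best <- chord
    }
    out[x, y, z] <- best
  }
  out
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Lattice-point-in-ball enumeration (0-based voxel centres).
oracle_ball_count <- function(shape, center, radius) {
  n <- 0L
  for (x in 0:(shape[1] - 1)) for (y in 0:(shape[2] - 1)) for (z in 0:(shape[3] - 1))
    if ((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= radius^2)
      n <- n + 1L
  n
}

# Random PSD tensor as a dyadic sum of random weighted directions.
random_dyadic_tensor <- function(k = 8) {
  A <- matrix(0, 3, 3)
  for (i in seq_len(k)) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * stats::runif(1, 0.5, 10)
    A <- A + tcrossprod(v)
  }
  (A + t(A)) / 2
}

# Random blob-ish binary mask (seeded by the caller).
random_mask <- function(shape, p = 0.4) {
  array(as.numeric(stats::runif(prod(shape)) < p), dim = shape)
}

slab_phantom <- function(n = 64, thickness = 3, center = n / 2) {
  make_phantom(phantom_spec(c(n, n, n), c(1, 1, 1),
    list(list(kind = "slab", axis = 3, center = center,
              thickness = thickness, class = 1))))
}

cylinder_phantom <- function(n = 64, radius = 2, center = c(n / 2, n / 2)) {
  make_phantom(phantom_spec(c(n, n, n), c(1, 1, 1),
    list(list(kind = "cylinder", axis = 3, center = center,
              radius = radius, class = 1))))
}

# Unpack the 6 lower-triangle components at one voxel into a 3x3 matrix.
tensor_at <- function(field, i, j, k) {
  a <- field$values[i, j, k, ]
  matrix(c(a[1], a[2], a[4],
           a[2], a[3], a[5],
           a[4], a[5], a[6]), 3, 3)
}

angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
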