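#' Per-voxel orientation tensor from directional scan rays
#'
#' At a foreground voxel, the local material orientation is summarised by the
#' second-moment matrix of run-length-weighted scan rays. For every sampled
#' direction `i` with unit vector `d_i`, the ray extent is
#' `r_i = 1 + ray_run_length(mask, voxel, generator_i, cap)` (the centre
#' voxel is counted once per ray), the scan-ray vector is `x_i = r_i * d_i`,
#' and the orientation tensor is the dyadic sum
#' `A = sum_i x_i (x_i)^T = sum_i r_i^2 d_i d_i^T`.
#'
#' `A` is symmetric positive semidefinite with `trace(A) = sum_i r_i^2`. In
#' isotropic surroundings (all `r_i` equal) the lattice direction sets are
#' balanced enough that `A` is exactly a multiple of the identity.
#'
#' The direction set must be unreduced (both signs of every axis present) so
#' that each sampled orientation contributes its own dyadic and the same
#' number of orientations is used at every voxel.
#'
#' @param mask binary [volume3d()].
#' @param voxel 1-based voxel index (length 3); must be foreground.
#' @param directions an unreduced [lattice_directions()] set.
#' @param cap per-ray scan range in voxels; default 16.
#' @return symmetric 3x3 numeric matrix.
#' @export
orientation_tensor <- function(mask, voxel,
                               directions = lattice_directions(2, FALSE),
                               cap = 16) {
  stopifnot(inherits(mask, "volume3d"), cap >= 1)
  assert_direction_set(directions, "orientation_tensor", reduced = FALSE)
  r <- 1 + vapply(seq_len(nrow(directions$generators)), function(i) {
    ray_run_length(mask, voxel, directions$generators[i, ], cap)
  }, numeric(1))
  u <- directions$units
  A <- crossprod(u * r)  # sum_i r_i^2 d_i d_i^T
  (A + t(A)) / 2
}

#' Orientation-tensor field with optional grid coarsening
#'
#' Computes the [orientation_tensor()] at every foreground voxel, then
#' block-averages the tensors over `output_bin^3` blocks: each output tensor
#' is the mean of the tensors of the foreground voxels in its block, and a
#' block with no foreground gets the zero tensor. Averaging dyadic-sum
#' tensors preserves positive semidefiniteness. Output spacing is the input
#' spacing times `output_bin`; the default of 2 halves the grid resolution,
#' which keeps tensor volumes manageable at whole-body scale.
#'
#' @param mask binary [volume3d()] with isometric spacing.
#' @param directions unreduced [lattice_directions()] set; default
#'   `lattice_directions(2, FALSE)` (98 signed directions).
#' @param cap per-ray scan range in voxels; default 16.
#' @param output_bin integer block edge for coarsening; default 2
#'   (1 = per-voxel tensors, no averaging).
#' @return a [tensor_volume()] with components in lower-triangle order
#'   `(a11, a21, a22, a31, a32, a33)`.
#' @export
tensor_field <- function(mask, directions = lattice_directions(2, FALSE),
                         cap = 16, output_bin = 2) {
  stopifnot(inherits(mask, "volume3d"), cap >= 1,
            output_bin >= 1, output_bin == round(output_bin))
  assert_direction_set(directions, "tensor_field", reduced = FALSE)
  assert_isometric(mask, "tensor_field")
  d <- vol_dim(mask)
  tf <- tensor_field_cpp(as_mask_array(mask), as.integer(d),
                         directions$generators, as.integer(cap))
  b <- as.integer(output_bin)
  if (b == 1L)
    return(tensor_volume(tf, spacing = mask$spacing))
  dout <- ceiling(d / b)
  out <- array(0, dim = c(dout, 6L))
  fg <- as_mask_array(mask)
  # per-block foreground count, then mean of member foreground tensors
  cnt <- block_reduce_sum(fg, b)
  for (k in 1:6) {
    sm <- block_reduce_sum(tf[, , , k], b)
    out[, , , k] <- ifelse(cnt > 0, sm / cnt, 0)
  }
  tensor_volume(out, spacing = mask$spacing * b)
}

# internal: sum a 3D array over non-overlapping b^3 blocks (ragged edge kept)
block_reduce_sum <- function(a, b) {
  d <- dim(a)
  dout <- ceiling(d / b)
  idx <- lapply(1:3, function(ax) rep(seq_len(dout[ax]), each = b,
                                      length.out = d[ax]))
  out <- array(0, dim = dout)
  acc <- rowsum(matrix(a, nrow = d[1]), idx[[1]], reorder = TRUE)       # x
  acc <- array(acc, dim = c(dout[1], d[2], d[3]))
  acc <- aperm(acc, c(2, 1, 3))
  acc <- rowsum(matrix(acc, nrow = d[2]), idx[[2]], reorder = TRUE)     # y
  acc <- array(acc, dim = c(dout[2], dout[1], d[3]))
  acc <- aperm(acc, c(3, 2, 1))
  acc <- rowsum(matrix(acc, nrow = d[3]), idx[[3]], reorder = TRUE)     # z
  acc <- array(acc, dim = c(dout[3], dout[1], dout[2]))
  aperm(acc, c(2, 3, 1))
}

#' Eigen-decomposition of a symmetric 3x3 orientation tensor
#'
#' Returns eigenvalues sorted descending (small negative values from floating
#' point are clamped to 0 within `1e-9 * lambda1`) and orthonormal
#' eigenvectors with a deterministic sign convention: `e1` and `e2` have
#' their largest-magnitude component positive, and `e3 = e1 x e2` completes a
#' right-handed frame.
#'
#' @param A symmetric 3x3 matrix (asymmetry beyond `1e-9` relative is an
#'   error).
#' @return a `tensor_eigensystem`: list with `values` (length 3, descending)
#'   and `vectors` (3x3 matrix, columns `e1, e2, e3`).
#' @export
eigensystem <- function(A) {
  if (!is.matrix(A) || !all(dim(A) == c(3L, 3L)))
    stop("eigensystem: A must be a 3x3 matrix")
  asym <- max(abs(A - t(A)))
  if (asym > 1e-9 * max(1, max(abs(A))))
    stop("eigensystem: matrix is not symmetric (max asymmetry ", asym, ")")
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- e$values  # already descending
  tol <- 1e-9 * max(abs(lam[1]), 1e-300)
  lam[lam < 0 & lam > -tol] <- 0
  vec <- e$vectors
  for (j in 1:2) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  vec[, 3] <- cross3(vec[, 1], vec[, 2])
  structure(list(values = lam, vectors = vec), class = "tensor_eigensystem")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Westin linear / planar / spherical anisotropy measures
#'
#' Sum-normalised Westin measures of a sorted eigenvalue triple
#' `lambda1 >= lambda2 >= lambda3 >= 0` with `S = lambda1+lambda2+lambda3`:
#'
#' * `c_l = (lambda1 - lambda2) / S` — linear (fibrous) character,
#' * `c_p = 2 (lambda2 - lambda3) / S` — planar (sheet) character,
#' * `c_s = 3 lambda3 / S` — spherical (isotropic) character.
#'
#' The triple is a partition of unity (`c_l + c_p + c_s = 1` identically,
#' each in `[0, 1]`), so it maps directly onto RGB colour. A zero-trace
#' tensor has no orientation content and yields the flagged all-zero
#' sentinel.
#'
#' @param eig a `tensor_eigensystem` from [eigensystem()], or a numeric
#'   length-3 vector of sorted eigenvalues.
#' @return a `westin_triple`: list with `c_l`, `c_p`, `c_s` and logical
#'   `unclassified` (TRUE only for the zero-trace sentinel).
#' @export
westin_measures <- function(eig) {
  lam <- if (inherits(eig, "tensor_eigensystem")) eig$values else as.numeric(eig)
  if (length(lam) != 3L) stop("westin_measures: need three eigenvalues")
  if (is.unsorted(rev(lam))) stop("westin_measures: eigenvalues must be sorted descending")
  S <- sum(lam)
  if (S <= 0)
    return(structure(list(c_l = 0, c_p = 0, c_s = 0, unclassified = TRUE),
                     class = "westin_triple"))
  structure(list(c_l = (lam[1] - lam[2]) / S,
                 c_p = 2 * (lam[2] - lam[3]) / S,
                 c_s = 3 * lam[3] / S,
                 unclassified = FALSE),
            class = "westin_triple")
}

#' Structural classification from Westin measures
#'
#' A voxel is fibrous when the linear measure dominates (one strong
#' eigenvector), planar when the planar measure dominates (two strong
#' eigenvectors) and spherical when all three eigenvalues are comparable.
#' The class is the argmax of `(c_l, c_p, c_s)` provided the maximum reaches
#' `threshold`; otherwise the voxel is unclassified. Ties break in the order
#' fibrous > planar > spherical. Integer codes: unclassified 0, fibrous 1,
#' planar 2, spherical 3.
#'
#' @param w a `westin_triple` from [westin_measures()].
#' @param threshold minimum dominant measure in `[0, 1)`; default 0
#'   (pure argmax).
#' @return character class name with the integer code as attribute `code`.
#' @seealso [structure_codes()]
#' @export
classify_structure <- function(w, threshold = 0) {
  stopifnot(inherits(w, "westin_triple"),
            threshold >= 0, threshold < 1)
  if (w$unclassified)
    return(structure("unclassified", code = 0L))
  v <- c(w$c_l, w$c_p, w$c_s)
  k <- which.max(v)  # which.max takes the first maximum: fibrous > planar > spherical
  if (v[k] < threshold)
    return(structure("unclassified", code = 0L))
  structure(c("fibrous", "planar", "spherical")[k], code = k)
}

#' Structure class code table
#'
#' Fixed mapping between structural class names and the integer codes used
#' in rank label volumes: unclassified 0, fibrous 1, planar 2, spherical 3.
#'
#' @return named integer vector.
#' @export
structure_codes <- function() {
  c(unclassified = 0L, fibrous = 1L, planar = 2L, spherical = 3L)
}

#' Classify every tensor of a field
#'
#' Applies [eigensystem()], [westin_measures()] and [classify_structure()] to
#' every voxel of a tensor field. Zero tensors (background) get code 0.
#'
#' @param field a [tensor_volume()].
#' @param threshold passed to [classify_structure()].
#' @return a [label_volume()] of structure codes (0-3).
#' @export
structure_rank <- function(field, threshold = 0) {
  stopifnot(inherits(field, "tensor_volume"))
  es <- field_eigen(field)
  out <- array(0L, dim = vol_dim(field))
  if (nrow(es$index) > 0) {
    for (i in seq_len(nrow(es$index))) {
      w <- westin_measures(es$values[i, ])
      cl <- classify_structure(w, threshold)
      out[es$index[i, 1], es$index[i, 2], es$index[i, 3]] <- attr(cl, "code")
    }
  }
  label_volume(out, spacing = field$spacing,
               label_names = c(`1` = "fibrous", `2` = "planar", `3` = "spherical"))
}

# internal: eigensystems of all nonzero tensors of a field.
# Returns index (m x 3, 1-based), values (m x 3), vectors (list of 3x3).
field_eigen <- function(field) {
  v <- field$values
  d <- vol_dim(field)
  comp <- matrix(v, ncol = 6L)
  nz <- which(rowSums(abs(comp)) > 0)
  idx <- arrayInd(nz, d)
  m <- length(nz)
  vals <- matrix(0, m, 3)
  vecs <- vector("list", m)
  for (i in seq_len(m)) {
    a <- comp[nz[i], ]
    A <- matrix(c(a[1], a[2], a[4],
                  a[2], a[3], a[5],
                  a[4], a[5], a[6]), 3, 3)
    es <- eigensystem(A)
    vals[i, ] <- es$values
    vecs[[i]] <- es$vectors
  }
  list(index = idx, linear = nz, values = vals, vectors = vecs)
}

#' Encode a tensor field as an RGB volume
#'
#' Colour encodings of per-voxel tensor eigenstructure:
#'
#' * `"e1"` / `"e2"` — absolute components of the chosen eigenvector,
#'   `(|ex|, |ey|, |ez|) * 255`, the standard direction-to-colour map.
#' * `"westin"` — `(c_l, c_p, c_s) * 255`, a continuous structural map.
#' * `"rank"` — categorical: fibrous red `(255,0,0)`, planar green
#'   `(0,255,0)`, spherical blue `(0,0,255)`, unclassified black.
#'
#' Values are rounded half-up. Zero (background) tensors encode to black in
#' every mode.
#'
#' @param field a [tensor_volume()].
#' @param mode one of `"e1"`, `"e2"`, `"westin"`, `"rank"`.
#' @param threshold classification threshold for `"rank"` mode.
#' @return an [rgb_volume()] on the tensor grid.
#' @export
encode_tensor_rgb <- function(field, mode = c("e1", "e2", "westin", "rank"),
                              threshold = 0) {
  stopifnot(inherits(field, "tensor_volume"))
  mode <- match.arg(mode)
  d <- vol_dim(field)
  out <- array(0L, dim = c(d, 3L))
  es <- field_eigen(field)
  class_col <- rbind(c(0L, 0L, 0L), c(255L, 0L, 0L), c(0L, 255L, 0L),
                     c(0L, 0L, 255L))
  nvox <- prod(d)
  for (i in seq_len(nrow(es$index))) {
    rgbv <- switch(mode,
      e1 = round_half_up(abs(es$vectors[[i]][, 1]) * 255),
      e2 = round_half_up(abs(es$vectors[[i]][, 2]) * 255),
      westin = {
        w <- westin_measures(es$values[i, ])
        round_half_up(c(w$c_l, w$c_p, w$c_s) * 255)
      },
      rank = {
        w <- westin_measures(es$values[i, ])
        class_col[attr(classify_structure(w, threshold), "code") + 1L, ]
      })
    out[es$linear[i] + nvox * (0:2)] <- as.integer(rgbv)
  }
  rgb_volume(out, spacing = field$spacing)
}

# deterministic half-up rounding (round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Decode a rank-mode RGB volume back to structure codes
#'
#' Inverts the categorical `"rank"` colouring of [encode_tensor_rgb()]
#' (red fibrous, green planar, blue spherical, black unclassified) into a
#' label volume of structure codes, so region statistics can be computed
#' from the colour-coded files alone.
#'
#' @param rgb an [rgb_volume()] containing only the four rank colours.
#' @return a [label_volume()] of codes 0-3.
#' @export
rank_labels_from_rgb <- function(rgb) {
  stopifnot(inherits(rgb, "rgb_volume"))
  d <- vol_dim(rgb)
  r <- rgb$values[, , , 1]; g <- rgb$values[, , , 2]; b <- rgb$values[, , , 3]
  out <- array(0L, dim = d)
  out[r == 255L & g == 0L & b == 0L] <- 1L
  out[r == 0L & g == 255L & b == 0L] <- 2L
  out[r == 0L & g == 0L & b == 255L] <- 3L
  bad <- sum((r | g | b) & out == 0L)
  if (bad > 0)
    stop("rank_labels_from_rgb: ", bad,
         " voxels carry colours that are not rank codes")
  label_volume(out, spacing = rgb$spacing,
               label_names = c(`1` = "fibrous", `2` = "planar", `3` = "spherical"))
}
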