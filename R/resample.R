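#' Summative binning to isometric voxels
#'
#' Converts an anisotropic binary or count volume to isometric voxels of
#' edge `target_spacing` by summative binning: each output count is the
#' total input value falling inside the output voxel. When the
#' target/source spacing ratio is integer on every axis this is an exact
#' sum over non-overlapping blocks. Otherwise each source voxel's value is
#' distributed over the output voxels it overlaps in proportion to the
#' overlap volume (the grids share the origin, so the 3D overlap weight is a
#' product of per-axis interval overlaps), and the resulting real-valued
#' counts are rounded to integers by half-up rounding with a
#' largest-remainder correction that preserves the rounded grand total.
#' Total mass `sum(counts) * t^3` therefore equals
#' `sum(values) * sx * sy * sz` exactly for integer ratios and within the
#' rounding granularity otherwise.
#'
#' Only downsampling is supported: the target spacing must be at least every
#' source spacing component. Counts are stored 16-bit-unsigned-compatible;
#' a block sum above 65535 raises an error.
#'
#' @param vol a [volume3d()] (or [label_volume()], treated as binary
#'   foreground) with binary or non-negative count values.
#' @param target_spacing isometric output voxel edge in mm.
#' @return an integer-count [volume3d()] with spacing
#'   `(target_spacing, target_spacing, target_spacing)`.
#' @examples
#' v <- volume3d(array(1, c(8, 8, 8)), spacing = c(0.25, 0.25, 0.25))
#' b <- isometric_bin(v, 0.5)   # 4 x 4 x 4, every count 8
#' @export
isometric_bin <- function(vol, target_spacing) {
  if (inherits(vol, "label_volume"))
    vol <- volume3d(array(as.numeric(vol$values > 0), dim = vol_dim(vol)),
                    spacing = vol$spacing)
  stopifnot(inherits(vol, "volume3d"))
  t <- as.numeric(target_spacing)
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("isometric_bin: target_spacing must be a positive scalar (mm)")
  s <- vol$spacing
  if (any(t < s - 1e-12))
    stop("isometric_bin: target spacing ", t,
         " is smaller than source spacing (", paste(format(s), collapse = ", "),
         "); upsampling is not supported")
  v <- vol$values
  if (min(v) < 0) stop("isometric_bin: values must be non-negative counts")
  d <- vol_dim(vol)
  ratio <- t / s
  integer_ratio <- all(abs(ratio - round(ratio)) < 1e-9)
  if (integer_ratio) {
    out <- block_reduce_sum_blocks(v, round(ratio))
  } else {
    w <- lapply(1:3, function(ax) overlap_weights(d[ax], s[ax], t))
    out <- contract_axis(v, w[[1]], 1L)
    out <- contract_axis(out, w[[2]], 2L)
    out <- contract_axis(out, w[[3]], 3L)
    out <- round_preserve_total(out)
  }
  if (max(out) > 65535)
    stop("isometric_bin: a binned count exceeds 65535 (16-bit unsigned)")
  storage.mode(out) <- "integer"
  volume3d(out, spacing = c(t, t, t), origin = vol$origin)
}

# internal: per-axis source->target distribution matrix. Row k, column j is
# the fraction of source interval j = [(j-1)s, js) overlapping target
# interval k = [(k-1)t, kt). Rows sum to <= 1 per column; column sums are 1
# (each source voxel fully distributed) because the output grid covers the
# source extent.
overlap_weights <- function(nin, s, t) {
  nout <- ceiling(nin * s / t - 1e-9)
  w <- matrix(0, nout, nin)
  for (j in seq_len(nin)) {
    lo <- (j - 1) * s
    hi <- j * s
    k0 <- max(1L, floor(lo / t - 1e-12) + 1L)
    k1 <- min(nout, floor((hi - 1e-12) / t) + 1L)
    for (k in k0:k1) {
      ov <- min(hi, k * t) - max(lo, (k - 1) * t)
      if (ov > 0) w[k, j] <- ov / s
    }
  }
  w
}

# internal: apply an (nout x nin) weight matrix along one axis of a 3D array
contract_axis <- function(a, w, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- w %*% matrix(ap, nrow = d[axis])
  dn <- d[perm]
  dn[1] <- nrow(w)
  res <- array(m, dim = dn)
  inv <- order(perm)
  aperm(res, inv)
}

# internal: block sum with integer block sizes per axis (exact path)
block_reduce_sum_blocks <- function(a, blocks) {
  d <- dim(a)
  out <- a
  for (ax in 1:3) {
    b <- blocks[ax]
    if (b == 1) next
    dd <- dim(out)
    nout <- ceiling(dd[ax] / b)
    idx <- rep(seq_len(nout), each = b, length.out = dd[ax])
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(out, perm)
    m <- rowsum(matrix(ap, nrow = dd[ax]), idx, reorder = TRUE)
    dn <- dd[perm]
    dn[1] <- nout
    out <- aperm(array(m, dim = dn), order(perm))
  }
  out
}

# internal: half-up rounding adjusted by largest remainders so the grand
# total matches the rounded exact total (deterministic; ties by index)
round_preserve_total <- function(x) {
  r <- floor(x + 0.5)
  target <- round(sum(x))
  diffn <- target - sum(r)
  if (diffn != 0) {
    frac <- x - floor(x)
    if (diffn > 0) {
      # bump up entries whose fractional part came closest to 0.5 from below
      cand <- which(frac < 0.5)
      cand <- cand[order(-frac[cand])]
      cand <- cand[seq_len(min(diffn, length(cand)))]
      r[cand] <- r[cand] + 1
    } else {
      # take back entries that only just rounded up
      cand <- which(frac >= 0.5)
      cand <- cand[order(frac[cand])]
      cand <- cand[seq_len(min(-diffn, length(cand)))]
      r[cand] <- r[cand] - 1
    }
  }
  r
}
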