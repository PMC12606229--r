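#' Depth-coded X-ray projection
#'
#' Projects a binary volume along one axis into a 2D colour image in which
#' colour encodes depth and brightness encodes the amount of tissue: for
#' every output pixel the foreground voxels of its projection column are
#' collected, each depth is normalised to `[0, 1]` and mapped through the
#' colormap, the mapped colours are arithmetically averaged, and the result
#' is scaled by `column count / max column count` (one global scale so
#' projections are comparable). Columns without foreground are black.
#'
#' @param mask binary [volume3d()].
#' @param axis projection axis (1, 2 or 3).
#' @param colormap palette name accepted by [grDevices::hcl.colors()];
#'   default `"viridis"` (perceptually uniform).
#' @return numeric array `(n1, n2, 3)` with values in `[0, 1]`, the two
#'   remaining axes in their original order.
#' @seealso [save_image()]
#' @export
depth_xray <- function(mask, axis = 3, colormap = "viridis") {
  stopifnot(inherits(mask, "volume3d"), axis %in% 1:3)
  d <- vol_dim(mask)
  D <- d[axis]
  ncmap <- max(D, 2L)
  cmap <- t(grDevices::col2rgb(grDevices::hcl.colors(ncmap, colormap))) / 255
  keep <- setdiff(1:3, axis)
  v <- aperm(mask$values > 0, c(keep, axis))        # (n1, n2, D)
  n1 <- d[keep[1]]; n2 <- d[keep[2]]
  counts <- rowSums(v, dims = 2)
  # mean mapped colour per column: depth d (0-based) maps to cmap row
  # round(d / (D - 1) * (ncmap - 1)) + 1
  depth_row <- if (D == 1) rep(1L, 1) else round((0:(D - 1)) / (D - 1) * (ncmap - 1)) + 1L
  img <- array(0, dim = c(n1, n2, 3))
  vm <- matrix(v, ncol = D)                          # (n1*n2, D)
  for (ch in 1:3) {
    acc <- vm %*% cmap[depth_row, ch]
    img[, , ch] <- matrix(acc, n1, n2)
  }
  maxc <- max(counts)
  if (maxc == 0) return(img)                          # empty mask -> black
  scale <- ifelse(counts > 0, (counts / maxc) / pmax(counts, 1), 0)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * scale
  img
}

#' Extract a 2D slice image
#'
#' Extracts an axial (xy at fixed z), coronal (xz at fixed y) or sagittal
#' (yz at fixed x) plane. The returned image is oriented with the first
#' array axis running along the first in-plane volume axis; for coronal and
#' sagittal planes the z (superior) axis is the image's second axis with
#' superior last, so `image[, ncol(image)]` is the top of the body. Scalar
#' volumes are rendered grey-scale (normalised to `[0, 1]`); RGB volumes
#' keep their colours (scaled to `[0, 1]`).
#'
#' @param vol an [rgb_volume()] or [volume3d()].
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param index 1-based slice index along the fixed axis.
#' @return numeric array `(n1, n2)` (grey) or `(n1, n2, 3)` (colour) in
#'   `[0, 1]`.
#' @export
slice_image <- function(vol, plane = c("axial", "coronal", "sagittal"), index) {
  plane <- match.arg(plane)
  d <- vol_dim(vol)
  ax <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  if (length(index) != 1L || index < 1L || index > d[ax])
    stop("slice_image: index ", index, " out of range [1, ", d[ax], "] for ",
         plane, " plane")
  if (inherits(vol, "rgb_volume")) {
    sl <- switch(plane,
                 axial = vol$values[, , index, ],
                 coronal = vol$values[, index, , ],
                 sagittal = vol$values[index, , , ])
    return(sl / 255)
  }
  sl <- switch(plane,
               axial = vol$values[, , index],
               coronal = vol$values[, index, ],
               sagittal = vol$values[index, , ])
  rng <- range(vol$values)
  if (rng[2] > rng[1]) (sl - rng[1]) / (rng[2] - rng[1]) else sl * 0
}

#' Save a 2D image as PNG
#'
#' Writes an image array from [depth_xray()] or [slice_image()] to a PNG
#' file. The first array axis is drawn left-to-right and the second
#' bottom-to-top, so the orientation convention of [slice_image()] (superior
#' = second axis, increasing) puts superior at the top of the PNG.
#'
#' @param img numeric array `(n1, n2)` or `(n1, n2, 3)` with values in
#'   `[0, 1]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  # png rows = image top-down y; our second axis increases upwards
  out <- aperm(img[, dim(img)[2]:1, , drop = FALSE], c(2, 1, 3))
  png::writePNG(out, path)
  invisible(path)
}
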