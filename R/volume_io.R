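#' Read a volume from compressed NIFTI-1
#'
#' Reads any of the four volumetric encodings used by the pipeline and
#' dispatches on the NIFTI header:
#'
#' * 24-bit RGB datatype (code 128) -> [rgb_volume()]
#' * symmetric-matrix intent (code 1005) with 6 components -> [tensor_volume()]
#' * integer datatype with a label-name sidecar file next to the volume
#'   (`<stem>.labels.tsv`) -> [label_volume()]
#' * anything else -> [volume3d()]
#'
#' Only NIFTI-1 is supported; NIFTI-2 files are rejected. Voxel spacing is
#' taken from the header pixel dimensions. The orientation matrix is not
#' interpreted: spacing is honoured, rotations are not.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume3d()], [rgb_volume()], [tensor_volume()] or
#'   [label_volume()] object.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path)
  assert_nifti1(path)
  hdr <- tryCatch(RNifti::niftiHeader(path),
                  error = function(e) stop("read_volume: malformed NIFTI header in ",
                                           path, ": ", conditionMessage(e)))
  dt <- hdr$datatype
  supported <- c(2L, 4L, 8L, 16L, 64L, 128L, 256L, 512L, 768L)
  if (!(dt %in% supported))
    stop("read_volume: unsupported NIFTI datatype code ", dt, " in ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_volume: failed to read ", path,
                                           ": ", conditionMessage(e)))
  spacing <- RNifti::pixdim(img)[1:3]

  if (dt == 128L) {
    ch <- RNifti::channels(img, c("red", "green", "blue"))
    ch <- array(as.integer(round(ch)), dim = dim(ch))
    return(rgb_volume(ch, spacing = spacing))
  }

  if (identical(hdr$intent_code, 1005L)) {
    a <- strip_nifti_attrs(img)
    d <- dim(a)
    if (length(d) == 5L && d[4] == 1L && d[5] == 6L) {
      a <- array(a, dim = c(d[1:3], 6L))
    } else if (!(length(d) == 4L && d[4] == 6L)) {
      stop("read_volume: symmetric-matrix intent with unexpected dimensions (",
           paste(d, collapse = " x "), ") - need 6 components")
    }
    return(tensor_volume(a, spacing = spacing))
  }

  a <- strip_nifti_attrs(img)
  if (length(dim(a)) != 3L) {
    dn <- dim(a)[dim(a) > 1L]
    if (length(dn) != 3L)
      stop("read_volume: expected a 3D grid, got dimensions ",
           paste(dim(a), collapse = " x "))
    a <- array(a, dim = dn)
  }

  side <- sidecar_path(path)
  if (is.integer(a) && file.exists(side)) {
    tab <- utils::read.delim(side, header = TRUE, sep = "\t",
                             colClasses = c("integer", "character"))
    nm <- stats::setNames(tab[[2]], as.character(tab[[1]]))
    return(label_volume(a, spacing = spacing, label_names = nm))
  }
  volume3d(a, spacing = spacing)
}

#' Write a volume to compressed NIFTI-1
#'
#' Writes any of the four volume kinds as gzip-compressed NIFTI-1:
#'
#' * [volume3d()] with integer values -> smallest unsigned/signed integer
#'   datatype that holds the range (bit-exact round trip); real values ->
#'   32-bit float.
#' * [label_volume()] -> integer datatype plus a two-column tab-separated
#'   sidecar `<stem>.labels.tsv` holding the label-name table.
#' * [rgb_volume()] -> 24-bit RGB datatype (code 128).
#' * [tensor_volume()] -> 6 lower-triangle components
#'   `(a11, a21, a22, a31, a32, a33)` with symmetric-matrix intent
#'   (code 1005), stored as 64-bit float so matrices round-trip exactly.
#'
#' @param vol the volume object.
#' @param path output path; `.nii.gz` recommended.
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
write_volume <- function(vol, path) UseMethod("write_volume")

#' @export
write_volume.volume3d <- function(vol, path) {
  v <- vol$values
  if (!all(is.finite(v)))
    stop("write_volume: non-finite values in a real-valued grid")
  if (all(v == round(v))) {
    storage.mode(v) <- "integer"
    dt <- pick_int_datatype(range(v))
  } else {
    storage.mode(v) <- "double"
    dt <- "float"
  }
  write_nii(v, vol$spacing, path, datatype = dt)
  invisible(path)
}

#' @export
write_volume.label_volume <- function(vol, path) {
  dt <- pick_int_datatype(range(vol$values))
  write_nii(vol$values, vol$spacing, path, datatype = dt)
  tab <- data.frame(label = as.integer(names(vol$label_names)),
                    name = unname(vol$label_names))
  tab <- tab[order(tab$label), , drop = FALSE]
  utils::write.table(tab, sidecar_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_volume.rgb_volume <- function(vol, path) {
  d <- dim(vol$values)[1:3]
  ra <- RNifti::rgbArray(vol$values[, , , 1], vol$values[, , , 2],
                         vol$values[, , , 3], max = 255L, dim = d)
  img <- RNifti::asNifti(ra)
  img$pixdim <- c(1, vol$spacing, 1, 1, 1, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
write_volume.tensor_volume <- function(vol, path) {
  d <- dim(vol$values)
  a <- array(as.double(vol$values), dim = c(d[1:3], 1L, 6L))
  img <- RNifti::asNifti(a)
  img$pixdim <- c(1, vol$spacing, 1, 1, 1, 1)
  img$intent_code <- 1005L
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# internal: smallest NIFTI integer datatype holding the value range
pick_int_datatype <- function(rng) {
  if (rng[1] >= 0 && rng[2] <= 255) "uint8"
  else if (rng[1] >= 0 && rng[2] <= 65535) "uint16"
  else if (rng[1] >= -2147483647 && rng[2] <= 2147483647) "int"
  else stop("write_volume: integer values out of 32-bit range")
}

# internal: write a plain array with spacing and datatype
write_nii <- function(a, spacing, path, datatype) {
  img <- RNifti::asNifti(a)
  img$pixdim <- c(1, spacing, rep(1, length(dim(a)) - 3L),
                  rep(1, 4 - max(0, length(dim(a)) - 3L)))[1:8]
  RNifti::writeNifti(img, path, datatype = datatype)
}

# internal: plain array from a niftiImage (drop header attributes)
strip_nifti_attrs <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim = dim(a))
}

# internal: label-name sidecar lives next to the volume
sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.tsv")
}

# internal: reject NIFTI-2 and non-NIFTI files early by sizeof_hdr
assert_nifti1 <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", n = 1L, size = 4L)
  if (length(sz) == 0)
    stop("read_volume: empty file: ", path)
  # sizeof_hdr: 348 for NIFTI-1, 540 for NIFTI-2 (either byte order)
  nifti1 <- c(348L, 1543503872L)
  nifti2 <- c(540L, 469893120L)
  if (sz %in% nifti2)
    stop("read_volume: ", path, " is NIFTI-2; only NIFTI-1 is supported")
  if (!(sz %in% nifti1))
    stop("read_volume: ", path, " does not look like a NIFTI-1 file")
  invisible(TRUE)
}
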