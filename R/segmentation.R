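#' Colour model for collagen segmentation
#'
#' Collagen-containing connective tissue occupies a distinctive, nearly
#' white region of the RGB colour space in cryo-section photographs, and a
#' linear transform of the colour coordinates makes the tissue classes
#' compactly separable. A colour model consists of a 3x3 transform applied
#' to each voxel's `(r, g, b)` triple, one reference colour per tissue class
#' in the transformed space, and a per-class distance threshold. Two classes
#' are typical: connective tissue surrounding the organs and connective
#' tissue embedded in subcutaneous fat differ slightly in hue.
#'
#' The default model uses the identity transform with two whitish reference
#' colours; the transform and thresholds are fully configurable because the
#' constants appropriate for a given photographic setup are
#' acquisition-specific.
#'
#' @param transform 3x3 real matrix applied to colour triples.
#' @param class_references matrix with one row per class of the reference
#'   colour in transformed space; row names (or `class_ids`) give the
#'   distinct positive integer class ids.
#' @param max_distance per-class positive scalar threshold in
#'   transformed-space units (recycled if length 1).
#' @param class_ids integer class ids, one per reference row.
#' @return a `color_model` object.
#' @seealso [segment_collagen()], [read_color_model()]
#' @export
color_model <- function(transform = diag(3),
                        class_references = rbind(c(225, 215, 200),
                                                 c(235, 225, 180)),
                        max_distance = 40,
                        class_ids = seq_len(nrow(class_references))) {
  transform <- as.matrix(transform)
  class_references <- as.matrix(class_references)
  if (!all(dim(transform) == c(3L, 3L)))
    stop("color_model: transform must be 3x3")
  if (ncol(class_references) != 3L || nrow(class_references) < 1L)
    stop("color_model: class_references must have >= 1 row of 3 components")
  class_ids <- as.integer(class_ids)
  if (anyDuplicated(class_ids) || any(class_ids <= 0) ||
      length(class_ids) != nrow(class_references))
    stop("color_model: class ids must be distinct positive integers, one per reference")
  max_distance <- rep_len(as.numeric(max_distance), nrow(class_references))
  if (any(max_distance <= 0))
    stop("color_model: max_distance must be > 0")
  structure(list(transform = transform, class_references = class_references,
                 max_distance = max_distance, class_ids = class_ids),
            class = "color_model")
}

#' Read / write a colour model as YAML
#'
#' Serialises the transform matrix (as rows), the per-class reference
#' colours and thresholds to a structured config file.
#'
#' @param model a [color_model()].
#' @param path YAML file path.
#' @return `read_color_model` returns a [color_model()];
#'   `write_color_model` returns `path` invisibly.
#' @export
write_color_model <- function(model, path) {
  stopifnot(inherits(model, "color_model"))
  obj <- list(transform = lapply(seq_len(3), function(i) as.numeric(model$transform[i, ])),
              classes = lapply(seq_along(model$class_ids), function(i) {
                list(id = model$class_ids[i],
                     reference = as.numeric(model$class_references[i, ]),
                     max_distance = model$max_distance[i])
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_color_model
#' @export
read_color_model <- function(path) {
  obj <- yaml::read_yaml(path)
  refs <- do.call(rbind, lapply(obj$classes, function(cl) as.numeric(cl$reference)))
  color_model(transform = do.call(rbind, obj$transform),
              class_references = refs,
              max_distance = vapply(obj$classes, function(cl) as.numeric(cl$max_distance), 0),
              class_ids = vapply(obj$classes, function(cl) as.integer(cl$id), 0L))
}

#' Segment collagen-containing tissue by colour
#'
#' Applies the model transform to every voxel colour and assigns the class
#' whose transformed reference colour is nearest in Euclidean distance,
#' provided that distance is within the class's `max_distance`; otherwise the
#' voxel is background (label 0). Deterministic; ties are broken by the
#' lowest class id.
#'
#' @param rgb an [rgb_volume()].
#' @param model a [color_model()] with at least one class.
#' @return a [label_volume()] of class ids on the same grid.
#' @export
segment_collagen <- function(rgb, model) {
  stopifnot(inherits(rgb, "rgb_volume"), inherits(model, "color_model"))
  d <- vol_dim(rgb)
  cols <- matrix(as.numeric(rgb$values), ncol = 3L)      # n x 3
  tcols <- cols %*% t(model$transform)
  ord <- order(model$class_ids)                           # low id wins ties
  best <- rep.int(0L, nrow(tcols))
  bestd <- rep.int(Inf, nrow(tcols))
  for (i in ord) {
    di <- sqrt(rowSums(sweep(tcols, 2L, model$class_references[i, ])^2))
    take <- di <= model$max_distance[i] & di < bestd      # strict: earlier (lower) id keeps ties
    best[take] <- model$class_ids[i]
    bestd[take] <- di[take]
  }
  nm <- stats::setNames(paste0("class_", sort(model$class_ids)),
                        as.character(sort(model$class_ids)))
  label_volume(array(best, dim = d), spacing = rgb$spacing, label_names = nm)
}

#' Remove small connected components
#'
#' Connected components of the foreground (the union of all classes,
#' 26-connectivity) with fewer than `min_component_voxels` voxels are set to
#' background; all other labels are unchanged. Cleaning on the class-union
#' mask means a small fragment of one class attached to a large body of
#' another survives. 26-connectivity is the most permissive choice and
#' avoids fragmenting thin fascia. Never increases the foreground count;
#' `min_component_voxels = 1` is the identity.
#'
#' @param labels a [label_volume()] (or binary [volume3d()]).
#' @param min_component_voxels minimum component size to keep, `>= 1`.
#' @return object of the same class as `labels` with small components removed.
#' @export
clean_artifacts <- function(labels, min_component_voxels) {
  stopifnot(min_component_voxels >= 1)
  if (min_component_voxels == 1) return(labels)
  v <- labels$values
  d <- dim(v)
  fg <- array(as.integer(v > 0), dim = d)
  cc <- connected_components_26(fg, as.integer(d))
  sizes <- tabulate(cc)
  drop <- which(sizes < min_component_voxels)
  if (length(drop) > 0)
    v[cc %in% drop] <- 0L
  out <- labels
  out$values <- v
  out
}

#' Fill missing cross-sections by shape interpolation
#'
#' Reconstructs missing z-slices of a binary volume from their nearest valid
#' neighbours by signed-distance-field interpolation: each neighbouring valid
#' slice is converted to its signed Euclidean distance field (positive inside
#' the foreground), the two fields are linearly blended by the slice's
#' fractional position inside the gap, and the blend is re-thresholded at 0
#' (boundary counted as foreground). This preserves the shape topology across
#' gaps, unlike per-voxel intensity interpolation, which smears boundaries. A
#' missing slice with a valid neighbour on only one side copies that
#' neighbour. Valid slices are returned bit-identical.
#'
#' @param vol a binary [volume3d()].
#' @param missing integer indices (1-based) of missing slices along z.
#' @return a [volume3d()] with the missing slices filled.
#' @export
fill_missing_slices <- function(vol, missing) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is_binary_volume(vol))
    stop("fill_missing_slices: volume must be binary")
  d <- vol_dim(vol)
  missing <- sort(unique(as.integer(missing)))
  if (any(missing < 1L) || any(missing > d[3]))
    stop("fill_missing_slices: missing indices out of range")
  valid <- setdiff(seq_len(d[3]), missing)
  if (length(valid) == 0)
    stop("fill_missing_slices: all slices missing")
  out <- vol$values
  sdf_cache <- new.env(parent = emptyenv())
  sdf <- function(z) {
    key <- as.character(z)
    if (is.null(sdf_cache[[key]]))
      sdf_cache[[key]] <- signed_distance_2d(vol$values[, , z])
    sdf_cache[[key]]
  }
  for (z in missing) {
    below <- valid[valid < z]
    above <- valid[valid > z]
    zb <- if (length(below)) max(below) else NA_integer_
    za <- if (length(above)) min(above) else NA_integer_
    if (is.na(zb) && is.na(za)) next  # unreachable: valid nonempty
    if (is.na(zb)) { out[, , z] <- vol$values[, , za]; next }
    if (is.na(za)) { out[, , z] <- vol$values[, , zb]; next }
    f <- (z - zb) / (za - zb)
    blend <- (1 - f) * sdf(zb) + f * sdf(za)
    out[, , z] <- (blend >= 0) * 1
  }
  volume3d(out, spacing = vol$spacing, origin = vol$origin)
}

# internal: signed 2D Euclidean distance field, positive inside foreground.
# Degenerate all-foreground / all-background slices get +/- a large constant.
signed_distance_2d <- function(slice) {
  big <- sum(dim(slice))  # exceeds any achievable in-plane distance
  if (all(slice > 0)) return(matrix(big, nrow(slice), ncol(slice)))
  if (all(slice == 0)) return(matrix(-big, nrow(slice), ncol(slice)))
  fg <- (slice > 0) * 1
  din <- EBImage::distmap(fg, metric = "euclidean")
  dout <- EBImage::distmap(1 - fg, metric = "euclidean")
  as.matrix(din) - as.matrix(dout)
}
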