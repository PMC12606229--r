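#' Synthetic tissue phantoms
#'
#' Builds binary masks and class label maps from geometric primitives with
#' exactly known geometry, so every pipeline stage can be validated without
#' external data. A voxel is foreground iff its centre lies inside at least
#' one primitive; voxel centres sit at integer coordinates `0 .. n-1` (in
#' voxel units) and there is no partial-volume antialiasing, so foreground
#' counts are integer-exact against enumeration oracles. Truth labels follow
#' primitive order: a later primitive overwrites an earlier one where they
#' overlap.
#'
#' Primitives (all parameters in voxel units, inclusive boundaries):
#' * `slab(axis, center, thickness)` — `|coord_axis - center| <= thickness/2`,
#'   spanning the grid in the other two axes.
#' * `cylinder(axis, center, radius, from, to)` — distance to the axis line
#'   `<= radius`; `from`/`to` optionally clip the extent along the axis
#'   (default: full grid).
#' * `ball(center, radius)` — Euclidean distance to `center <= radius`.
#' * `cuboid(lo, hi)` — componentwise `lo <= coord <= hi`.
#'
#' @param shape grid dimensions (3 positive integers).
#' @param spacing voxel size in mm.
#' @param primitives list of primitive descriptors, each a list with `kind`
#'   (one of `"slab"`, `"cylinder"`, `"ball"`, `"cuboid"`), the geometric
#'   parameters above, and a positive integer `class` id (default 1).
#' @param seed integer seed carried alongside the phantom definition for
#'   stochastic companion operations.
#' @return `phantom_spec` returns the validated spec; `make_phantom` returns
#'   `list(mask = volume3d binary, truth = label_volume)`.
#' @examples
#' spec <- phantom_spec(c(32, 32, 32), c(1, 1, 1),
#'                      list(list(kind = "slab", axis = 3, center = 16,
#'                                thickness = 5, class = 1)))
#' ph <- make_phantom(spec)
#' sum(ph$mask$values)  # 32 * 32 * 5
#' @export
phantom_spec <- function(shape, spacing = c(1, 1, 1), primitives = list(),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("phantom_spec: shape must be three positive integers")
  check_spacing(spacing)
  primitives <- lapply(primitives, function(p) {
    # numeric fields may arrive as nested lists from YAML configs
    for (f in c("axis", "center", "thickness", "radius", "from", "to",
                "lo", "hi", "class"))
      if (!is.null(p[[f]])) p[[f]] <- unlist(p[[f]])
    p
  })
  for (p in primitives) {
    if (is.null(p$kind) || !(p$kind %in% c("slab", "cylinder", "ball", "cuboid")))
      stop("phantom_spec: unknown primitive kind: ", p$kind)
    cls <- if (is.null(p$class)) 1L else as.integer(p$class)
    if (cls < 1L) stop("phantom_spec: class ids must be positive")
    check_primitive_fits(p, shape)
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 primitives = primitives, seed = as.integer(seed)),
            class = "phantom_spec")
}

check_primitive_fits <- function(p, shape) {
  inside <- function(coord, ax) coord >= 0 && coord <= shape[ax] - 1
  ok <- switch(p$kind,
    slab = inside(p$center, p$axis),
    cylinder = TRUE,
    ball = all(vapply(1:3, function(ax) inside(p$center[ax], ax), TRUE)),
    cuboid = all(p$lo <= p$hi) && all(p$lo >= 0) && all(p$hi <= shape - 1))
  if (!ok)
    stop("phantom_spec: ", p$kind, " primitive does not fit inside the grid")
  invisible(TRUE)
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  cx <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), dim = d)
  cy <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), dim = d)
  cz <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), dim = d)
  coords <- list(cx, cy, cz)
  truth <- array(0L, dim = d)
  for (p in spec$primitives) {
    cls <- if (is.null(p$class)) 1L else as.integer(p$class)
    inside <- switch(p$kind,
      slab = abs(coords[[p$axis]] - p$center) <= p$thickness / 2,
      cylinder = {
        others <- setdiff(1:3, p$axis)
        dist2 <- (coords[[others[1]]] - p$center[1])^2 +
                 (coords[[others[2]]] - p$center[2])^2
        ok <- dist2 <= p$radius^2
        if (!is.null(p$from)) ok <- ok & coords[[p$axis]] >= p$from
        if (!is.null(p$to)) ok <- ok & coords[[p$axis]] <= p$to
        ok
      },
      ball = (cx - p$center[1])^2 + (cy - p$center[2])^2 +
             (cz - p$center[3])^2 <= p$radius^2,
      cuboid = cx >= p$lo[1] & cx <= p$hi[1] &
               cy >= p$lo[2] & cy <= p$hi[2] &
               cz >= p$lo[3] & cz <= p$hi[3])
    truth[inside] <- cls
  }
  mask <- volume3d((truth > 0) * 1, spacing = spec$spacing)
  cls_present <- setdiff(sort(unique(as.vector(truth))), 0L)
  nm <- stats::setNames(paste0("class_", cls_present), as.character(cls_present))
  list(mask = mask,
       truth = label_volume(truth, spacing = spec$spacing, label_names = nm))
}

#' Corrupt a binary mask with independent voxel flips
#'
#' Flips each voxel independently with probability `p` using a local seeded
#' generator (the global RNG state is left untouched). Identical seeds give
#' bit-identical outputs.
#'
#' @param mask binary [volume3d()].
#' @param p flip probability, `0 <= p < 0.5`.
#' @param seed integer seed.
#' @return a binary [volume3d()].
#' @export
corrupt_mask <- function(mask, p, seed) {
  stopifnot(inherits(mask, "volume3d"), p >= 0, p < 0.5)
  if (!is_binary_volume(mask)) stop("corrupt_mask: mask must be binary")
  if (p == 0) return(mask)
  flips <- with_local_seed(seed, stats::runif(length(mask$values)) < p)
  v <- mask$values
  v[flips] <- 1 - v[flips]
  volume3d(v, spacing = mask$spacing, origin = mask$origin)
}

#' Colourise a phantom label map
#'
#' Renders a class label map as an RGB stack the way the segmentation module
#' expects to see tissue: each voxel receives its class colour (background
#' voxels the background colour) plus independent Gaussian channel noise,
#' rounded and clipped to `[0, 255]`. This emulates colour-separable tissue
#' classes in cryo-section photographs; it does not emulate lighting
#' gradients, specularities or texture.
#'
#' @param truth a [label_volume()] of phantom classes.
#' @param class_colors matrix with one row per class (rownames = class id)
#'   of RGB triples in `[0, 255]`.
#' @param background_color RGB triple for label 0.
#' @param color_noise_sd per-channel Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return an [rgb_volume()].
#' @export
colorize_phantom <- function(truth, class_colors,
                             background_color = c(40, 30, 35),
                             color_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "label_volume"))
  present <- setdiff(sort(unique(as.vector(truth$values))), 0L)
  have <- rownames(class_colors)
  if (is.null(have)) have <- as.character(seq_len(nrow(class_colors)))
  if (!all(as.character(present) %in% have))
    stop("colorize_phantom: missing colour for class ",
         paste(setdiff(as.character(present), have), collapse = ", "))
  d <- vol_dim(truth)
  lut <- matrix(rep(as.numeric(background_color), each = max(c(present, 0L)) + 1L),
                ncol = 3L)
  for (cl in present)
    lut[cl + 1L, ] <- as.numeric(class_colors[match(as.character(cl), have), ])
  v <- truth$values
  out <- array(0, dim = c(d, 3L))
  for (ch in 1:3)
    out[, , , ch] <- lut[v + 1L, ch]
  if (color_noise_sd > 0) {
    noise <- with_local_seed(seed,
      stats::rnorm(length(out), sd = color_noise_sd))
    out <- out + noise
  }
  out <- pmin(pmax(round_half_up(out), 0), 255)
  rgb_volume(array(as.integer(out), dim = c(d, 3L)), spacing = truth$spacing)
}

# internal: evaluate expr under a temporary RNG state; restores global state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
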