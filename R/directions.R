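#' Lattice direction sets for ray casting
#'
#' Enumerates the distinct lattice directions whose integer generator vectors
#' have components in `[-n, n]`. Collinear duplicates are removed, keeping the
#' shortest (primitive) generator, so every direction is represented exactly
#' once. With `antipodal_reduced = TRUE` each `+/-` pair is collapsed to one
#' axis, keeping the lexicographically larger generator of the pair — the form
#' used for chord (thickness) measurements, where both ray arms of an axis are
#' cast anyway. The unreduced form keeps both signs and is required for
#' orientation tensors, where each sampled orientation contributes its own
#' dyadic.
#'
#' `n = 1` gives the 13 axes (26 signed directions) of the voxel
#' neighbourhood; `n = 2` gives 49 axes (98 signed directions) with roughly
#' 13 degrees of angular resolution.
#'
#' @param n positive integer bound on generator components.
#' @param antipodal_reduced collapse `+/-` pairs to single axes? Default `TRUE`.
#' @return a `direction_set`: list with `generators` (m x 3 integer matrix,
#'   lexicographically ordered), `units` (m x 3 matrix of unit vectors) and
#'   `antipodal_reduced` flag.
#' @examples
#' lattice_directions(1)         # 13 axes
#' lattice_directions(1, FALSE)  # 26 signed directions
#' @export
lattice_directions <- function(n, antipodal_reduced = TRUE) {
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("lattice_directions: n must be a positive integer")
  n <- as.integer(n)
  g <- as.matrix(expand.grid(x = -n:n, y = -n:n, z = -n:n))
  g <- g[rowSums(g != 0L) > 0L, , drop = FALSE]
  # primitive generator per direction: divide by gcd of |components|
  gc <- apply(abs(g), 1L, function(v) Reduce(gcd2, v[v > 0L]))
  g <- unique(g / gc)
  storage.mode(g) <- "integer"
  if (antipodal_reduced) {
    keep <- apply(g, 1L, function(v) lex_greater(v, -v))
    g <- g[keep, , drop = FALSE]
  }
  ord <- order(g[, 1], g[, 2], g[, 3])
  g <- g[ord, , drop = FALSE]
  dimnames(g) <- NULL
  units <- g / sqrt(rowSums(g^2))
  structure(list(generators = g, units = units,
                 antipodal_reduced = antipodal_reduced),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("<direction_set> %d %s, max |component| %d\n",
              nrow(x$generators),
              if (x$antipodal_reduced) "axes (antipodal-reduced)" else "signed directions",
              max(abs(x$generators))))
  invisible(x)
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

# lexicographic comparison of integer 3-vectors
lex_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

# internal: validated direction set or error naming the caller
assert_direction_set <- function(x, caller, reduced = NULL) {
  if (!inherits(x, "direction_set"))
    stop(caller, ": 'directions' must be a direction_set (see lattice_directions)")
  if (!is.null(reduced) && x$antipodal_reduced != reduced)
    stop(caller, ": needs ", if (reduced) "an antipodal-reduced" else "an unreduced",
         " direction set")
  x
}
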