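#' Build the geodesic vector scaffold
#'
#' Constructs the fan of unit directions along which binding-site vectors
#' are cast.  A regular icosahedron is subdivided class-I at integer edge
#' frequency `f` (every edge split into `f` segments, faces triangulated)
#' and the resulting vertices are projected radially onto the unit sphere,
#' giving exactly `10 f^2 + 2` distinct directions.  At the default
#' frequency 7 this yields 492 directions; restricting to the hemisphere
#' above the anchor plane (see [restrict_hemisphere()]) leaves 260.
#'
#' The icosahedron is fixed in its standard coordinates (vertices at the
#' cyclic permutations of \eqn{(0, \pm 1, \pm\varphi)}, normalised), so an
#' edge midpoint lies on the +z axis.  With this orientation the f = 7
#' lattice places 28 vertices exactly on the equator, and the default
#' "keep the closed upper hemisphere" rule retains 260 of 492 directions.
#' Directions are sorted canonically (decreasing z, then azimuth), so the
#' same frequency always yields the same ordered list and descriptors
#' indexed on the scaffold are comparable across structures.
#'
#' @param frequency positive integer subdivision frequency (edges per
#'   icosahedron edge).  Default 7.
#' @param max_length maximum vector length in Angstrom (the casting sphere
#'   radius).  Default 20.
#' @return An object of class `svec_scaffold`: a list with elements
#'   `directions` (n x 3 matrix of unit vectors), `max_length`,
#'   `frequency`, and `hemisphere` (logical mask, initially all `TRUE`).
#' @examples
#' sc <- build_scaffold(7, 20)
#' nrow(sc$directions)   # 492
#' @seealso [restrict_hemisphere()], [write_scaffold()]
#' @export
build_scaffold <- function(frequency = 7L, max_length = 20) {
  if (length(frequency) != 1L || is.na(frequency) || frequency < 1 ||
      frequency != round(frequency))
    stop("'frequency' must be a positive integer", call. = FALSE)
  if (length(max_length) != 1L || is.na(max_length) || max_length <= 0)
    stop("'max_length' must be a positive length in Angstrom", call. = FALSE)
  frequency <- as.integer(frequency)

  v <- icosahedron_vertices()
  faces <- icosahedron_faces()
  f <- frequency
  # barycentric lattice on each face, projected to the sphere
  pts <- vector("list", nrow(faces))
  for (r in seq_len(nrow(faces))) {
    A <- v[faces[r, 1L], ]; B <- v[faces[r, 2L], ]; C <- v[faces[r, 3L], ]
    ij <- expand.grid(i = 0:f, j = 0:f)
    ij <- ij[ij$i + ij$j <= f, , drop = FALSE]
    P <- outer(ij$i, A) + outer(ij$j, B) + outer(f - ij$i - ij$j, C)
    pts[[r]] <- P / sqrt(rowSums(P^2))
  }
  P <- do.call(rbind, pts)
  # vertices on shared edges/corners are generated repeatedly; deduplicate
  # on coordinates rounded to 1e-8
  key <- apply(round(P, 8L), 1L, paste, collapse = ",")
  P <- P[!duplicated(key), , drop = FALSE]
  # canonical, orientation-stable order: decreasing z, then azimuth
  az <- atan2(P[, 2L], P[, 1L])
  P <- P[order(-round(P[, 3L], 9L), round(az, 9L)), , drop = FALSE]
  dimnames(P) <- list(NULL, c("x", "y", "z"))

  stopifnot(nrow(P) == 10L * f^2 + 2L)
  structure(
    list(directions = P,
         max_length = max_length,
         frequency  = frequency,
         hemisphere = rep(TRUE, nrow(P))),
    class = "svec_scaffold")
}

# standard-coordinate icosahedron: cyclic permutations of (0, +-1, +-phi),
# normalised.  An edge midpoint points along +z; this orientation puts 28
# of the f = 7 lattice vertices exactly on the equator.
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v / sqrt(rowSums(v^2))
}

icosahedron_faces <- function() {
  matrix(c(1L, 2L, 6L,  1L, 2L, 8L,  1L, 6L, 12L, 1L, 8L, 11L,
           1L, 11L, 12L, 2L, 6L, 10L, 2L, 8L, 9L,  2L, 9L, 10L,
           3L, 4L, 5L,  3L, 4L, 7L,  3L, 5L, 12L, 3L, 7L, 11L,
           3L, 11L, 12L, 4L, 5L, 10L, 4L, 7L, 9L,  4L, 9L, 10L,
           5L, 6L, 10L, 5L, 6L, 12L, 7L, 8L, 9L,  7L, 8L, 11L),
         ncol = 3L, byrow = TRUE)
}

#' Restrict a scaffold to a hemisphere
#'
#' Marks the directions lying in the hemisphere on the positive side of the
#' plane through the origin with normal `plane_normal`.  Indexing of the
#' full direction list is preserved — only the `hemisphere` mask changes —
#' so descriptors computed on the restricted scaffold from different
#' structures remain index-comparable.
#'
#' The default rule (`"equator"`) keeps every direction whose dot product
#' with the normal is `>= -tol`, i.e. the closed upper hemisphere including
#' the equator ring.  For the default frequency-7 scaffold and the +z
#' normal this retains 260 of 492 directions (232 strictly above the plane
#' plus the 28 equatorial ones).  `"strict"` drops the equator ring;
#' `"all"` clears the restriction.
#'
#' @param scaffold an `svec_scaffold`.
#' @param plane_normal 3-vector normal of the anchor plane (need not be
#'   unit length; must be nonzero).  Default `c(0, 0, 1)`.
#' @param rule `"equator"` (closed hemisphere, default), `"strict"`
#'   (open hemisphere), or `"all"` (no restriction).
#' @param tol numeric tolerance for membership of the equator ring.
#' @return the scaffold with its `hemisphere` mask set.
#' @examples
#' sc <- restrict_hemisphere(build_scaffold(7, 20))
#' sum(sc$hemisphere)   # 260
#' @export
restrict_hemisphere <- function(scaffold, plane_normal = c(0, 0, 1),
                                rule = c("equator", "strict", "all"),
                                tol = 1e-9) {
  stopifnot(inherits(scaffold, "svec_scaffold"))
  rule <- match.arg(rule)
  nrm <- sqrt(sum(plane_normal^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("'plane_normal' must be a nonzero 3-vector", call. = FALSE)
  n <- plane_normal / nrm
  dp <- drop(scaffold$directions %*% n)
  scaffold$hemisphere <- switch(rule,
    equator = dp >= -tol,
    strict  = dp > tol,
    all     = rep(TRUE, length(dp)))
  scaffold
}

#' Indices of the retained scaffold directions
#'
#' @param scaffold an `svec_scaffold`.
#' @return integer vector of direction indices for which the hemisphere
#'   mask is `TRUE` (all indices if no restriction was applied).
#' @export
retained_indices <- function(scaffold) {
  stopifnot(inherits(scaffold, "svec_scaffold"))
  which(scaffold$hemisphere)
}

#' @export
print.svec_scaffold <- function(x, ...) {
  cat("Binding-site vector scaffold\n")
  cat(sprintf("  frequency : %d  (class-I geodesic, %d directions)\n",
              x$frequency, nrow(x$directions)))
  cat(sprintf("  max length: %g Angstrom\n", x$max_length))
  cat(sprintf("  retained  : %d of %d directions\n",
              sum(x$hemisphere), nrow(x$directions)))
  invisible(x)
}

#' Write / read a scaffold as TSV
#'
#' Plain tabular exchange format: one row per direction with columns
#' `index`, `x`, `y`, `z`, `max_length`, `in_hemisphere`.
#'
#' @param scaffold an `svec_scaffold`.
#' @param path file path.
#' @param retained_only write only the hemisphere-retained rows.
#' @return `write_scaffold()` returns `path` invisibly; `read_scaffold()`
#'   returns an `svec_scaffold` (with `frequency` recovered from the row
#'   count when the full sphere is present, `NA` otherwise).
#' @export
write_scaffold <- function(scaffold, path, retained_only = FALSE) {
  stopifnot(inherits(scaffold, "svec_scaffold"))
  keep <- if (retained_only) scaffold$hemisphere else rep(TRUE, nrow(scaffold$directions))
  df <- data.frame(index = which(keep),
                   x = scaffold$directions[keep, 1L],
                   y = scaffold$directions[keep, 2L],
                   z = scaffold$directions[keep, 3L],
                   max_length = scaffold$max_length,
                   in_hemisphere = scaffold$hemisphere[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaffold
#' @export
read_scaffold <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("index", "x", "y", "z", "max_length", "in_hemisphere")
  if (!all(need %in% names(df)))
    stop("scaffold file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(df)
  f <- sqrt((n - 2) / 10)
  structure(
    list(directions = as.matrix(df[, c("x", "y", "z")]),
         max_length = df$max_length[1L],
         frequency  = if (abs(f - round(f)) < 1e-12) as.integer(round(f)) else NA_integer_,
         hemisphere = as.logical(df$in_hemisphere)),
    class = "svec_scaffold")
}
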