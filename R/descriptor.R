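#' Ray / atom-sphere intersection
#'
#' Core geometric primitive.  For a ray from `origin` along unit vector
#' `direction` and an atom modelled as a hard sphere of its van der Waals
#' radius: with \eqn{a = |c - o|} the origin-to-center distance,
#' \eqn{b = (c - o)\cdot u} the projection of that vector on the ray and
#' \eqn{y = \sqrt{a^2 - b^2}} the perpendicular distance from the center
#' to the ray, the ray misses the sphere when \eqn{y > r}; otherwise it
#' enters at \eqn{c_{in} = b - \sqrt{r^2 - y^2}} and exits at
#' \eqn{c_{out} = b + \sqrt{r^2 - y^2}}.
#'
#' @param direction unit 3-vector.
#' @param center atom center (3-vector, Angstrom).
#' @param radius atom van der Waals radius (Angstrom).
#' @param origin ray origin (default the coordinate origin).
#' @return `NULL` if the ray misses the sphere or the sphere lies
#'   entirely behind the origin; otherwise `c(entry, exit)` in Angstrom
#'   along the ray (entry may be negative when the origin is inside the
#'   sphere).
#' @export
intersect_ray_sphere <- function(direction, center, radius,
                                 origin = c(0, 0, 0)) {
  if (abs(sum(direction^2) - 1) > 1e-6)
    stop("'direction' must be a unit vector", call. = FALSE)
  v <- center - origin
  b <- sum(v * direction)
  y2 <- sum(v * v) - b^2
  disc <- radius^2 - y2
  if (disc < 0) return(NULL)
  s <- sqrt(disc)
  if (b + s <= 0) return(NULL)      # sphere entirely behind the origin
  c(entry = b - s, exit = b + s)
}

# vectorised entry/exit over all (atom, direction) pairs.
# returns list(entry, exit): n_atoms x n_dir matrices, NA where no hit.
ray_sphere_grid <- function(centers, radii, dirs, origin) {
  V <- sweep(centers, 2L, origin)
  b <- V %*% t(dirs)                              # natoms x ndir
  a2 <- rowSums(V^2)
  disc <- radii^2 - (a2 - b^2)
  hit <- disc >= 0
  s <- sqrt(pmax(disc, 0))
  entry <- ifelse(hit, b - s, NA_real_)
  exit  <- ifelse(hit, b + s, NA_real_)
  list(entry = entry, exit = exit)
}

#' Trace binding-site vectors
#'
#' Casts one ray per retained scaffold direction from `origin` and
#' truncates it at the first van der Waals surface met: among all
#' non-excluded atoms whose entry distance is positive and no larger than
#' the scaffold's maximum length, the smallest entry distance wins (ties
#' broken by lowest atom index).  The vector takes that length and the
#' winning atom's partial charge.  A ray that hits nothing keeps the full
#' maximum length and charge zero.  Atoms whose surface starts at or
#' behind the origin (entry <= 0) are skipped — an atom overlapping the
#' anchor would yield nonphysical lengths; exclude such groups (the heme)
#' explicitly via `exclude` or [mark_excluded()].
#'
#' @param structure an `svec_structure` with radii and charges assigned.
#' @param scaffold an `svec_scaffold` (hemisphere-restricted or not).
#' @param origin anchor point, default the coordinate origin (where the
#'   reference frame puts the anchor atom).
#' @param exclude logical vector over atoms, a predicate
#'   `function(atoms_df) -> logical`, or `NULL` to use the structure's
#'   `excluded` flags.
#' @return An object of class `svec_descriptor`: list with
#'   `structure_id`, `frame_index`, `vector_index` (scaffold indices of
#'   the retained directions), `lengths` (Angstrom), `charges` (e),
#'   `hit_atom` (atom row index, `NA` for misses) and `max_length`.
#' @export
trace_site <- function(structure, scaffold, origin = c(0, 0, 0),
                       exclude = NULL) {
  stopifnot(inherits(structure, "svec_structure"),
            inherits(scaffold, "svec_scaffold"))
  a <- structure$atoms
  if (anyNA(a$radius))
    stop("structure has unassigned radii; call assign_radii() first",
         call. = FALSE)
  if (anyNA(a$charge))
    stop("structure has unassigned charges; call assign_charges() first",
         call. = FALSE)
  if (!all(is.finite(origin)) || length(origin) != 3L)
    stop("'origin' must be a finite 3-vector", call. = FALSE)

  excl <- if (is.null(exclude)) a$excluded
          else if (is.function(exclude)) exclude(a)
          else as.logical(exclude)
  keep <- which(!excl)
  ridx <- retained_indices(scaffold)
  dirs <- scaffold$directions[ridx, , drop = FALSE]
  L <- scaffold$max_length
  m <- length(ridx)

  lengths <- rep(L, m)
  charges <- numeric(m)
  hit_atom <- rep(NA_integer_, m)

  if (length(keep) > 0L) {
    g <- ray_sphere_grid(as.matrix(a[keep, c("x", "y", "z")]),
                         a$radius[keep], dirs, origin)
    entry <- g$entry
    entry[!is.na(entry) & (entry <= 0 | entry > L)] <- NA_real_
    for (k in seq_len(m)) {
      ek <- entry[, k]
      if (all(is.na(ek))) next
      w <- which.min(ek)                 # first index among exact ties
      lengths[k] <- ek[w]
      charges[k] <- a$charge[keep[w]]
      hit_atom[k] <- keep[w]
    }
  }
  structure(list(structure_id = structure$id,
                 frame_index = structure$frame_index,
                 vector_index = ridx,
                 lengths = lengths,
                 charges = charges,
                 hit_atom = hit_atom,
                 max_length = L),
            class = "svec_descriptor")
}

#' Trace ligand vectors
#'
#' The companion descriptor of a bound ligand: the same rays as the site
#' vectors, but terminated at the ligand surface point *farthest* from
#' the origin — per direction, the largest exit distance over all ligand
#' atoms the ray intersects (clamped to the scaffold's maximum length).
#' Rays that miss the ligand get length 0 and `hit` `FALSE`.  The charge
#' of the atom providing the farthest exit is recorded for
#' complementarity diagnostics; the geometric pose criterion
#' ([pose_compatible()]) does not use it.
#'
#' @param ligand an `svec_structure` of the ligand with radii assigned
#'   (charges optional; unassigned charges are treated as 0).
#' @param scaffold an `svec_scaffold`.
#' @param origin anchor point (same as used for the site descriptor).
#' @return An object of class `svec_ligand_descriptor`: list with
#'   `ligand_id`, `vector_index`, `lengths`, `charges`, `hit`,
#'   `max_length`.
#' @export
trace_ligand <- function(ligand, scaffold, origin = c(0, 0, 0)) {
  stopifnot(inherits(ligand, "svec_structure"),
            inherits(scaffold, "svec_scaffold"))
  a <- ligand$atoms
  if (anyNA(a$radius))
    stop("ligand has unassigned radii; call assign_radii() first",
         call. = FALSE)
  q <- ifelse(is.na(a$charge), 0, a$charge)
  ridx <- retained_indices(scaffold)
  dirs <- scaffold$directions[ridx, , drop = FALSE]
  L <- scaffold$max_length
  m <- length(ridx)

  g <- ray_sphere_grid(as.matrix(a[, c("x", "y", "z")]), a$radius, dirs,
                       origin)
  exit <- g$exit
  exit[!is.na(exit) & exit <= 0] <- NA_real_   # sphere behind the origin

  lengths <- numeric(m)
  charges <- numeric(m)
  hit <- logical(m)
  for (k in seq_len(m)) {
    ek <- exit[, k]
    if (all(is.na(ek))) next
    w <- which.max(ek)
    hit[k] <- TRUE
    lengths[k] <- min(ek[w], L)
    charges[k] <- q[w]
  }
  structure(list(ligand_id = ligand$id,
                 vector_index = ridx,
                 lengths = lengths,
                 charges = charges,
                 hit = hit,
                 max_length = L),
            class = "svec_ligand_descriptor")
}

#' @export
print.svec_descriptor <- function(x, ...) {
  nh <- sum(!is.na(x$hit_atom))
  cat(sprintf("Site descriptor '%s' (frame %d): %d vectors, %d hits\n",
              x$structure_id, x$frame_index, length(x$lengths), nh))
  cat(sprintf("  lengths: %.2f - %.2f A (max %.2f)\n",
              min(x$lengths), max(x$lengths), x$max_length))
  invisible(x)
}

#' @export
summary.svec_descriptor <- function(object, ...) {
  hits <- !is.na(object$hit_atom)
  out <- list(structure_id = object$structure_id,
              n_vectors = length(object$lengths),
              n_hits = sum(hits),
              mean_length = mean(object$lengths),
              mean_charge = mean(object$charges))
  class(out) <- "summary.svec_descriptor"
  out
}

#' @export
print.summary.svec_descriptor <- function(x, ...) {
  cat(sprintf(
    "Site descriptor '%s': %d vectors (%d hits), mean length %.2f A, mean charge %+.3f e\n",
    x$structure_id, x$n_vectors, x$n_hits, x$mean_length, x$mean_charge))
  invisible(x)
}

#' @export
print.svec_ligand_descriptor <- function(x, ...) {
  cat(sprintf("Ligand descriptor '%s': %d vectors, %d intersect the ligand\n",
              x$ligand_id, length(x$lengths), sum(x$hit)))
  invisible(x)
}

#' Polar plot of a site descriptor
#'
#' Quick diagnostic: vector length against direction azimuth, coloured by
#' charge sign, for the retained hemisphere.
#'
#' @param x an `svec_descriptor`.
#' @param scaffold the scaffold the descriptor was traced on.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.svec_descriptor <- function(x, scaffold, ...) {
  dirs <- scaffold$directions[x$vector_index, , drop = FALSE]
  az <- atan2(dirs[, 2L], dirs[, 1L])
  col <- ifelse(x$charges > 0, "firebrick",
                ifelse(x$charges < 0, "steelblue", "grey40"))
  graphics::plot(az, x$lengths, col = col, pch = 16,
                 xlab = "azimuth (rad)", ylab = "vector length (A)",
                 main = x$structure_id, ...)
  invisible(x)
}

#' Write / read descriptors as TSV
#'
#' Long tabular format, one row per vector: `vector_index`, `x`, `y`,
#' `z` (direction), `length_A`, `charge_e`, `hit_atom`.  Site and ligand
#' descriptors share the format; ligand files carry `hit_atom` as 0/1
#' hit flags.
#'
#' @param descriptor an `svec_descriptor` or `svec_ligand_descriptor`.
#' @param scaffold the matching `svec_scaffold` (for the direction
#'   columns).
#' @param path file path.
#' @return `write_descriptor()`: `path` invisibly.  `read_descriptor()`:
#'   an `svec_descriptor`.
#' @export
write_descriptor <- function(descriptor, scaffold, path) {
  dirs <- scaffold$directions[descriptor$vector_index, , drop = FALSE]
  hit <- if (inherits(descriptor, "svec_ligand_descriptor"))
    as.integer(descriptor$hit) else descriptor$hit_atom
  df <- data.frame(vector_index = descriptor$vector_index,
                   x = dirs[, 1L], y = dirs[, 2L], z = dirs[, 3L],
                   length_A = descriptor$lengths,
                   charge_e = descriptor$charges,
                   hit_atom = hit)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor
#' @param id structure id to attach on read.
#' @param max_length maximum vector length to attach on read (default:
#'   the largest length in the file).
#' @export
read_descriptor <- function(path, id = NULL, max_length = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(
    structure_id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
    frame_index = 1L,
    vector_index = df$vector_index,
    lengths = df$length_A,
    charges = df$charge_e,
    hit_atom = df$hit_atom,
    max_length = if (is.null(max_length)) max(df$length_A) else max_length),
    class = "svec_descriptor")
}
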