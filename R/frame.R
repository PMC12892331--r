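#' Compute the anchor reference frame
#'
#' All descriptors are compared per vector index, so every structure must
#' sit in one common frame: the anchor atom (for cytochromes P450, the
#' heme iron) at the coordinate origin and the anchor plane (the heme)
#' in the xy-plane with its normal along +z.  This function derives the
#' rigid transform that puts a structure into that frame.
#'
#' The plane is the least-squares plane through the plane-defining atoms
#' (default: the four pyrrole nitrogens NA/NB/NC/ND of the anchor residue
#' when present, otherwise all non-hydrogen atoms of that residue).  The
#' sign of the normal is chosen so that the `above` selection — default
#' the whole-structure centroid, i.e. the protein body — ends up at
#' positive z.  The rotation is the minimal (smallest-angle) proper
#' rotation taking the plane normal to +z, which makes the frame
#' deterministic.
#'
#' @param structure an `svec_structure`.
#' @param anchor named list passed to [select_atoms()] selecting exactly
#'   one atom (default the heme iron, `list(resname = c("HEM","HEC"),
#'   name = "FE")`).
#' @param plane named list selecting at least 3 non-collinear atoms, or
#'   `NULL` for the default described above.
#' @param above optional named list selecting atoms whose centroid must
#'   map to positive z; `NULL` uses the structure centroid.
#' @return An object of class `svec_frame`: list with `rotation` (3 x 3
#'   proper orthonormal matrix) and `translation` (3-vector), applied as
#'   `x' = R x + t`.
#' @seealso [apply_frame()]
#' @export
compute_reference_frame <- function(structure,
                                    anchor = list(resname = c("HEM", "HEC"),
                                                  name = "FE"),
                                    plane = NULL, above = NULL) {
  stopifnot(inherits(structure, "svec_structure"))
  xyz <- coords_of(structure)
  ai <- which(do.call(select_atoms, c(list(structure), anchor)))
  if (length(ai) == 0L)
    stop("anchor selection matched no atom", call. = FALSE)
  if (length(ai) > 1L)
    stop("anchor selection matched ", length(ai), " atoms; need exactly one",
         call. = FALSE)
  anchor_xyz <- xyz[ai, ]

  if (is.null(plane)) {
    res <- structure$atoms$resname[ai]
    rid <- structure$atoms$resid[ai]
    pyr <- select_atoms(structure, resname = res, resid = rid,
                        name = c("NA", "NB", "NC", "ND"))
    if (sum(pyr) >= 3L) {
      pi_ <- which(pyr)
    } else {
      heavy <- select_atoms(structure, resname = res, resid = rid) &
        structure$atoms$element != "H" & structure$atoms$name != "FE"
      pi_ <- which(heavy)
    }
  } else {
    pi_ <- which(do.call(select_atoms, c(list(structure), plane)))
  }
  if (length(pi_) < 3L)
    stop("plane selection matched fewer than 3 atoms", call. = FALSE)
  P <- sweep(xyz[pi_, , drop = FALSE], 2L, colMeans(xyz[pi_, , drop = FALSE]))
  sv <- svd(P)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1))
    stop("plane-defining atoms are collinear", call. = FALSE)
  normal <- sv$v[, 3L]

  ref_pt <- if (is.null(above)) colMeans(xyz) else {
    bi <- which(do.call(select_atoms, c(list(structure), above)))
    if (length(bi) == 0L) stop("'above' selection matched no atom",
                               call. = FALSE)
    colMeans(xyz[bi, , drop = FALSE])
  }
  if (sum((ref_pt - anchor_xyz) * normal) < 0) normal <- -normal

  R <- rotation_to_z(normal)
  structure(list(rotation = R, translation = -drop(R %*% anchor_xyz)),
            class = "svec_frame")
}

# minimal proper rotation taking unit vector n to +z (Rodrigues)
rotation_to_z <- function(n) {
  n <- n / sqrt(sum(n^2))
  z <- c(0, 0, 1)
  ax <- c(n[2L], -n[1L], 0)            # n x z
  s <- sqrt(sum(ax^2))
  cth <- n[3L]
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))         # n = -z: half-turn about x
  }
  ax <- ax / s
  K <- matrix(c(0, -ax[3L], ax[2L],
                ax[3L], 0, -ax[1L],
                -ax[2L], ax[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3) + s * K + (1 - cth) * (K %*% K)
}

#' Apply a reference frame to a structure
#'
#' @param structure an `svec_structure`.
#' @param frame an `svec_frame` from [compute_reference_frame()].
#' @return the structure with transformed coordinates.
#' @export
apply_frame <- function(structure, frame) {
  stopifnot(inherits(structure, "svec_structure"),
            inherits(frame, "svec_frame"))
  xyz <- coords_of(structure)
  new <- sweep(xyz %*% t(frame$rotation), 2L, -frame$translation)
  set_coords(structure, new)
}

#' @export
print.svec_frame <- function(x, ...) {
  cat("Reference frame (x' = R x + t)\n")
  cat("  rotation determinant:", round(det(x$rotation), 6), "\n")
  cat("  translation:", paste(sprintf("%.3f", x$translation), collapse = " "),
      "\n")
  invisible(x)
}

#' Least-squares rigid superposition
#'
#' Superposes `mobile` onto `reference` by the proper rotation +
#' translation minimising the positional RMSD over a matched atom
#' selection (default: backbone atoms N, CA, C, O), using the
#' least-squares fit of [bio3d::rot.lsq()].  The whole mobile structure
#' is transformed; the returned RMSD is over the selection.
#'
#' Atoms are paired by order of appearance within the selection, so the
#' two structures must present the selected atoms in the same order
#' (true for frames of one trajectory or copies of one chain).
#'
#' @param mobile,reference `svec_structure` objects.
#' @param selection atom-name vector, or a named list for
#'   [select_atoms()].
#' @return list with `structure` (transformed mobile) and `rmsd`
#'   (Angstrom, over the selection).
#' @export
superpose <- function(mobile, reference, selection = c("N", "CA", "C", "O")) {
  stopifnot(inherits(mobile, "svec_structure"),
            inherits(reference, "svec_structure"))
  sel <- function(st) {
    if (is.list(selection)) do.call(select_atoms, c(list(st), selection))
    else select_atoms(st, name = selection)
  }
  mi <- which(sel(mobile)); ri <- which(sel(reference))
  if (length(mi) != length(ri))
    stop("selection sizes differ (", length(mi), " vs ", length(ri),
         "); cannot pair atoms", call. = FALSE)
  if (length(mi) < 3L)
    stop("need at least 3 matched atoms for superposition", call. = FALSE)

  mx <- coords_of(mobile)
  rx <- coords_of(reference)
  fitmask <- rep(FALSE, nrow(mx)); fitmask[mi] <- TRUE
  refmask <- rep(FALSE, nrow(rx)); refmask[ri] <- TRUE
  xx <- as.vector(t(mx))                     # x1 y1 z1 x2 ...
  yy <- as.vector(t(rx))
  new <- bio3d::rot.lsq(xx, yy,
                        xfit = rep(fitmask, each = 3L),
                        yfit = rep(refmask, each = 3L))
  new <- matrix(new, ncol = 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((new[mi, , drop = FALSE] -
                             rx[ri, , drop = FALSE])^2)))
  list(structure = set_coords(mobile, new), rmsd = rmsd)
}
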