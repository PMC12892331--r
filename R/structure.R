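#' Read a structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] returning the atom table used
#' throughout the package.  Elements are taken from PDB columns 77-78 when
#' present, otherwise inferred from the atom name.  Multi-model files
#' (e.g. NMR or trajectory snapshots) are addressed with `model_index`;
#' use [read_ensemble()] to load every model at once.
#'
#' @param path path to a PDB file.
#' @param model_index 1-based model number for multi-model files
#'   (default 1).
#' @param drop_solvent drop water and monoatomic-ion residues
#'   (default `TRUE`).
#' @param id structure identifier; defaults to the file name without
#'   extension.
#' @return An object of class `svec_structure`: a list with `id`,
#'   `frame_index` and `atoms`, a data.frame with one row per atom
#'   (columns `element`, `name`, `resname`, `resid`, `x`, `y`, `z`,
#'   `radius`, `charge`, `excluded`, `backbone`).  Radii and charges are
#'   `NA` until assigned with [assign_radii()] / [assign_charges()].
#' @export
read_structure <- function(path, model_index = 1L, drop_solvent = TRUE,
                           id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod)) nmod <- 1L
  if (model_index < 1L || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ", nmod,
         " model", if (nmod > 1L) "s", ")", call. = FALSE)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else pdb$xyz
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty model: no ATOM/HETATM records", call. = FALSE)
  st <- new_structure(
    id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
    frame_index = as.integer(model_index),
    element = infer_elements(at$elesy, at$elety),
    name    = trimws(at$elety),
    resname = trimws(at$resid),
    resid   = at$resno,
    coords  = matrix(xyz, ncol = 3L, byrow = TRUE))
  if (drop_solvent) {
    solv <- st$atoms$resname %in% c("HOH", "WAT", "SOL", "DOD", "TIP3",
                                    "NA", "CL", "K", "MG", "ZN", "MN",
                                    "IOD", "BR", "CS", "LI")
    if (all(solv)) stop("empty model after removing solvent/ions",
                        call. = FALSE)
    st$atoms <- st$atoms[!solv, , drop = FALSE]
    rownames(st$atoms) <- NULL
  }
  st
}

#' Read every model of a multi-model PDB as an ensemble
#'
#' @inheritParams read_structure
#' @return list of `svec_structure`, one per model, with `frame_index`
#'   set to the model number.
#' @export
read_ensemble <- function(path, drop_solvent = TRUE, id = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  lapply(seq_len(nmod), function(m)
    read_structure(path, model_index = m, drop_solvent = drop_solvent, id = id))
}

#' Construct a structure from raw fields
#'
#' Low-level constructor used by the readers and the synthetic-cavity
#' generators.
#'
#' @param id structure identifier.
#' @param element,name,resname,resid per-atom vectors.
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param frame_index integer frame/model index.
#' @param radius,charge optional per-atom vectors (recycled).
#' @return an `svec_structure`.
#' @export
new_structure <- function(id, element, name, resname, resid, coords,
                          frame_index = 1L, radius = NA_real_,
                          charge = NA_real_) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) stop("structure must contain at least one atom", call. = FALSE)
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  atoms <- data.frame(
    element = toupper(as.character(element)),
    name    = as.character(name),
    resname = as.character(resname),
    resid   = as.integer(resid),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    radius = rep_len(radius, n),
    charge = rep_len(charge, n),
    excluded = FALSE,
    stringsAsFactors = FALSE)
  atoms$backbone <- atoms$name %in% c("N", "CA", "C", "O")
  structure(list(id = as.character(id),
                 frame_index = as.integer(frame_index),
                 atoms = atoms),
            class = "svec_structure")
}

infer_elements <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the atom name: strip digits/primes, handle leading digit
    nm <- toupper(gsub("[0-9']", "", trimws(elety[miss])))
    two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "CU")
    el[miss] <- ifelse(substr(nm, 1L, 2L) %in% two,
                       substr(nm, 1L, 2L), substr(nm, 1L, 1L))
  }
  el
}

coords_of <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, coords) {
  structure$atoms$x <- coords[, 1L]
  structure$atoms$y <- coords[, 2L]
  structure$atoms$z <- coords[, 3L]
  structure
}

#' @export
print.svec_structure <- function(x, ...) {
  cat(sprintf("svec_structure '%s' (frame %d): %d atoms, %d residues\n",
              x$id, x$frame_index, nrow(x$atoms),
              length(unique(paste(x$atoms$resname, x$atoms$resid)))))
  if (all(is.na(x$atoms$radius))) cat("  radii: unassigned\n")
  if (all(is.na(x$atoms$charge))) cat("  charges: unassigned\n")
  invisible(x)
}

#' Select atoms by fields
#'
#' @param structure an `svec_structure`.
#' @param name,resname,resid,element optional vectors of values to match;
#'   `NULL` matches everything.
#' @return logical vector over atoms.
#' @export
select_atoms <- function(structure, name = NULL, resname = NULL,
                         resid = NULL, element = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resid))   keep <- keep & a$resid %in% resid
  if (!is.null(element)) keep <- keep & a$element %in% toupper(element)
  keep
}

#' Assign van der Waals radii
#'
#' Looks every atom's element up in an element -> radius table.  Unknown
#' elements take `fallback` (with a warning listing them); with
#' `fallback = NULL` unknown elements are an error.
#'
#' @param structure an `svec_structure`.
#' @param table named numeric vector (element -> Angstrom); default the
#'   packaged table from [default_radius_table()].
#' @param fallback radius for elements absent from the table, or `NULL`
#'   to forbid them.
#' @return the structure with `atoms$radius` filled in.  Coordinates and
#'   atom order are untouched.
#' @export
assign_radii <- function(structure, table = default_radius_table(),
                         fallback = NULL) {
  stopifnot(inherits(structure, "svec_structure"))
  el <- structure$atoms$element
  r <- unname(table[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    missing_el <- sort(unique(el[unknown]))
    if (is.null(fallback))
      stop("no van der Waals radius for element(s): ",
           paste(missing_el, collapse = ", "), call. = FALSE)
    warning("fallback radius ", fallback, " A used for element(s): ",
            paste(missing_el, collapse = ", "), call. = FALSE)
    r[unknown] <- fallback
  }
  structure$atoms$radius <- r
  structure
}

#' Assign partial charges
#'
#' Matches atoms against a (residue name, atom name) -> charge table.
#' Exact residue matches win over wildcard (`*`) residue entries; atoms
#' matched by neither take `fallback` (default 0 e).  The fraction of
#' unmatched atoms is reported as a message.
#'
#' @param structure an `svec_structure`.
#' @param table data.frame with columns `residue_name`, `atom_name`,
#'   `charge_e`; default [default_charge_table()].
#' @param fallback charge (e) for unmatched atoms.
#' @param quiet suppress the unmatched-fraction message.
#' @return the structure with `atoms$charge` filled in, plus attribute
#'   `n_unmatched` on the return value's atoms data.frame omitted;
#'   the unmatched count is available as `attr(result, "n_unmatched")`.
#' @export
assign_charges <- function(structure, table = default_charge_table(),
                           fallback = 0, quiet = FALSE) {
  stopifnot(inherits(structure, "svec_structure"))
  a <- structure$atoms
  key_exact <- paste(a$resname, a$name, sep = "\r")
  tab_exact <- stats::setNames(table$charge_e,
                               paste(table$residue_name, table$atom_name,
                                     sep = "\r"))
  wild <- table$residue_name == "*"
  tab_wild <- stats::setNames(table$charge_e[wild], table$atom_name[wild])
  q <- unname(tab_exact[key_exact])
  usew <- is.na(q)
  q[usew] <- unname(tab_wild[a$name[usew]])
  unmatched <- is.na(q)
  q[unmatched] <- fallback
  if (!quiet && any(unmatched))
    message(sum(unmatched), " of ", length(q),
            " atoms had no charge-table entry; fallback ", fallback,
            " e assigned")
  structure$atoms$charge <- q
  attr(structure, "n_unmatched") <- sum(unmatched)
  structure
}

#' Mark atoms excluded from site tracing
#'
#' Vectors are traced against non-excluded atoms only.  By default the
#' heme group is excluded (tracing against it would give degenerate,
#' near-zero vectors from an anchor at the heme iron).
#'
#' @param structure an `svec_structure`.
#' @param resnames residue names to exclude (default `c("HEM", "HEC")`).
#' @return the structure with `atoms$excluded` set.
#' @export
mark_excluded <- function(structure, resnames = c("HEM", "HEC")) {
  stopifnot(inherits(structure, "svec_structure"))
  structure$atoms$excluded <- structure$atoms$resname %in% resnames
  structure
}

#' Write a structure back to PDB
#'
#' @param structure an `svec_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords_of(structure))),
                   resno = a$resid, resid = a$resname, elety = a$name,
                   elesy = a$element)
  invisible(path)
}
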