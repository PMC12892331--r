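#' Packaged van der Waals radius table
#'
#' Element-based hard-sphere radii (Angstrom), Bondi-type values, used to
#' define the atomic surfaces that truncate binding-site vectors.  Metals
#' not covered by the Bondi set (notably Fe) carry documented conventional
#' values.  Override any entry by supplying your own table to
#' [assign_radii()] or [read_radius_table()].
#'
#' @return named numeric vector, names are upper-case element symbols,
#'   values radii in Angstrom.
#' @export
default_radius_table <- function() {
  path <- system.file("extdata", "vdw_radii.tsv", package = "sitevec",
                      mustWork = TRUE)
  read_radius_table(path)
}

#' Read a radius table from TSV
#'
#' Two tab-separated columns with a header: `element`, `radius_A`.
#'
#' @param path file path.
#' @return named numeric vector (element -> Angstrom).
#' @export
read_radius_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("element", "radius_A") %in% names(df)))
    stop("radius table needs columns 'element' and 'radius_A'", call. = FALSE)
  if (any(df$radius_A <= 0)) stop("radii must be positive", call. = FALSE)
  stats::setNames(df$radius_A, toupper(df$element))
}

#' Packaged partial-charge table
#'
#' A simplified per-(residue, atom) partial-charge table in elementary
#' charge units, in the spirit of united-atom force-field charge groups:
#' backbone amide/carbonyl dipoles, charged and polar side-chain termini,
#' and the heme iron/pyrrole nitrogens.  Apolar carbons default to zero.
#' The wildcard residue `*` matches any residue name.  The table is
#' intentionally compact — the descriptor only requires consistent per-atom
#' charges — and can be replaced wholesale with a force-field table in the
#' same format via [read_charge_table()].
#'
#' @return data.frame with columns `residue_name`, `atom_name`, `charge_e`.
#' @export
default_charge_table <- function() {
  path <- system.file("extdata", "charges_default.tsv", package = "sitevec",
                      mustWork = TRUE)
  read_charge_table(path)
}

#' Read a partial-charge table from TSV
#'
#' Three tab-separated columns with a header: `residue_name`, `atom_name`,
#' `charge_e`.  `residue_name` may be `*` to match all residues; exact
#' residue matches take precedence over wildcard matches.
#'
#' @param path file path.
#' @return data.frame with columns `residue_name`, `atom_name`, `charge_e`.
#' @export
read_charge_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("residue_name", "atom_name", "charge_e") %in% names(df)))
    stop("charge table needs columns 'residue_name', 'atom_name', 'charge_e'",
         call. = FALSE)
  df
}
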