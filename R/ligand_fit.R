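#' Binary ligand-pose compatibility criterion
#'
#' Tests whether a ligand's vector envelope fits inside a site's vector
#' envelope.  Only the vectors that actually intersect the ligand are
#' considered.  A considered vector is a *violation* when the ligand
#' vector is longer than the site vector, i.e. the ligand protrudes past
#' the pocket surface along that direction.  The pose is accepted iff
#' every protrusion is at most `slack` Angstrom *and* the violating
#' fraction is at most `max_violation_fraction`.  The defaults (10% of
#' the ligand vectors, 1 Angstrom) reproduce the published screening
#' criterion.
#'
#' @param ligand an `svec_ligand_descriptor`.
#' @param site an `svec_descriptor` on the same scaffold.
#' @param max_violation_fraction maximum allowed fraction of considered
#'   vectors that may protrude (default 0.10).
#' @param slack maximum allowed per-vector protrusion in Angstrom
#'   (default 1.0).
#' @return list with `accept` (logical), `n_violations`, `n_considered`
#'   and `max_protrusion` (Angstrom).
#' @export
pose_compatible <- function(ligand, site, max_violation_fraction = 0.10,
                            slack = 1.0) {
  stopifnot(inherits(ligand, "svec_ligand_descriptor"),
            inherits(site, "svec_descriptor"))
  if (!identical(ligand$vector_index, site$vector_index))
    stop("ligand and site descriptors are on different scaffolds",
         call. = FALSE)
  considered <- which(ligand$hit)
  if (length(considered) == 0L)
    stop("undefined pose: the ligand intersects none of the vectors",
         call. = FALSE)
  protrusion <- ligand$lengths[considered] - site$lengths[considered]
  viol <- protrusion > 0
  n_viol <- sum(viol)
  max_prot <- if (n_viol > 0L) max(protrusion[viol]) else 0
  accept <- (max_prot <= slack) &&
    (n_viol / length(considered) <= max_violation_fraction)
  list(accept = accept, n_violations = n_viol,
       n_considered = length(considered), max_protrusion = max_prot)
}

#' Screen a conformational ensemble against a ligand pose
#'
#' Applies [pose_compatible()] to every site descriptor (one per frame)
#' and reports which frames can geometrically accommodate the pose.
#'
#' @param ligand an `svec_ligand_descriptor`.
#' @param sites list of `svec_descriptor` on the common scaffold.
#' @inheritParams pose_compatible
#' @return list with `n_accepted`, `accepted` (frame indices) and
#'   `table` (data.frame: frame, structure_id, accept, n_violations,
#'   n_considered, max_protrusion).
#' @export
screen_ensemble <- function(ligand, sites, max_violation_fraction = 0.10,
                            slack = 1.0) {
  rows <- lapply(seq_along(sites), function(i) {
    r <- pose_compatible(ligand, sites[[i]], max_violation_fraction, slack)
    data.frame(frame = i, structure_id = sites[[i]]$structure_id,
               accept = r$accept, n_violations = r$n_violations,
               n_considered = r$n_considered,
               max_protrusion = r$max_protrusion)
  })
  tab <- do.call(rbind, rows)
  list(n_accepted = sum(tab$accept), accepted = which(tab$accept),
       table = tab)
}
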