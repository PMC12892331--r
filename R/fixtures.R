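#' Synthetic hemispherical cavity with known geometry
#'
#' Places identical hard-sphere atoms on a spherical shell of radius
#' `pocket_radius` centred on the origin, covering the upper hemisphere
#' (plus a small angular margin below the equator so that equatorial
#' rays of a hemisphere scaffold are also covered).  Atoms sit on a
#' Fibonacci lattice, giving near-uniform coverage; the first-surface
#' distance along any covered ray is `pocket_radius - atom_radius` up to
#' the tiling granularity, which the generator reports as attribute
#' `"granularity"` (a bound on the length deviation) so tests can set
#' tolerances programmatically.  Deterministic for a fixed seed.
#'
#' @param pocket_radius shell radius rho (Angstrom).
#' @param atom_radius van der Waals radius r of the shell atoms
#'   (Angstrom); must be smaller than `pocket_radius`.
#' @param shell_density atoms per square Angstrom of shell (default 4).
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @param jitter_sd optional Gaussian jitter (Angstrom) on atom centres.
#' @param rim_margin angular margin (radians) the shell extends below
#'   the equator (default 0.2).
#' @param charge per-atom partial charge (default 0).
#' @param id structure id.
#' @return an `svec_structure` with radii and charges assigned, carrying
#'   attributes `granularity` (Angstrom, bound on hit-length deviation)
#'   and `spacing` (typical lattice spacing, Angstrom).
#' @export
make_cavity <- function(pocket_radius, atom_radius, shell_density = 4,
                        seed = 1L, jitter_sd = 0, rim_margin = 0.2,
                        charge = 0, id = "cavity") {
  if (!(pocket_radius > atom_radius && atom_radius > 0))
    stop("need pocket_radius > atom_radius > 0", call. = FALSE)
  z0 <- -sin(rim_margin)
  area <- 2 * pi * pocket_radius^2 * (1 - z0)
  n <- max(8L, ceiling(shell_density * area))
  spacing <- sqrt(area / n)
  # covering radius of the Fibonacci cap lattice, empirical safe bound
  cover <- 1.3 * spacing + 3 * jitter_sd
  if (cover >= atom_radius)
    warning("shell too sparse: expected max gap ", signif(cover, 3),
            " A exceeds the atom radius; rays may slip through",
            call. = FALSE)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  z <- 1 - (i - 0.5) * (1 - z0) / n
  rho_xy <- sqrt(pmax(1 - z^2, 0))
  az <- golden * i
  P <- pocket_radius * cbind(rho_xy * cos(az), rho_xy * sin(az), z)
  if (jitter_sd > 0)
    P <- P + with_seed(seed, matrix(stats::rnorm(3 * n, sd = jitter_sd),
                                    n, 3L))
  st <- new_structure(id = id, element = "C",
                      name = paste0("C", i), resname = "CAV", resid = i,
                      coords = P, radius = atom_radius, charge = charge)
  # worst-case hit-length excess for a ray at angular offset alpha from
  # the nearest atom: entry(alpha) - (rho - r), exact hard-sphere form
  alpha <- min(cover / pocket_radius, pi / 2)
  disc <- atom_radius^2 - (pocket_radius * sin(alpha))^2
  gran <- if (disc > 0)
    pocket_radius * cos(alpha) - sqrt(disc) - (pocket_radius - atom_radius)
  else atom_radius
  attr(st, "granularity") <- gran
  attr(st, "spacing") <- spacing
  st
}

#' Two-state synthetic conformational ensemble
#'
#' Frames are synthetic cavities whose pocket radius is drawn from one
#' of two states according to `mix`, with seeded Gaussian coordinate
#' noise — a minimal stand-in for an MD ensemble hopping between two
#' pocket geometries.  Ground-truth state labels are attached as
#' attribute `"state"`.
#'
#' @param n_frames number of frames (>= 2).
#' @param state_radii length-2 vector of pocket radii (Angstrom).
#' @param mix fraction of frames in state 1, strictly between 0 and 1.
#' @param noise_sd per-coordinate Gaussian noise (Angstrom).
#' @param seed integer seed.
#' @param atom_radius,shell_density passed to [make_cavity()].
#' @return list of `svec_structure` with attribute `state` (integer
#'   vector of ground-truth labels, 1 or 2).
#' @export
make_two_state_ensemble <- function(n_frames, state_radii = c(6, 9),
                                    mix = 0.5, noise_sd = 0.05, seed = 1L,
                                    atom_radius = 1, shell_density = 3) {
  if (n_frames < 2L) stop("need at least 2 frames", call. = FALSE)
  if (length(state_radii) != 2L || any(state_radii <= atom_radius))
    stop("state_radii must be two radii larger than atom_radius",
         call. = FALSE)
  if (!(mix > 0 && mix < 1)) stop("mix must be in (0, 1)", call. = FALSE)
  n1 <- max(1L, min(n_frames - 1L, round(mix * n_frames)))
  states <- with_seed(seed, sample(rep(c(1L, 2L), c(n1, n_frames - n1))))
  frames <- lapply(seq_len(n_frames), function(f)
    make_cavity(state_radii[states[f]], atom_radius,
                shell_density = shell_density,
                seed = seed + f, jitter_sd = noise_sd,
                id = sprintf("frame%03d", f)))
  frames <- lapply(seq_len(n_frames), function(f) {
    frames[[f]]$frame_index <- f; frames[[f]]
  })
  attr(frames, "state") <- states
  frames
}

#' Cavity with a charged surface patch
#'
#' A synthetic cavity whose atoms within a spherical cap around +z carry
#' `patch_charge` while the rest stay neutral.  Comparing the patched
#' and unpatched cavities isolates the charge metric: the expected
#' charge RMSD is `|patch_charge| * sqrt(fraction of vectors in the
#' patch)`, up to tiling granularity at the patch rim.
#'
#' @param pocket_radius,atom_radius,shell_density,seed,rim_margin as in
#'   [make_cavity()].
#' @param patch_solid_angle patch size in steradians (0 to 2*pi for the
#'   upper hemisphere; the cap is centred on +z).
#' @param patch_charge charge (e) of patch atoms.
#' @return an `svec_structure`; attribute `patch_cos_z` gives the cap
#'   boundary (atoms with unit z above it are charged).
#' @export
make_charged_patch <- function(pocket_radius, atom_radius,
                               patch_solid_angle, patch_charge,
                               shell_density = 4, seed = 1L,
                               rim_margin = 0.2) {
  st <- make_cavity(pocket_radius, atom_radius,
                    shell_density = shell_density, seed = seed,
                    rim_margin = rim_margin, id = "charged_patch")
  uz <- st$atoms$z / sqrt(st$atoms$x^2 + st$atoms$y^2 + st$atoms$z^2)
  if (patch_solid_angle >= 2 * pi) {
    # full coverage: include the rim atoms below the equator too
    cosz <- -1
  } else {
    cosz <- 1 - patch_solid_angle / (2 * pi)
  }
  st$atoms$charge <- ifelse(uz >= cosz, patch_charge, 0)
  attr(st, "patch_cos_z") <- cosz
  st
}
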