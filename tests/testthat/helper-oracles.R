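# Independent oracles and small constructors shared across tests.

# Ray-marching point-in-union-of-spheres oracle: walk each direction in
# fixed steps from the origin and report the first sampled point lying
# inside any atom sphere (max_length if none).  Deliberately independent
# of the analytic entry/exit construction used by trace_site().
march_trace <- function(structure, dirs, max_length, step = 0.001,
                        origin = c(0, 0, 0)) {
  a <- structure$atoms
  C <- sweep(as.matrix(a[, c("x", "y", "z")]), 2L, origin)
  r2 <- a$radius^2
  tgrid <- seq(step, max_length, by = step)
  vapply(seq_len(nrow(dirs)), function(k) {
    P <- outer(tgrid, dirs[k, ])                   # steps x 3
    # squared distance from every sample to every atom centre
    d2 <- outer(rowSums(P^2), rowSums(C^2), "+") - 2 * P %*% t(C)
    inside <- d2 <= matrix(r2, nrow(P), length(r2), byrow = TRUE)
    hit <- which(rowSums(inside) > 0)
    if (length(hit) == 0L) max_length else tgrid[hit[1L]]
  }, numeric(1L))
}

# random small structure with all atoms well in front of the origin
random_structure <- function(n_atoms, seed, rmin = 2.6, rmax = 9,
                             radius_range = c(1, 2)) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_atoms), n_atoms, 3L)
  u <- u / sqrt(rowSums(u^2))
  d <- runif(n_atoms, rmin, rmax)
  new_structure(paste0("rand", seed), element = "C",
                name = paste0("C", seq_len(n_atoms)), resname = "UNK",
                resid = seq_len(n_atoms), coords = u * d,
                radius = runif(n_atoms, radius_range[1L], radius_range[2L]),
                charge = round(runif(n_atoms, -0.5, 0.5), 3L))
}

# bare descriptor from explicit per-vector values
make_desc <- function(lengths, charges = rep(0, length(lengths)),
                      id = "d", idx = seq_along(lengths),
                      max_length = max(lengths)) {
  structure(list(structure_id = id, frame_index = 1L,
                 vector_index = as.integer(idx),
                 lengths = as.numeric(lengths),
                 charges = as.numeric(charges),
                 hit_atom = seq_along(lengths),
                 max_length = max_length),
            class = "svec_descriptor")
}

make_ligand_desc <- function(lengths, hit = lengths > 0,
                             charges = rep(0, length(lengths)),
                             idx = seq_along(lengths),
                             max_length = max(c(lengths, 1))) {
  structure(list(ligand_id = "lig", vector_index = as.integer(idx),
                 lengths = as.numeric(lengths),
                 charges = as.numeric(charges), hit = hit,
                 max_length = max_length),
            class = "svec_ligand_descriptor")
}

random_desc_pair <- function(n, seed) {
  set.seed(seed)
  list(make_desc(runif(n, 2, 20), rnorm(n, sd = 0.2), id = "a"),
       make_desc(runif(n, 2, 20), rnorm(n, sd = 0.2), id = "b"))
}

# Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# write a minimal PDB text fixture; returns the path
write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, resid, x, y, z,
                          element, record = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, "A", resid, x, y, z, 1, 0, element)
}
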