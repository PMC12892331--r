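test_that("handcrafted PDB blocks round-trip field by field", {
  path <- write_pdb_fixture(c(
    pdb_atom_line(1, "N",  "ALA", 1, 1.000, 2.000, 3.000, "N"),
    pdb_atom_line(2, "CA", "ALA", 1, 2.500, 2.000, 3.000, "C"),
    pdb_atom_line(3, "O",  "ALA", 1, 3.200, 1.100, 3.000, "O"),
    "END"))
  st <- read_structure(path, id = "tiny")
  expect_identical(nrow(st$atoms), 3L)
  expect_identical(st$atoms$name, c("N", "CA", "O"))
  expect_identical(st$atoms$element, c("N", "C", "O"))
  expect_equal(st$atoms$x, c(1, 2.5, 3.2))
  expect_true(all(st$atoms$backbone))
  expect_error(read_structure(tempfile()), "no such file")
})

test_that("multi-model files yield the requested model", {
  lines <- unlist(lapply(1:5, function(m) c(
    sprintf("MODEL     %4d", m),
    pdb_atom_line(1, "CA", "GLY", 1, m * 1.0, 0, 0, "C"),
    pdb_atom_line(2, "CA", "GLY", 2, m * 1.0, 1, 0, "C"),
    "ENDMDL")))
  path <- write_pdb_fixture(lines)
  st2 <- read_structure(path, model_index = 2)
  expect_identical(st2$frame_index, 2L)
  expect_equal(st2$atoms$x, c(2, 2))
  ens <- read_ensemble(path)
  expect_length(ens, 5L)
  expect_equal(vapply(ens, function(s) s$atoms$x[1L], numeric(1)), 1:5)
  expect_error(read_structure(path, model_index = 9), "out of range")
})

test_that("heme HETATM records survive with residue names preserved", {
  path <- write_pdb_fixture(c(
    pdb_atom_line(1, "FE", "HEM", 9, 0, 0, 0, "FE", record = "HETATM"),
    pdb_atom_line(2, "NA", "HEM", 9, 2, 0, 0, "N", record = "HETATM"),
    pdb_atom_line(3, "O",  "HOH", 10, 5, 5, 5, "O", record = "HETATM"),
    "END"))
  st <- read_structure(path, drop_solvent = TRUE)
  expect_identical(st$atoms$resname, c("HEM", "HEM"))
  expect_identical(st$atoms$element, c("FE", "N"))
  st_all <- read_structure(path, drop_solvent = FALSE)
  expect_identical(nrow(st_all$atoms), 3L)
})

test_that("radius assignment uses the table, fallback and errors correctly", {
  st <- new_structure("t", element = c("C", "N", "XX"),
                      name = c("C1", "N1", "X1"), resname = "UNK",
                      resid = 1:3, coords = diag(3))
  expect_error(assign_radii(st), "XX")
  expect_warning(st2 <- assign_radii(st, fallback = 1.5), "XX")
  expect_equal(st2$atoms$radius, c(1.70, 1.55, 1.5))
  st3 <- assign_radii(st, table = c(C = 2, N = 2, XX = 2))
  expect_equal(st3$atoms$radius, rep(2, 3))
  # assignment must not touch coordinates or order
  expect_identical(coords_of(st3), coords_of(st))
  expect_identical(st3$atoms$name, st$atoms$name)
})

test_that("charge assignment: exact beats wildcard, fallback counted", {
  tab <- data.frame(residue_name = c("*", "GLY", "ASP"),
                    atom_name = c("CA", "CA", "OD1"),
                    charge_e = c(0.1, -0.5, -0.635))
  st <- new_structure("t", element = c("C", "C", "O", "S"),
                      name = c("CA", "CA", "OD1", "SG"),
                      resname = c("ALA", "GLY", "ASP", "CYS"),
                      resid = 1:4, coords = matrix(rnorm(12), 4))
  st2 <- suppressMessages(assign_charges(st, tab))
  expect_equal(st2$atoms$charge, c(0.1, -0.5, -0.635, 0))
  expect_identical(attr(st2, "n_unmatched"), 1L)
})

test_that("reference frame inverts a known rigid motion", {
  th <- 0.7
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  ang <- seq(0, 2 * pi, length.out = 5)[1:4]
  ring <- cbind(2 * cos(ang), 2 * sin(ang), 0)
  coords <- rbind(c(0, 0, 0), ring, c(0, 0, 5), c(1, 1, 6))
  moved <- t(R %*% t(coords)) +
    matrix(c(3, -2, 7), nrow(coords), 3, byrow = TRUE)
  st <- new_structure("f", element = c("FE", rep("N", 4), "C", "C"),
                      name = c("FE", "NA", "NB", "NC", "ND", "C1", "C2"),
                      resname = c(rep("HEM", 5), "ALA", "ALA"),
                      resid = c(rep(1, 5), 2, 3), coords = moved)
  fr <- compute_reference_frame(st)
  expect_equal(det(fr$rotation), 1, tolerance = 1e-9)
  out <- apply_frame(st, fr)
  xyz <- coords_of(out)
  expect_lt(max(abs(xyz[1, ])), 1e-6)           # anchor at origin
  expect_lt(max(abs(xyz[2:5, 3])), 1e-6)        # ring in the xy-plane
  expect_gt(xyz[6, 3], 0)                       # body above the plane

  # idempotence: a framed structure re-frames to itself
  fr2 <- compute_reference_frame(out)
  out2 <- apply_frame(out, fr2)
  expect_lt(max(abs(coords_of(out2) - xyz)), 1e-6)
})

test_that("reference frame selection errors are informative", {
  st <- new_structure("t", element = "C", name = "CA", resname = "GLY",
                      resid = 1, coords = matrix(1:3, 1))
  expect_error(compute_reference_frame(st), "matched no atom")
  lin <- new_structure("t", element = c("FE", "N", "N", "N"),
                       name = c("FE", "NA", "NB", "NC"),
                       resname = "HEM", resid = 1,
                       coords = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                      c(3, 0, 0)))
  expect_error(compute_reference_frame(lin), "collinear")
})

test_that("superposition recovers exact rigid copies and noise floor", {
  set.seed(42)
  n <- 1000
  ref <- new_structure("r", element = "C", name = "CA", resname = "GLY",
                       resid = 1:n, coords = matrix(rnorm(3 * n, sd = 5), n))
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  mob <- set_coords(ref, t(R %*% t(coords_of(ref))) + 2)
  fit <- superpose(mob, ref, selection = "CA")
  expect_lt(fit$rmsd, 1e-6)
  expect_lt(max(abs(coords_of(fit$structure) - coords_of(ref))), 1e-6)

  # isotropic sigma = 0.1 A noise: minimal RMSD approaches sqrt(3)*sigma
  noisy <- set_coords(ref, coords_of(ref) + matrix(rnorm(3 * n, sd = 0.1), n))
  fit2 <- superpose(noisy, ref, selection = "CA")
  expect_equal(fit2$rmsd, sqrt(3) * 0.1, tolerance = 0.15)

  # invariance to any proper pre-rotation of the mobile structure
  th2 <- 2.2
  R2 <- matrix(c(1, 0, 0, 0, cos(th2), -sin(th2), 0, sin(th2), cos(th2)),
               3, 3, byrow = TRUE)
  pre <- set_coords(noisy, t(R2 %*% t(coords_of(noisy))))
  expect_equal(superpose(pre, ref, selection = "CA")$rmsd, fit2$rmsd,
               tolerance = 1e-9)
})

test_that("superposition rejects unpairable or too-small selections", {
  n <- 5
  ref <- new_structure("r", element = "C", name = "CA", resname = "GLY",
                       resid = 1:n, coords = matrix(rnorm(15), n))
  two <- new_structure("m", element = "C", name = "CA", resname = "GLY",
                       resid = 1:2, coords = matrix(rnorm(6), 2))
  expect_error(superpose(two, ref, selection = "CA"), "differ")
  expect_error(superpose(two, two, selection = "CA"), "at least 3")
})
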