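test_that("shape and charge RMSDs match hand-evaluated cases", {
  expect_equal(rmsd_shape(make_desc(5), make_desc(8)), 3)
  expect_equal(rmsd_shape(make_desc(1:4), make_desc(c(2, 2, 3, 4))), 0.5)
  expect_equal(rmsd_charge(make_desc(1, -0.3), make_desc(1, 0.1)), 0.4)
  expect_equal(rmsd_charge(make_desc(c(1, 1), c(0.2, -0.2)),
                           make_desc(c(1, 1), c(0, 0))), 0.2)
  d <- make_desc(runif(10), rnorm(10))
  expect_equal(rmsd_shape(d, d), 0)
  expect_equal(rmsd_charge(d, d), 0)
  expect_error(rmsd_shape(make_desc(1:3), make_desc(1:4)), "vector counts")
})

test_that("weights follow the tuning parameter and always average to 1", {
  expect_equal(unname(weights_from_d(0)), c(1, 1))
  expect_equal(unname(weights_from_d(2)), c(0.5, 1.5))
  for (d in c(-0.9, -0.5, 0, 1, 10, 100)) {
    w <- weights_from_d(d)
    expect_equal(unname(w[["w_c"]] / w[["w_s"]]), 1 + d, tolerance = 1e-12)
    expect_equal(unname(sum(w)), 2, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
  expect_error(weights_from_d(-1), "> -1")
  expect_error(weights_from_d(-2), "> -1")
})

test_that("combined metric at d = 0 is the quadrature sum of the parts", {
  for (seed in 1:50) {
    p <- random_desc_pair(30, seed)
    sl <- runif(1, 0.5, 5); sq <- runif(1, 0.05, 0.5)
    par0 <- similarity_params("combined", d = 0, sigma_l = sl, sigma_q = sq)
    lhs <- rmsd_combined(p[[1]], p[[2]], par0)
    rhs <- sqrt((rmsd_shape(p[[1]], p[[2]]) / sl)^2 +
                (rmsd_charge(p[[1]], p[[2]]) / sq)^2)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # equal charges: the combined metric reduces to shape / sigma_l
  a <- make_desc(c(2, 4, 6), c(0.1, 0.2, 0.3))
  b <- make_desc(c(3, 4, 8), c(0.1, 0.2, 0.3))
  par <- similarity_params("combined", d = 0, sigma_l = 2, sigma_q = 1)
  expect_equal(rmsd_combined(a, b, par), rmsd_shape(a, b) / 2,
               tolerance = 1e-12)
})

test_that("combined metric is invariant under joint rescaling", {
  p <- random_desc_pair(40, 77)
  par <- similarity_params("combined", d = 1.5, sigma_l = 3, sigma_q = 0.2)
  base <- rmsd_combined(p[[1]], p[[2]], par)
  for (s in c(0.5, 2, 10)) {
    scaled <- lapply(p, function(d) { d$lengths <- d$lengths * s; d })
    par_s <- similarity_params("combined", d = 1.5, sigma_l = 3 * s,
                               sigma_q = 0.2)
    expect_equal(rmsd_combined(scaled[[1]], scaled[[2]], par_s), base,
                 tolerance = 1e-12)
    scaled_q <- lapply(p, function(d) { d$charges <- d$charges * s; d })
    par_q <- similarity_params("combined", d = 1.5, sigma_l = 3,
                               sigma_q = 0.2 * s)
    expect_equal(rmsd_combined(scaled_q[[1]], scaled_q[[2]], par_q), base,
                 tolerance = 1e-12)
  }
})

test_that("metrics are symmetric, zero on identity, nonnegative", {
  par <- similarity_params("combined", d = 0.5, sigma_l = 2, sigma_q = 0.1)
  for (seed in 1:20) {
    p <- random_desc_pair(25, seed)
    for (f in list(rmsd_shape, rmsd_charge,
                   function(a, b) rmsd_combined(a, b, par))) {
      expect_equal(f(p[[1]], p[[2]]), f(p[[2]], p[[1]]), tolerance = 1e-12)
      expect_gte(f(p[[1]], p[[2]]), 0)
      expect_equal(f(p[[1]], p[[1]]), 0)
    }
  }
})

test_that("pooled normalisers use the population convention", {
  a <- make_desc(c(1, 3), c(0.1, -0.1))
  b <- make_desc(c(1, 3), c(-0.1, 0.1))
  nz <- compute_normalizers(list(a, b))
  expect_equal(nz$mean_l, 2)
  expect_equal(nz$sigma_l, 1)        # population SD of {1,3,1,3}
  expect_equal(nz$sigma_q, 0.1)
  # doubling all lengths doubles sigma_l and leaves the metric unchanged
  a2 <- a; a2$lengths <- a$lengths * 2
  b2 <- b; b2$lengths <- b$lengths * 2
  nz2 <- compute_normalizers(list(a2, b2))
  expect_equal(nz2$sigma_l, 2 * nz$sigma_l)
  par <- similarity_params("combined", d = 0, sigma_l = nz$sigma_l,
                           sigma_q = nz$sigma_q)
  par2 <- similarity_params("combined", d = 0, sigma_l = nz2$sigma_l,
                            sigma_q = nz2$sigma_q)
  expect_equal(rmsd_combined(a2, b2, par2), rmsd_combined(a, b, par),
               tolerance = 1e-12)
  expect_error(compute_normalizers(list(make_desc(c(2, 2)),
                                        make_desc(c(2, 2)))),
               "lengths identical")
})

test_that("pairwise matrices are consistent with elementwise calls", {
  expect_equal(unclass(pairwise_matrix(list(make_desc(1:5)),
                                       similarity_params("shape"))),
               matrix(0, 1, 1, dimnames = list("d", "d")))
  descs <- lapply(1:4, function(i) random_desc_pair(20, i)[[1]])
  par <- similarity_params("shape")
  M <- pairwise_matrix(descs, par, labels = letters[1:4])
  expect_equal(max(abs(M - t(M))), 0)
  expect_equal(unname(diag(M)), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(M[i, j], rmsd_shape(descs[[i]], descs[[j]]))
  # permuting the inputs permutes rows and columns identically
  set.seed(11)
  for (rep in 1:5) {
    perm <- sample(4)
    Mp <- pairwise_matrix(descs[perm], par, labels = letters[1:4][perm])
    expect_equal(unclass(Mp), unclass(M)[perm, perm])
  }
})

test_that("matrix TSV round-trips with labels", {
  descs <- lapply(1:3, function(i) random_desc_pair(10, i)[[1]])
  M <- pairwise_matrix(descs, similarity_params("shape"),
                       labels = c("sysA", "sysB", "sysC"))
  tf <- tempfile(fileext = ".tsv")
  write_matrix(M, tf)
  M2 <- read_matrix(tf)
  expect_equal(unclass(M2), unclass(M), tolerance = 1e-12)
  expect_identical(rownames(M2), c("sysA", "sysB", "sysC"))
})

test_that("ensemble-weighted RMSD reduces to hand-evaluated forms", {
  a <- make_desc(c(2, 4), c(0.1, 0))
  b <- make_desc(c(3, 6), c(0, -0.1))
  c_ <- make_desc(c(5, 5), c(0.2, 0.2))
  par <- similarity_params("shape")
  # single exemplar on both sides: plain descriptor RMSD
  A1 <- ensemble_summary("A", list(a), 10)
  B1 <- ensemble_summary("B", list(b), 7)
  expect_equal(ensemble_rmsd(A1, B1, par), rmsd_shape(a, b),
               tolerance = 1e-12)
  expect_equal(ensemble_rmsd(A1, A1, par), 0)
  # 50/50 split against a single exemplar: mean of the pairwise values
  A2 <- ensemble_summary("A", list(a, c_), c(5, 5))
  B2 <- ensemble_summary("B", list(b), 4)
  expect_equal(ensemble_rmsd(A2, B2, par),
               (rmsd_shape(a, b) + rmsd_shape(c_, b)) / 2,
               tolerance = 1e-12)
  # symmetry
  expect_equal(ensemble_rmsd(A2, B2, par), ensemble_rmsd(B2, A2, par),
               tolerance = 1e-12)
})

test_that("splitting an exemplar into weighted duplicates changes nothing", {
  a <- make_desc(c(2, 4), c(0.1, 0))
  b <- make_desc(c(3, 6), c(0, -0.1))
  c_ <- make_desc(c(7, 1), c(0, 0.3))
  par <- similarity_params("charge")
  A <- ensemble_summary("A", list(a, b), c(6, 4))
  Asplit <- ensemble_summary("A", list(a, a, b), c(2, 4, 4))
  B <- ensemble_summary("B", list(c_), 3)
  expect_equal(ensemble_rmsd(Asplit, B, par), ensemble_rmsd(A, B, par),
               tolerance = 1e-12)
})

test_that("ensemble weight bookkeeping is validated", {
  a <- make_desc(1:3)
  expect_error(ensemble_summary("A", list(a), c(2, 3)), "one weight per")
  expect_error(ensemble_summary("A", list(a), 5, total = 7),
               "must equal the total")
  expect_error(ensemble_summary("A", list(a), -1), "positive integers")
})
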