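#' Shape/charge weighting from the tuning parameter d
#'
#' The combined metric weights its shape and charge terms by
#' \eqn{w_s = 2/(2+d)} and \eqn{w_c = 2(1+d)/(2+d)}, so that
#' \eqn{w_c = (1+d) w_s} and \eqn{(w_s + w_c)/2 = 1} for every
#' \eqn{d > -1}.  Negative `d` emphasises shape, positive `d` charge;
#' `d = 0` weights both equally.
#'
#' @param d tuning parameter, `d > -1` (at `d = -1` the charge weight
#'   vanishes and the weighting degenerates).
#' @return named numeric vector `c(w_s = ..., w_c = ...)`.
#' @examples
#' weights_from_d(0)   # 1, 1
#' weights_from_d(2)   # 0.5, 1.5
#' @export
weights_from_d <- function(d) {
  if (length(d) != 1L || !is.finite(d) || d <= -1)
    stop("'d' must be a single number > -1", call. = FALSE)
  c(w_s = 2 / (2 + d), w_c = 2 * (1 + d) / (2 + d))
}

#' Similarity parameters
#'
#' Bundles the comparison mode and its tuning constants.  For the
#' combined mode, lengths are normalised by `sigma_l` (Angstrom) and
#' charges by `sigma_q` (e) to make the two unit-free and commensurate;
#' use [compute_normalizers()] to pool them over the comparison set, or
#' set them explicitly to reuse constants from another dataset.
#'
#' @param mode `"shape"`, `"charge"` or `"combined"`.
#' @param d shape/charge tuning parameter (combined mode), see
#'   [weights_from_d()].
#' @param sigma_l,sigma_q normalising standard deviations (combined
#'   mode); must be positive.
#' @return an object of class `svec_params`.
#' @export
similarity_params <- function(mode = c("combined", "shape", "charge"),
                              d = 0, sigma_l = NULL, sigma_q = NULL) {
  mode <- match.arg(mode)
  w <- weights_from_d(d)
  if (mode == "combined") {
    if (is.null(sigma_l) || is.null(sigma_q))
      stop("combined mode requires sigma_l and sigma_q ",
           "(see compute_normalizers())", call. = FALSE)
    if (sigma_l <= 0 || sigma_q <= 0)
      stop("sigma_l and sigma_q must be positive", call. = FALSE)
  }
  structure(list(mode = mode, d = d, w_s = unname(w[1L]),
                 w_c = unname(w[2L]),
                 sigma_l = sigma_l, sigma_q = sigma_q),
            class = "svec_params")
}

#' @export
print.svec_params <- function(x, ...) {
  cat("Similarity parameters: mode =", x$mode)
  if (x$mode == "combined")
    cat(sprintf(", d = %g (w_s = %.4g, w_c = %.4g), sigma_l = %g A, sigma_q = %g e",
                x$d, x$w_s, x$w_c, x$sigma_l, x$sigma_q))
  cat("\n")
  invisible(x)
}

check_pair <- function(a, b) {
  if (length(a$lengths) != length(b$lengths))
    stop("descriptors have different vector counts (",
         length(a$lengths), " vs ", length(b$lengths), ")", call. = FALSE)
  if (!identical(a$vector_index, b$vector_index))
    stop("descriptors are indexed on different scaffolds", call. = FALSE)
}

#' Shape RMSD between two site descriptors
#'
#' \deqn{RMSD^s_{ij} = \sqrt{\frac{1}{N}\sum_{k=1}^{N}(l_{k,i}-l_{k,j})^2}}
#' over the N common vector indices; units Angstrom.
#'
#' @param a,b `svec_descriptor` objects on the same scaffold.
#' @return nonnegative number (Angstrom).
#' @export
rmsd_shape <- function(a, b) {
  check_pair(a, b)
  sqrt(mean((a$lengths - b$lengths)^2))
}

#' Charge RMSD between two site descriptors
#'
#' As [rmsd_shape()] with per-vector charges in place of lengths; units
#' elementary charge.
#'
#' @param a,b `svec_descriptor` objects on the same scaffold.
#' @return nonnegative number (e).
#' @export
rmsd_charge <- function(a, b) {
  check_pair(a, b)
  sqrt(mean((a$charges - b$charges)^2))
}

#' Combined (shape + charge) RMSD
#'
#' Lengths and charges are normalised to be unitless and commensurate,
#' then combined with the weights from [weights_from_d()]:
#' \deqn{RMSD^{sc}_{ij} = \sqrt{\frac{1}{N}\Big[w_s \sum_k
#'   \Big(\frac{\Delta l_k}{\sigma_l}\Big)^2 + w_c \sum_k
#'   \Big(\frac{\Delta q_k}{\sigma_q}\Big)^2\Big]}}
#' The per-pool means cancel in the difference, so only the standard
#' deviations enter.  At `d = 0` this is the plain quadrature sum of the
#' two normalised RMSDs.
#'
#' @param a,b `svec_descriptor` objects on the same scaffold.
#' @param params an `svec_params` with `sigma_l`, `sigma_q` set.
#' @return nonnegative dimensionless number.
#' @export
rmsd_combined <- function(a, b, params) {
  check_pair(a, b)
  stopifnot(inherits(params, "svec_params"))
  if (is.null(params$sigma_l) || is.null(params$sigma_q) ||
      params$sigma_l <= 0 || params$sigma_q <= 0)
    stop("rmsd_combined() needs positive sigma_l and sigma_q", call. = FALSE)
  n <- length(a$lengths)
  sl <- sum(((a$lengths - b$lengths) / params$sigma_l)^2)
  sq <- sum(((a$charges - b$charges) / params$sigma_q)^2)
  sqrt((params$w_s * sl + params$w_c * sq) / n)
}

#' Distance between descriptors under the selected mode
#'
#' Dispatches to [rmsd_shape()], [rmsd_charge()] or [rmsd_combined()]
#' according to `params$mode`.
#'
#' @inheritParams rmsd_combined
#' @return nonnegative number.
#' @export
site_distance <- function(a, b, params) {
  switch(params$mode,
         shape = rmsd_shape(a, b),
         charge = rmsd_charge(a, b),
         combined = rmsd_combined(a, b, params))
}

#' Pooled normalisers for the combined metric
#'
#' Mean and population standard deviation of all vector lengths and all
#' vector charges pooled over the whole comparison set (every vector of
#' every descriptor counts once).
#'
#' @param descriptors list of `svec_descriptor`.
#' @return list with `sigma_l`, `sigma_q`, `mean_l`, `mean_q`.
#' @export
compute_normalizers <- function(descriptors) {
  if (length(descriptors) < 1L)
    stop("need at least one descriptor", call. = FALSE)
  l <- unlist(lapply(descriptors, `[[`, "lengths"))
  q <- unlist(lapply(descriptors, `[[`, "charges"))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sl <- pop_sd(l); sq <- pop_sd(q)
  if (sl == 0)
    stop("degenerate normaliser: all vector lengths identical", call. = FALSE)
  if (sq == 0)
    stop("degenerate normaliser: all vector charges identical", call. = FALSE)
  list(sigma_l = sl, sigma_q = sq, mean_l = mean(l), mean_q = mean(q))
}

#' Pairwise distance matrix over descriptors
#'
#' @param descriptors list of `svec_descriptor` on a common scaffold.
#' @param params an `svec_params`.
#' @param labels optional character labels; default the descriptors'
#'   `structure_id` (made unique).
#' @return An object of class `svec_dist`: a symmetric numeric matrix
#'   with zero diagonal and dimnames set to the labels.
#' @export
pairwise_matrix <- function(descriptors, params, labels = NULL) {
  n <- length(descriptors)
  if (is.null(labels))
    labels <- make.unique(vapply(descriptors, function(d)
      as.character(d$structure_id), character(1L)))
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      M[i, j] <- M[j, i] <- site_distance(descriptors[[i]],
                                          descriptors[[j]], params)
    }
  class(M) <- c("svec_dist", "matrix")
  M
}

#' Write / read a labelled square matrix as TSV
#'
#' @param matrix an `svec_dist` (or any labelled square matrix).
#' @param path file path.
#' @return `write_matrix()`: `path` invisibly; `read_matrix()`: an
#'   `svec_dist` matrix.
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(label = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(M) <- list(df$label, colnames(df)[-1L])
  class(M) <- c("svec_dist", "matrix")
  M
}

#' Ensemble summary: exemplars and frame weights
#'
#' A conformational ensemble reduced to its cluster exemplars, each
#' weighted by the number of frames it represents.
#'
#' @param system_id identifier of the system (e.g. the CYP isoform).
#' @param exemplars list of `svec_descriptor` (the exemplar frames).
#' @param weights positive integer frame counts, one per exemplar.
#' @param total total frame count `N`; default `sum(weights)`.  Must
#'   equal the sum of the weights.
#' @return an object of class `svec_ensemble`.
#' @export
ensemble_summary <- function(system_id, exemplars, weights,
                             total = sum(weights)) {
  if (length(exemplars) != length(weights))
    stop("one weight per exemplar required", call. = FALSE)
  if (any(weights <= 0) || any(weights != round(weights)))
    stop("weights must be positive integers", call. = FALSE)
  if (sum(weights) != total)
    stop("sum(weights) must equal the total frame count N", call. = FALSE)
  structure(list(system_id = as.character(system_id),
                 exemplars = exemplars,
                 weights = as.numeric(weights),
                 total = as.numeric(total)),
            class = "svec_ensemble")
}

#' @export
print.svec_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble '%s': %d exemplars representing %g frames\n",
              x$system_id, length(x$exemplars), x$total))
  invisible(x)
}

#' Ensemble-weighted RMSD between two systems
#'
#' Each exemplar pair contributes its descriptor RMSD weighted by the
#' product of the frame fractions the exemplars represent:
#' \deqn{RMSD_{A,B} = \sum_{i\in A}\sum_{j\in B} RMSD_{i,j}\,
#'   \frac{n_i}{N_A}\frac{n_j}{N_B}}
#' so conformations that dominate an ensemble dominate the comparison.
#'
#' @param A,B `svec_ensemble` objects on a common scaffold.
#' @param params an `svec_params`.
#' @return nonnegative number in the units of the selected metric.
#' @export
ensemble_rmsd <- function(A, B, params) {
  stopifnot(inherits(A, "svec_ensemble"), inherits(B, "svec_ensemble"))
  tot <- 0
  for (i in seq_along(A$exemplars)) for (j in seq_along(B$exemplars)) {
    r <- site_distance(A$exemplars[[i]], B$exemplars[[j]], params)
    tot <- tot + r * (A$weights[i] / A$total) * (B$weights[j] / B$total)
  }
  tot
}

#' Ensemble-weighted distance matrix over systems
#'
#' @param ensembles list of `svec_ensemble`.
#' @param params an `svec_params`.
#' @return an `svec_dist` matrix labelled by `system_id`.
#' @export
ensemble_matrix <- function(ensembles, params) {
  n <- length(ensembles)
  labels <- make.unique(vapply(ensembles, `[[`, character(1L), "system_id"))
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      M[i, j] <- M[j, i] <- ensemble_rmsd(ensembles[[i]], ensembles[[j]],
                                          params)
  class(M) <- c("svec_dist", "matrix")
  M
}
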