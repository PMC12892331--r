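# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Affinity propagation on a similarity matrix
#'
#' Frey-Dueck message passing: responsibilities and availabilities are
#' iterated with damping until the exemplar set is stable for
#' `conv_iter` consecutive iterations or `max_iter` is reached.  A tiny
#' seeded jitter is added to the similarities to break the degeneracies
#' of exactly symmetric inputs; with a fixed seed the result is
#' reproducible.
#'
#' @param S square similarity matrix (larger = more similar; distances
#'   should be negated before calling, as [cluster_descriptors()] does).
#' @param damping message damping factor in `[0.5, 1)`; default 0.9.
#' @param preference self-similarity (scalar or per-point); default the
#'   median off-diagonal similarity, the usual choice when the number of
#'   clusters is not known in advance.
#' @param max_iter,conv_iter iteration budget and stability window.
#' @param seed integer seed for the degeneracy-breaking jitter.
#' @return list with `labels` (cluster index per item, 1..K),
#'   `exemplars` (item indices, one per cluster), `converged` (logical)
#'   and `iterations`.
#' @references Frey & Dueck (2007) Clustering by passing messages
#'   between data points. Science 315, 972-976.
#' @export
affinity_propagation <- function(S, damping = 0.9, preference = NULL,
                                 max_iter = 1000L, conv_iter = 50L,
                                 seed = 0L) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("similarity matrix must be square", call. = FALSE)
  if (damping < 0.5 || damping >= 1)
    stop("'damping' must be in [0.5, 1)", call. = FALSE)
  if (n == 1L)
    return(list(labels = 1L, exemplars = 1L, converged = TRUE,
                iterations = 0L))
  off <- S[row(S) != col(S)]
  scale <- max(off) - min(off)
  if (!is.finite(scale) || scale == 0) {
    # all items mutually indistinguishable: one cluster, first item exemplar
    return(list(labels = rep(1L, n), exemplars = 1L, converged = TRUE,
                iterations = 0L))
  }
  if (is.null(preference)) preference <- stats::median(off)
  diag(S) <- preference
  S <- S + with_seed(seed, matrix(stats::rnorm(n * n), n, n)) * 1e-10 * scale

  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; it <- 0L; exemplars_prev <- integer(0)
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (identical(ex, exemplars_prev)) stable <- stable + 1L
    else { stable <- 0L; exemplars_prev <- ex }
    if (stable >= conv_iter && length(ex) > 0L) break
  }
  converged <- stable >= conv_iter && length(exemplars_prev) > 0L
  ex <- exemplars_prev
  if (length(ex) == 0L) ex <- which.max(diag(A + R))
  if (!converged)
    warning("affinity propagation did not converge in ", max_iter,
            " iterations; returning best iterate", call. = FALSE)
  # assign every point to its best exemplar, exemplars to themselves
  lab_ex <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  lab_ex[ex] <- seq_along(ex)
  list(labels = lab_ex, exemplars = ex, converged = converged,
       iterations = it)
}

new_cluster_assignment <- function(labels, exemplars, converged = TRUE) {
  w <- as.numeric(tabulate(labels, nbins = length(exemplars)))
  structure(list(labels = labels, exemplars = exemplars, weights = w,
                 converged = converged),
            class = "svec_clusters")
}

#' @export
print.svec_clusters <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d items in %d clusters%s\n",
              length(x$labels), length(x$exemplars),
              if (x$converged) "" else " (not converged)"))
  cat("  weights:", paste(x$weights, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster descriptors by affinity propagation
#'
#' Runs [affinity_propagation()] on the negated distance matrix (distance
#' 0 = maximal similarity) and returns exemplars, per-item labels and
#' per-cluster frame counts (weights).
#'
#' @param matrix an `svec_dist` (or square symmetric distance matrix).
#' @param damping,preference,seed,max_iter,conv_iter passed to
#'   [affinity_propagation()].
#' @return an object of class `svec_clusters`: `labels`, `exemplars`
#'   (row indices of the matrix), `weights`, `converged`.
#' @export
cluster_descriptors <- function(matrix, damping = 0.9, preference = NULL,
                                seed = 0L, max_iter = 1000L,
                                conv_iter = 50L) {
  M <- as.matrix(matrix)
  if (any(is.na(M)) || any(M < 0))
    stop("distance matrix must be nonnegative and complete", call. = FALSE)
  if (max(abs(M - t(M))) > 1e-9)
    stop("distance matrix must be symmetric", call. = FALSE)
  ap <- affinity_propagation(-M, damping = damping, preference = preference,
                             max_iter = max_iter, conv_iter = conv_iter,
                             seed = seed)
  new_cluster_assignment(ap$labels, ap$exemplars, ap$converged)
}

#' Cluster trajectory frames on backbone RMSD
#'
#' Builds the pairwise atom-positional RMSD matrix over a superposable
#' selection (default backbone N, CA, C, O) using [superpose()], then
#' clusters it as [cluster_descriptors()] does.
#'
#' @param frames list of `svec_structure` (e.g. from [read_ensemble()]).
#' @param selection passed to [superpose()].
#' @inheritParams cluster_descriptors
#' @return an `svec_clusters`; `exemplars` are frame indices.
#' @export
cluster_backbone <- function(frames, selection = c("N", "CA", "C", "O"),
                             damping = 0.9, preference = NULL, seed = 0L) {
  n <- length(frames)
  M <- matrix(0, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      M[i, j] <- M[j, i] <- superpose(frames[[j]], frames[[i]],
                                      selection)$rmsd
  cluster_descriptors(M, damping = damping, preference = preference,
                      seed = seed)
}

#' Summarise clustered descriptors into an ensemble
#'
#' @param system_id system identifier.
#' @param descriptors the clustered descriptors (one per frame).
#' @param clusters the `svec_clusters` for those frames.
#' @return an `svec_ensemble` with the exemplar descriptors and frame
#'   counts as weights.
#' @export
summarize_ensemble <- function(system_id, descriptors, clusters) {
  stopifnot(inherits(clusters, "svec_clusters"))
  ensemble_summary(system_id,
                   exemplars = descriptors[clusters$exemplars],
                   weights = clusters$weights)
}

#' Joint second-round clustering with weight propagation
#'
#' Pools the exemplars of several systems, clusters the pool by affinity
#' propagation on the selected descriptor metric, and propagates the
#' first-round weights: a system's frame count in a joint cluster is the
#' sum of the weights of its exemplars assigned there.  The population
#' table normalises each system's row by its total frame count, giving
#' the fraction of that system's ensemble in each joint cluster.
#'
#' @param ensembles list of `svec_ensemble` on a common scaffold.
#' @param params an `svec_params`.
#' @inheritParams cluster_descriptors
#' @return list with `clusters` (an `svec_clusters` over the pooled
#'   exemplars, with `weights` holding propagated frame counts),
#'   `population` (matrix, systems x joint clusters, rows summing to 1)
#'   and `pool` (data.frame mapping pooled items to system/exemplar).
#' @export
joint_recluster <- function(ensembles, params, damping = 0.9,
                            preference = NULL, seed = 0L) {
  ids <- vapply(ensembles, `[[`, character(1L), "system_id")
  pool <- do.call(rbind, lapply(seq_along(ensembles), function(s) {
    e <- ensembles[[s]]
    data.frame(system = e$system_id, system_idx = s,
               exemplar = seq_along(e$exemplars), weight = e$weights)
  }))
  descs <- unlist(lapply(ensembles, `[[`, "exemplars"), recursive = FALSE)
  M <- pairwise_matrix(descs, params)
  cl <- cluster_descriptors(M, damping = damping, preference = preference,
                            seed = seed)
  k <- length(cl$exemplars)
  popn <- matrix(0, length(ensembles), k,
                 dimnames = list(ids, paste0("cluster", seq_len(k))))
  for (r in seq_len(nrow(pool)))
    popn[pool$system_idx[r], cl$labels[r]] <-
      popn[pool$system_idx[r], cl$labels[r]] + pool$weight[r]
  # propagated frame counts per joint cluster
  cl$weights <- as.numeric(colSums(popn))
  totals <- vapply(ensembles, `[[`, numeric(1L), "total")
  popn <- sweep(popn, 1L, totals, "/")
  list(clusters = cl, population = popn, pool = pool)
}

#' Average-linkage similarity tree
#'
#' Agglomerative average-linkage (UPGMA-style) clustering of a distance
#' matrix via [stats::hclust()], returned as an [ape] `phylo` tree whose
#' branch lengths derive from the merge heights, ready for Newick export.
#'
#' @param matrix an `svec_dist` (square, symmetric, nonnegative, zero
#'   diagonal) with labels.
#' @return list of class `svec_tree` with `hclust` (the merge object)
#'   and `phylo` (the ape tree).
#' @export
build_tree <- function(matrix) {
  M <- as.matrix(matrix)
  if (any(is.na(M)) || any(M < 0))
    stop("invalid distance matrix: NA or negative entries", call. = FALSE)
  if (is.null(rownames(M)))
    rownames(M) <- colnames(M) <- paste0("item", seq_len(nrow(M)))
  hc <- stats::hclust(stats::as.dist(M), method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc)),
            class = "svec_tree")
}

#' @export
print.svec_tree <- function(x, ...) {
  cat("Average-linkage similarity tree,", length(x$hclust$labels),
      "leaves\n")
  invisible(x)
}

#' @export
plot.svec_tree <- function(x, ...) {
  ape::plot.phylo(x$phylo, ...)
  invisible(x)
}

#' Write a tree as Newick
#'
#' @param tree an `svec_tree` (or `phylo`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ph <- if (inherits(tree, "svec_tree")) tree$phylo else tree
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Write a cluster assignment / population table as TSV
#'
#' @param clusters an `svec_clusters`.
#' @param path output file.
#' @param item_ids optional item identifiers.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(clusters, path, item_ids = NULL) {
  n <- length(clusters$labels)
  if (is.null(item_ids)) item_ids <- seq_len(n)
  df <- data.frame(item_id = item_ids,
                   cluster = clusters$labels,
                   is_exemplar = seq_len(n) %in% clusters$exemplars,
                   weight = clusters$weights[clusters$labels])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @param population population matrix from [joint_recluster()].
#' @export
write_population <- function(population, path) {
  df <- data.frame(system = rownames(population), population,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
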