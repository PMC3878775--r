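# Per-sample nearest-neighbour sets built from Euclidean distances on a random
# probe subsample. These neighbourhoods drive both imputation of missing betas
# and neighbourhood-restricted quantile normalisation: with thousands of
# heterogeneous arrays, normalising each array only against arrays that
# resemble it avoids forcing one global beta distribution onto every tissue.

#' Draw a random probe subsample
#'
#' Uniform sampling without replacement, clamped to the number of available
#' probes. Deterministic for a given seed; the caller's RNG state is left
#' untouched.
#'
#' @param m beta matrix.
#' @param n_probes number of probes to draw (default 10000).
#' @param seed integer seed.
#' @return character vector of probe IDs.
#' @export
subsample_probes <- function(m, n_probes = 10000, seed) {
  if (!is.numeric(n_probes) || length(n_probes) != 1 || n_probes < 1)
    stop("n_probes must be a positive integer", call. = FALSE)
  withr::with_seed(as.integer(seed),
                   sample(rownames(m), min(n_probes, nrow(m))))
}

#' Pairwise Euclidean distance between samples on a probe set
#'
#' For samples i and j the distance is
#' `sqrt((P / n_ij) * sum_p (x_ip - x_jp)^2)`, where the sum runs over the
#' chosen probes that are non-missing in both samples, `n_ij` is their count
#' and `P` the number of chosen probes. The `P / n_ij` rescaling keeps
#' distances comparable between pairs with different missingness; with no
#' missing data it reduces to the textbook Euclidean distance. Pairs with no
#' shared probe are incomparable and get `Inf` (with a warning).
#'
#' @param m beta matrix (>= 2 samples).
#' @param probes probe IDs to use; default all rows of `m`.
#' @return symmetric numeric matrix with zero diagonal; the per-pair shared
#'   probe counts are attached as attribute `"n_shared"`.
#' @export
pairwise_distance <- function(m, probes = rownames(m)) {
  validate_beta_matrix(m)
  if (ncol(m) < 2) stop("need at least two samples", call. = FALSE)
  missing_probes <- setdiff(probes, rownames(m))
  if (length(missing_probes))
    stop("probes not in matrix: ",
         paste(utils::head(missing_probes, 5), collapse = ", "), call. = FALSE)
  X <- m[probes, , drop = FALSE]
  P <- nrow(X)
  W <- !is.na(X)
  A <- X
  A[!W] <- 0
  storage.mode(W) <- "double"
  cross <- crossprod(A)
  sq <- crossprod(A^2, W)
  n_shared <- crossprod(W)
  ss <- sq + t(sq) - 2 * cross
  ss[ss < 0] <- 0  # guard against tiny negative rounding residues
  d <- sqrt(P * ss / n_shared)
  d[n_shared == 0] <- Inf
  diag(d) <- 0
  if (any(n_shared[upper.tri(n_shared)] == 0))
    warning("sample pair(s) share no non-missing probe; distance set to Inf")
  dimnames(d) <- list(colnames(m), colnames(m))
  attr(d, "n_shared") <- n_shared
  d
}

#' Extract the k nearest neighbours of every sample
#'
#' Neighbour lists are sorted by ascending distance with exact ties broken by
#' sample ID (C-locale lexicographic), so the result is fully deterministic
#' and invariant to the input sample order. A sample is never its own
#' neighbour; lists are clamped to `n_samples - 1`.
#'
#' @param d symmetric distance matrix with sample dimnames
#'   (see [pairwise_distance()]).
#' @param k number of neighbours (default 25).
#' @param probe_ids,seed optional provenance stored on the graph.
#' @return a `neighbor_graph`: list with `sample_ids`, `k`, `neighbors` (named
#'   list of data frames with columns `sample_id`, `distance`), `probe_ids`,
#'   `seed`.
#' @export
k_nearest <- function(d, k = 25, probe_ids = NULL, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  ids <- colnames(d)
  n <- length(ids)
  if (n < 2) warning("fewer than two samples; neighbour lists are empty")
  kk <- min(k, max(n - 1L, 0L))
  neighbors <- lapply(seq_len(n), function(i) {
    di <- d[i, -i]
    other <- ids[-i]
    ord <- order(di, other, method = "radix")[seq_len(kk)]
    data.frame(sample_id = other[ord], distance = unname(di[ord]),
               stringsAsFactors = FALSE)
  })
  names(neighbors) <- ids
  structure(list(sample_ids = ids, k = as.integer(k), neighbors = neighbors,
                 probe_ids = probe_ids, seed = seed),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph:", length(x$sample_ids), "samples, k =", x$k)
  if (!is.null(x$probe_ids)) cat(",", length(x$probe_ids), "subsampled probes")
  cat("\n")
  invisible(x)
}

#' Build a neighbour graph from a beta matrix
#'
#' Convenience wrapper: subsample probes, compute pairwise distances, take the
#' k nearest neighbours. One shared probe subsample is used for the whole
#' graph.
#'
#' @inheritParams subsample_probes
#' @inheritParams k_nearest
#' @return a `neighbor_graph`.
#' @export
build_neighbor_graph <- function(m, k = 25, n_probes = 10000, seed = 1) {
  probes <- subsample_probes(m, n_probes, seed)
  d <- pairwise_distance(m, probes)
  k_nearest(d, k, probe_ids = probes, seed = as.integer(seed))
}

.neighbor_sets <- function(g) lapply(g$neighbors, function(df) df$sample_id)

#' Stability of neighbour sets across probe subsamples
#'
#' Rebuilds the neighbour graph `n_repeats` times with sub-seeds
#' `seed + 1, ..., seed + n_repeats` and scores, for every sample, the Jaccard
#' overlap of its neighbour sets between every pair of repeats. High overlap
#' means the neighbourhood structure does not depend on which random probes
#' were drawn.
#'
#' @inheritParams build_neighbor_graph
#' @param n_repeats number of graph rebuilds (>= 2).
#' @return list with `per_sample` (named mean Jaccard per sample) and
#'   `overall` (grand mean).
#' @export
neighbor_stability <- function(m, n_probes = 10000, k = 25, n_repeats = 5,
                               seed = 1) {
  if (n_repeats < 2) stop("n_repeats must be at least 2", call. = FALSE)
  sets <- lapply(seq_len(n_repeats), function(r)
    .neighbor_sets(build_neighbor_graph(m, k, n_probes, seed + r)))
  ids <- colnames(m)
  pairs <- utils::combn(n_repeats, 2)
  per_sample <- vapply(ids, function(s) {
    mean(apply(pairs, 2, function(pr) {
      a <- sets[[pr[1]]][[s]]
      b <- sets[[pr[2]]][[s]]
      length(intersect(a, b)) / length(union(a, b))
    }))
  }, numeric(1))
  list(per_sample = per_sample, overall = mean(per_sample))
}

#' Serialise a neighbour graph as JSON
#' @param g a `neighbor_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_neighbor_graph <- function(g, path) {
  stopifnot(inherits(g, "neighbor_graph"))
  jsonlite::write_json(
    list(k = g$k, seed = g$seed, sample_ids = g$sample_ids,
         probe_ids = g$probe_ids,
         neighbors = lapply(g$neighbors, function(df)
           list(sample_id = df$sample_id, distance = df$distance))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_neighbor_graph
#' @export
read_neighbor_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  neighbors <- lapply(x$neighbors, function(nb)
    data.frame(sample_id = as.character(nb$sample_id),
               distance = as.numeric(nb$distance), stringsAsFactors = FALSE))
  structure(list(sample_ids = as.character(x$sample_ids), k = as.integer(x$k),
                 neighbors = neighbors,
                 probe_ids = if (!is.null(x$probe_ids)) as.character(x$probe_ids),
                 seed = if (!is.null(x$seed)) as.integer(x$seed)),
            class = "neighbor_graph")
}
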