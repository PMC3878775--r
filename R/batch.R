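# Banded Euclidean distances: restricting the distance calculation to probes
# whose absolute beta difference falls in a chosen band separates the scales
# at which samples differ. Small differences (|d beta| < 0.1) track the
# experiment (batch) a sample came from; large differences (0.2-0.3) track
# tissue. Clustering on banded distances therefore diagnoses how much of the
# structure in a combined dataset is technical.

#' Banded Euclidean distance between samples
#'
#' For samples i and j, only probes with `band_low <= |x_i - x_j| < band_high`
#' contribute: `d(i, j) = sqrt(mean of the in-band squared differences)`.
#' Normalising by the in-band count keeps bands with different probe counts
#' comparable. A pair with no in-band probe gets distance 0 (maximally similar
#' at that difference scale) and an in-band count of 0. When `band_high` is 1
#' the upper edge is closed so the full range \[0, 1\] can be covered.
#'
#' @param m complete beta matrix (no missing values; impute first).
#' @param band_low,band_high absolute-difference band,
#'   `0 <= band_low < band_high <= 1`.
#' @return a `banded_dist`: list with `distances` (symmetric matrix, zero
#'   diagonal), `counts` (in-band probe counts per pair), `band`,
#'   `sample_ids`.
#' @export
banded_distance <- function(m, band_low, band_high) {
  validate_beta_matrix(m)
  if (anyNA(m))
    stop("matrix contains missing values; run knn_impute() first", call. = FALSE)
  if (!is.numeric(band_low) || !is.numeric(band_high) ||
      band_low < 0 || band_high > 1 || band_low >= band_high)
    stop("band must satisfy 0 <= low < high <= 1", call. = FALSE)
  n <- ncol(m)
  ids <- colnames(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  C <- matrix(0L, n, n, dimnames = list(ids, ids))
  closed_top <- band_high == 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      delta <- m[, i] - m[, j]
      a <- abs(delta)
      inband <- a >= band_low & (a < band_high | (closed_top & a <= 1))
      cnt <- sum(inband)
      d <- if (cnt > 0) sqrt(sum(delta[inband]^2) / cnt) else 0
      D[i, j] <- D[j, i] <- d
      C[i, j] <- C[j, i] <- cnt
    }
  }
  structure(list(distances = D, counts = C,
                 band = c(low = band_low, high = band_high),
                 sample_ids = ids),
            class = "banded_dist")
}

#' @export
print.banded_dist <- function(x, ...) {
  cat(sprintf("banded_dist: %d samples, band [%g, %g)\n",
              length(x$sample_ids), x$band[["low"]], x$band[["high"]]))
  invisible(x)
}

#' Agglomerative clustering of a banded distance matrix
#'
#' @param bd a `banded_dist` (or plain symmetric distance matrix).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return an [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(bd, linkage = c("average", "complete",
                                                 "single")) {
  linkage <- match.arg(linkage)
  D <- if (inherits(bd, "banded_dist")) bd$distances else bd
  if (ncol(D) < 2) stop("need at least two samples", call. = FALSE)
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Purity of a dendrogram cut against known labels
#'
#' Cuts the tree into `k` clusters and reports purity
#' (`sum_c max_label |c intersect label| / n`) plus the adjusted Rand index
#' between the partition and the labels as a chance-corrected agreement
#' measure.
#'
#' @param dend an [stats::hclust] tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @param labels named character vector mapping every clustered sample to a
#'   label (e.g. tissue or experiment accession).
#' @return a `cluster_purity` object: list with `k`, `linkage`, `purity`,
#'   `ari`, and the `clusters` assignment.
#' @export
label_purity <- function(dend, k, labels) {
  stopifnot(inherits(dend, "hclust"))
  ids <- dend$labels
  if (is.null(ids)) ids <- as.character(seq_along(dend$order))
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab))
    stop("unlabelled sample(s): ",
         paste(utils::head(missing_lab, 5), collapse = ", "), call. = FALSE)
  if (k < 1 || k > length(ids))
    stop("k must be between 1 and the number of samples", call. = FALSE)
  cl <- stats::cutree(dend, k = k)
  lab <- labels[ids]
  purity <- sum(tapply(seq_along(cl), cl,
                       function(ix) max(table(lab[ix])))) / length(cl)
  ari <- mclust::adjustedRandIndex(cl, lab)
  structure(list(k = as.integer(k), linkage = dend$method,
                 purity = purity, ari = ari, clusters = cl),
            class = "cluster_purity")
}

#' @export
print.cluster_purity <- function(x, ...) {
  cat(sprintf("cluster_purity: k = %d (%s linkage), purity %.3f, ARI %.3f\n",
              x$k, x$linkage, x$purity, x$ari))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' @param dend an [stats::hclust] tree.
#' @param path output path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "hclust"))
  labels <- dend$labels
  height_of <- function(node)
    if (node < 0) 0 else dend$height[node]
  render <- function(node) {
    if (node < 0) return(labels[-node])
    h <- dend$height[node]
    kids <- dend$merge[node, ]
    parts <- vapply(kids, function(kid)
      sprintf("%s:%.10g", render(kid), h - height_of(kid)), character(1))
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  nwk <- paste0(render(nrow(dend$merge)), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
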