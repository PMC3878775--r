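# Missing-value imputation from nearest-neighbour arrays and quantile
# normalisation of each array against its own neighbourhood, plus the
# mask-and-impute validation harness used to measure imputation accuracy.

# Inverse-distance weights with the zero-distance convention: zero-distance
# neighbours get the maximum finite weight among the neighbours, or uniform
# weights if every neighbour is at distance zero.
.neighbor_weights <- function(distance, weighting) {
  if (weighting == "uniform") return(rep(1, length(distance)))
  w <- 1 / distance
  zero <- distance == 0
  if (any(zero)) {
    finite <- w[is.finite(w)]
    w[zero] <- if (length(finite)) max(finite) else 1
  }
  w[!is.finite(w)] <- 0  # Inf-distance (incomparable) neighbours drop out
  w
}

# Impute the cells `probe_idx` of sample `s` from its neighbours' values in
# `m`. Returns the imputed values (NA where even the probe-mean fallback is
# undefined).
.impute_cells <- function(m, s, probe_idx, nb, weighting) {
  V <- m[probe_idx, nb$sample_id, drop = FALSE]
  w <- .neighbor_weights(nb$distance, weighting)
  obs <- !is.na(V)
  Vz <- V
  Vz[!obs] <- 0
  num <- drop(Vz %*% w)
  den <- drop(obs %*% w)
  out <- num / den
  # all-neighbours-missing fallback: probe mean over every other sample
  fb <- which(den == 0)
  if (length(fb)) {
    rest <- m[probe_idx[fb], setdiff(colnames(m), s), drop = FALSE]
    out[fb] <- rowMeans(rest, na.rm = TRUE)
  }
  out[!is.finite(out)] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Impute missing betas from nearest-neighbour arrays
#'
#' Each missing cell is replaced by the (inverse-distance or uniform) weighted
#' mean of the neighbouring arrays' values at that probe, using only
#' neighbours with an observed value there. If all neighbours are missing at
#' the probe, the probe's mean over all other samples is used; if the probe is
#' missing everywhere the cell stays missing and is reported. Observed cells
#' are passed through bit-exactly and imputed values are clipped to \[0, 1\].
#'
#' @param m beta matrix.
#' @param g a `neighbor_graph` built on exactly the samples of `m`.
#' @param weighting `"inverse_distance"` (default) or `"uniform"`.
#' @param samples samples to impute; default every sample with a missing
#'   value.
#' @return the completed beta matrix. Cells that could not be imputed are
#'   listed in attribute `"unimputed"` (data frame of probe/sample IDs).
#' @export
knn_impute <- function(m, g, weighting = c("inverse_distance", "uniform"),
                       samples = NULL) {
  validate_beta_matrix(m)
  weighting <- match.arg(weighting)
  if (!inherits(g, "neighbor_graph") || !setequal(g$sample_ids, colnames(m)))
    stop("neighbour graph was not built on the samples of this matrix",
         call. = FALSE)
  if (is.null(samples))
    samples <- colnames(m)[colSums(is.na(m)) > 0]
  out <- m
  unimputed <- list()
  for (s in samples) {
    idx <- which(is.na(m[, s]))
    if (!length(idx)) next
    vals <- .impute_cells(m, s, idx, g$neighbors[[s]], weighting)
    out[idx, s] <- vals
    if (anyNA(vals))
      unimputed[[s]] <- data.frame(probe_id = rownames(m)[idx[is.na(vals)]],
                                   sample_id = s, stringsAsFactors = FALSE)
  }
  attr(out, "unimputed") <- if (length(unimputed))
    do.call(rbind, unname(unimputed))
  else
    data.frame(probe_id = character(), sample_id = character(),
               stringsAsFactors = FALSE)
  out
}

# classical quantile-normalisation assignment of the reference distribution
# `ref` (sorted ascending) to the vector `x`; tied values receive the mean of
# the reference values at the rank positions the tie group occupies.
.qn_assign <- function(x, ref) {
  y <- numeric(length(x))
  y[order(x, method = "radix")] <- ref
  stats::ave(y, x, FUN = mean)
}

#' Quantile-normalise each array against its own neighbourhood
#'
#' For each sample, the reference distribution is the element-wise mean of the
#' sorted value vectors of the sample and its k nearest neighbours; the
#' sample's values are then replaced rank-wise by that reference. Because the
#' sample itself enters the reference, normalisation contracts each array
#' toward its neighbourhood rather than replacing its distribution outright.
#' Every sample is normalised independently, so arrays from different tissues
#' are never forced onto one global distribution. Within-sample rank order is
#' preserved exactly.
#'
#' @param m complete beta matrix (impute first; missing values are an error).
#' @param g a `neighbor_graph` built on the samples of `m`.
#' @return normalised beta matrix (values in \[0, 1\]).
#' @export
neighborhood_quantile_normalize <- function(m, g) {
  validate_beta_matrix(m)
  if (anyNA(m))
    stop("matrix contains missing values; run knn_impute() first",
         call. = FALSE)
  if (!inherits(g, "neighbor_graph") || !setequal(g$sample_ids, colnames(m)))
    stop("neighbour graph was not built on the samples of this matrix",
         call. = FALSE)
  out <- m
  attr(out, "unimputed") <- NULL  # imputation-stage report, not carried over
  sorted <- apply(m, 2, sort, method = "radix")  # probes x samples, per-column sorted
  for (s in colnames(m)) {
    cols <- c(s, g$neighbors[[s]]$sample_id)
    ref <- rowMeans(sorted[, cols, drop = FALSE])
    out[, s] <- .qn_assign(m[, s], ref)
  }
  out
}

#' Mask-and-impute validation of imputation accuracy
#'
#' Per repeat, a sample is chosen at random, `n_mask` of its non-missing
#' probes are masked, the masked cells are re-imputed from the neighbour graph
#' (no quantile normalisation), and the fraction of imputed values within
#' `tol` of the held-out truth is recorded. Repeat r uses sub-seed
#' `seed + r`, so the whole experiment is reproducible from one seed. Values
#' that could not be imputed at all count as failures.
#'
#' @param m beta matrix.
#' @param g a `neighbor_graph` built on the samples of `m`.
#' @param n_mask probes masked per repeat (default 1000).
#' @param n_repeats number of mask/impute rounds (default 100).
#' @param tol absolute beta error counted as recovered (default 0.2).
#' @param seed integer seed.
#' @param weighting passed to the imputation step.
#' @return an `imputation_validation` object: `per_repeat` data frame
#'   (`repeat_index`, `sample_id`, `fraction_within_tol`), `mean_fraction`
#'   (mean of per-repeat fractions), `pooled_fraction` (over all masked cells
#'   of all repeats), plus the parameters used.
#' @export
validate_imputation <- function(m, g, n_mask = 1000, n_repeats = 100,
                                tol = 0.2, seed = 1,
                                weighting = "inverse_distance") {
  validate_beta_matrix(m)
  stopifnot(n_mask >= 1, n_repeats >= 1, tol >= 0)
  n_obs <- colSums(!is.na(m))
  eligible <- colnames(m)[n_obs >= n_mask]
  if (!length(eligible))
    stop("no sample has at least n_mask non-missing probes", call. = FALSE)
  res <- vector("list", n_repeats)
  n_hit <- 0L
  for (r in seq_len(n_repeats)) {
    pick <- withr::with_seed(as.integer(seed + r), {
      s <- sample(eligible, 1)
      list(s = s, idx = sample(which(!is.na(m[, s])), n_mask))
    })
    s <- pick$s
    truth <- m[pick$idx, s]
    # the target column itself never enters .impute_cells, so masking it is
    # implicit: neighbours and the probe-mean fallback both exclude sample s
    imputed <- .impute_cells(m, s, pick$idx, g$neighbors[[s]], weighting)
    ok <- !is.na(imputed) & abs(imputed - truth) <= tol
    n_hit <- n_hit + sum(ok)
    res[[r]] <- data.frame(repeat_index = r, sample_id = s,
                           fraction_within_tol = mean(ok),
                           stringsAsFactors = FALSE)
  }
  per_repeat <- do.call(rbind, res)
  structure(list(per_repeat = per_repeat,
                 mean_fraction = mean(per_repeat$fraction_within_tol),
                 pooled_fraction = n_hit / (n_mask * n_repeats),
                 n_mask = n_mask, n_repeats = n_repeats, tol = tol,
                 seed = as.integer(seed), weighting = weighting),
            class = "imputation_validation")
}

#' @export
print.imputation_validation <- function(x, ...) {
  cat(sprintf(
    "imputation_validation: %d repeats x %d masked probes, tol %.2g\n",
    x$n_repeats, x$n_mask, x$tol))
  cat(sprintf("  mean fraction within tol:   %.4f\n", x$mean_fraction))
  cat(sprintf("  pooled fraction within tol: %.4f\n", x$pooled_fraction))
  invisible(x)
}

#' Serialise an imputation-validation report as JSON
#' @param report an `imputation_validation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imputation_report <- function(report, path) {
  stopifnot(inherits(report, "imputation_validation"))
  jsonlite::write_json(
    list(n_repeats = report$n_repeats, n_mask = report$n_mask,
         tol = report$tol, seed = report$seed, weighting = report$weighting,
         mean_fraction = report$mean_fraction,
         pooled_fraction = report$pooled_fraction,
         per_repeat = report$per_repeat),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
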