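#' Validate a beta-value matrix
#'
#' Beta matrices are plain numeric matrices with probes in rows and samples in
#' columns; missing values are `NA`. Row names are probe IDs, column names are
#' sample IDs, and both must be unique. By default values are not required to
#' lie in \[0, 1\] so that raw deposits containing M-values can be read and
#' then cleaned with [filter_out_of_range()]; set `check_range = TRUE` to
#' enforce the closed unit interval.
#'
#' @param m numeric matrix, probes x samples, with `dimnames`.
#' @param check_range enforce that all non-missing values lie in \[0, 1\].
#' @return `m`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(m, check_range = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    stop("beta matrix must have probe row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(rownames(m))) || any(!nzchar(colnames(m))))
    stop("probe and sample IDs must be non-empty", call. = FALSE)
  if (check_range) {
    v <- m[!is.na(m)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("beta values outside [0, 1]; run filter_out_of_range() first",
           call. = FALSE)
  }
  invisible(m)
}

#' Two-channel intensity matrices
#'
#' Bundles the methylated and unmethylated channel intensities of an array set.
#' The two matrices must have identical dimensions and dimnames, and all
#' non-missing intensities must be non-negative.
#'
#' @param methylated,unmethylated numeric matrices, probes x samples, with
#'   matching `dimnames`.
#' @return an object of class `intensity_matrix`.
#' @seealso [compute_beta()]
#' @export
intensity_matrix <- function(methylated, unmethylated) {
  for (ch in list(methylated, unmethylated)) {
    if (!is.matrix(ch) || !is.numeric(ch))
      stop("intensity channels must be numeric matrices", call. = FALSE)
    if (is.null(rownames(ch)) || is.null(colnames(ch)))
      stop("intensity channels must carry probe/sample dimnames", call. = FALSE)
    if (any(ch < 0, na.rm = TRUE))
      stop("negative intensities are not allowed", call. = FALSE)
  }
  if (!identical(dim(methylated), dim(unmethylated)) ||
      !identical(dimnames(methylated), dimnames(unmethylated)))
    stop("methylated and unmethylated channels must have identical shape and dimnames",
         call. = FALSE)
  structure(list(methylated = methylated, unmethylated = unmethylated),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$methylated), "probes x",
      ncol(x$methylated), "samples\n")
  invisible(x)
}
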