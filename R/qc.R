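# Array-level quality control: beta computation from channel intensities,
# removal of arrays carrying out-of-[0,1] values (M-value deposits) or lacking
# annotation, and methylation-based sex prediction.

#' Compute beta values from channel intensities
#'
#' beta = I_M / (I_M + I_U + offset), where I_M and I_U are the methylated and
#' unmethylated channel intensities. The additive offset (100 by default)
#' regularises low-intensity probes, so outputs lie in \[0, 1). Cells missing
#' in either channel are missing in the result.
#'
#' @param im an [intensity_matrix()].
#' @param offset non-negative regularising offset added to the denominator.
#' @return numeric beta matrix, same dimnames as the input channels.
#' @export
compute_beta <- function(im, offset = 100) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (!is.numeric(offset) || length(offset) != 1 || is.na(offset) || offset < 0)
    stop("offset must be a single non-negative number", call. = FALSE)
  M <- im$methylated
  U <- im$unmethylated
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("negative intensities are not allowed", call. = FALSE)
  beta <- M / (M + U + offset)
  beta[is.na(M) | is.na(U)] <- NA_real_
  beta
}

.qc_report <- function(kept, dropped_ids, reason, n_out_of_range = NULL) {
  dropped <- data.frame(
    sample_id = dropped_ids,
    reason = rep_len(reason, length(dropped_ids)),
    stringsAsFactors = FALSE
  )
  if (!is.null(n_out_of_range))
    dropped$n_out_of_range <- n_out_of_range
  structure(list(kept_sample_ids = kept, dropped = dropped),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", length(x$kept_sample_ids), "kept,",
      nrow(x$dropped), "dropped\n")
  if (nrow(x$dropped)) print(x$dropped)
  invisible(x)
}

#' Serialise a QC report as JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(
    list(kept_sample_ids = report$kept_sample_ids, dropped = report$dropped),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Drop arrays with values outside the unit interval
#'
#' Public deposits occasionally contain M-values (logit-scale, unbounded)
#' where betas are expected. Any sample with at least one non-missing value
#' below 0 or above 1 is removed whole; exact 0 and 1 are valid betas
#' (closed interval). Surviving samples pass through bit-exactly.
#'
#' @param m beta matrix (probes x samples).
#' @return list with elements `beta` (the filtered matrix) and `report`
#'   (a `qc_report`; dropped samples have reason `"out_of_range"` and a count
#'   of offending values).
#' @export
filter_out_of_range <- function(m) {
  validate_beta_matrix(m)
  n_bad <- colSums(m < 0 | m > 1, na.rm = TRUE)
  drop <- n_bad > 0
  list(
    beta = m[, !drop, drop = FALSE],
    report = .qc_report(colnames(m)[!drop], colnames(m)[drop],
                        "out_of_range", unname(n_bad[drop]))
  )
}

#' Drop arrays lacking a sample-annotation record
#'
#' @param m beta matrix.
#' @param ann annotation `data.frame` with an `ID` column
#'   (see [read_annotation()]).
#' @return list with elements `beta` and `report` (reason
#'   `"no_annotation"`).
#' @export
filter_unannotated <- function(m, ann) {
  validate_beta_matrix(m)
  stopifnot(is.data.frame(ann), "ID" %in% names(ann))
  keep <- colnames(m) %in% ann$ID
  list(
    beta = m[, keep, drop = FALSE],
    report = .qc_report(colnames(m)[keep], colnames(m)[!keep], "no_annotation")
  )
}

#' Predict sample sex from X-chromosome methylation
#'
#' X inactivation leaves female samples with intermediate methylation across
#' much of the X chromosome, whereas male samples (one active X) show the
#' usual bimodal pattern dominated by unmethylated promoter CpGs. The rule:
#' a sample is called `female` when its mean beta over annotated chrX probes
#' falls inside `[lower, upper]`, `male` otherwise, and `undetermined` when
#' fewer than `min_probes` chrX probes are available (or the mean is
#' undefined).
#'
#' @param m beta matrix.
#' @param probe_ann probe-annotation `data.frame`; chrX probes are the rows
#'   with `chromosome == x_chromosome`.
#' @param lower,upper bounds of the intermediate-methylation band called
#'   female.
#' @param min_probes minimum number of usable chrX probes.
#' @param x_chromosome chromosome name identifying X probes.
#' @return named character vector over samples with values `"male"`,
#'   `"female"` or `"undetermined"`.
#' @export
predict_sex <- function(m, probe_ann, lower = 0.3, upper = 0.7,
                        min_probes = 10, x_chromosome = "chrX") {
  validate_beta_matrix(m)
  if (missing(probe_ann) || is.null(probe_ann) || nrow(probe_ann) == 0)
    stop("probe annotation is required for sex prediction", call. = FALSE)
  validate_probe_annotation(probe_ann)
  stopifnot(lower < upper)
  xp <- intersect(probe_ann$probe_id[probe_ann$chromosome == x_chromosome],
                  rownames(m))
  out <- rep("undetermined", ncol(m))
  names(out) <- colnames(m)
  if (length(xp) < min_probes) return(out)
  mu <- colMeans(m[xp, , drop = FALSE], na.rm = TRUE)
  n_used <- colSums(!is.na(m[xp, , drop = FALSE]))
  ok <- n_used >= min_probes & is.finite(mu)
  out[ok] <- ifelse(mu[ok] >= lower & mu[ok] <= upper, "female", "male")
  out
}
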