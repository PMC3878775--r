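# A local methylation repository: beta matrices from several studies merged
# into one store with a shared annotation table and probe map, queryable by
# sample/probe ID or genomic region. The store is a directory of exact-text
# files (17-significant-digit TSV), so build/open round trips are bit-exact.

#' Build a methylation repository from per-study beta matrices
#'
#' Sample sets across the input matrices must be disjoint; probe sets are
#' resolved to their intersection (the number of dropped probes is recorded in
#' the repository metadata). Every stored sample must have an annotation
#' record.
#'
#' @param beta_paths character vector of beta-matrix file paths
#'   (see [read_beta_matrix()]).
#' @param annotation_path sample-annotation file (see [read_annotation()]).
#' @param probe_annotation_path probe-annotation file
#'   (see [read_probe_annotation()]).
#' @param out_path directory to create the store in (`NULL` for an in-memory
#'   repository).
#' @return a `methylation_repository`.
#' @export
build_repository <- function(beta_paths, annotation_path,
                             probe_annotation_path, out_path = NULL) {
  mats <- lapply(beta_paths, read_beta_matrix)
  all_samples <- unlist(lapply(mats, colnames))
  if (anyDuplicated(all_samples))
    stop("sample ID(s) occur in more than one input matrix: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  shared <- Reduce(intersect, lapply(mats, rownames))
  n_dropped <- sum(vapply(mats, nrow, integer(1)) - length(shared))
  if (n_dropped > 0)
    message("probe sets differ across inputs; keeping the ", length(shared),
            "-probe intersection (", n_dropped, " matrix rows dropped)")
  beta <- do.call(cbind, lapply(mats, function(x)
    x[shared, , drop = FALSE]))
  ann <- read_annotation(annotation_path)
  unannotated <- setdiff(colnames(beta), ann$ID)
  if (length(unannotated))
    stop("stored sample(s) lack an annotation record: ",
         paste(utils::head(unannotated, 5), collapse = ", "), call. = FALSE)
  probes <- read_probe_annotation(probe_annotation_path)
  meta <- list(n_samples = ncol(beta), n_probes = nrow(beta),
               n_dropped_probes = n_dropped,
               format_version = 1L)
  repo <- structure(list(path = out_path, beta = beta,
                         annotation = ann, probes = probes, meta = meta),
                    class = "methylation_repository")
  if (!is.null(out_path)) {
    dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
    write_beta_matrix(beta, file.path(out_path, "beta.tsv"))
    write_annotation(ann, file.path(out_path, "annotation.tsv"))
    data.table::fwrite(probes, file.path(out_path, "probes.tsv"), sep = "\t",
                       quote = FALSE)
    jsonlite::write_json(meta, file.path(out_path, "meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  repo
}

#' @rdname build_repository
#' @param path an existing store directory.
#' @export
open_repository <- function(path) {
  for (f in c("beta.tsv", "annotation.tsv", "probes.tsv", "meta.json"))
    if (!file.exists(file.path(path, f)))
      stop("not a repository store (missing ", f, "): ", path, call. = FALSE)
  structure(list(path = path,
                 beta = read_beta_matrix(file.path(path, "beta.tsv")),
                 annotation = read_annotation(file.path(path, "annotation.tsv")),
                 probes = read_probe_annotation(file.path(path, "probes.tsv")),
                 meta = jsonlite::read_json(file.path(path, "meta.json"),
                                            simplifyVector = TRUE)),
            class = "methylation_repository")
}

#' @export
print.methylation_repository <- function(x, ...) {
  cat("methylation_repository:", nrow(x$beta), "probes x", ncol(x$beta),
      "samples", if (!is.null(x$path)) paste0("(", x$path, ")"), "\n")
  invisible(x)
}

.check_known <- function(requested, known, what) {
  unknown <- setdiff(requested, known)
  if (length(unknown))
    stop("unknown ", what, " ID(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
}

#' Extract a beta submatrix by sample and probe IDs
#'
#' Returns the requested submatrix in exactly the requested row and column
#' order. Unknown IDs are a hard error listing every offender — silent
#' dropping would corrupt downstream meta-analyses.
#'
#' @param repo a `methylation_repository`.
#' @param samples character vector of sample IDs.
#' @param probes character vector of probe IDs (may be empty).
#' @return numeric beta matrix `length(probes)` x `length(samples)`.
#' @export
getbeta <- function(repo, samples, probes) {
  stopifnot(inherits(repo, "methylation_repository"))
  .check_known(samples, colnames(repo$beta), "sample")
  .check_known(probes, rownames(repo$beta), "probe")
  repo$beta[probes, samples, drop = FALSE]
}

#' Extract betas for all probes inside a genomic region
#'
#' Equivalent to [getbeta()] on [probes_in_region()] restricted to probes
#' present in the store; rows are ordered by genomic position. A region
#' containing no probes yields a 0-row matrix.
#'
#' @inheritParams getbeta
#' @param region a `genomic_region` or region text such as
#'   `"chr1:67,217,505-67,219,505"`.
#' @return numeric beta matrix.
#' @export
getbeta_region <- function(repo, samples, region) {
  stopifnot(inherits(repo, "methylation_repository"))
  probes <- probes_in_region(repo$probes, region)
  getbeta(repo, samples, intersect(probes, rownames(repo$beta)))
}

#' Per-probe group summary of a genomic region
#'
#' For every probe in the region and every level of an annotation column
#' (default `TISSUE`), reports the mean beta over non-missing values and the
#' count of non-missing samples. Groups with no samples are omitted; a probe
#' missing in all samples of a group is reported as `NA` with count 0. Rows
#' are ordered by position, then group name.
#'
#' @inheritParams getbeta_region
#' @param group_by annotation column to group samples by.
#' @return `data.frame` with columns `probe_id`, `chromosome`, `position`,
#'   `group`, `mean_beta`, `n`.
#' @export
region_tissue_summary <- function(repo, region, group_by = "TISSUE") {
  stopifnot(inherits(repo, "methylation_repository"))
  if (!group_by %in% names(repo$annotation))
    stop("unknown annotation column: ", group_by, call. = FALSE)
  if (is.character(region)) region <- parse_region(region)
  probes <- intersect(probes_in_region(repo$probes, region),
                      rownames(repo$beta))
  lab <- repo$annotation[[group_by]]
  names(lab) <- repo$annotation$ID
  lab <- lab[colnames(repo$beta)]
  groups <- sort(unique(lab[!is.na(lab)]), method = "radix")
  pos <- repo$probes$position[match(probes, repo$probes$probe_id)]
  chrom <- repo$probes$chromosome[match(probes, repo$probes$probe_id)]
  rows <- list()
  for (i in seq_along(probes)) {
    for (gr in groups) {
      v <- repo$beta[probes[i], which(!is.na(lab) & lab == gr)]
      n <- sum(!is.na(v))
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = probes[i], chromosome = chrom[i], position = pos[i],
        group = gr, mean_beta = if (n) mean(v, na.rm = TRUE) else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(probe_id = character(), chromosome = character(),
                      position = integer(), group = character(),
                      mean_beta = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Filter the sample annotation by exact-match conditions
#'
#' Conjunctive exact-match filtering, e.g.
#' `filter_samples(repo, c(TISSUE = "Blood", DISEASE = "Cancer"))`.
#'
#' @param repo a `methylation_repository`.
#' @param where named character vector of `column = value` conditions.
#' @return the matching annotation rows.
#' @export
filter_samples <- function(repo, where = character()) {
  stopifnot(inherits(repo, "methylation_repository"))
  ann <- repo$annotation
  for (col in names(where)) {
    if (!col %in% names(ann))
      stop("unknown annotation column: ", col, call. = FALSE)
    ann <- ann[!is.na(ann[[col]]) & ann[[col]] == where[[col]], , drop = FALSE]
  }
  ann
}
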