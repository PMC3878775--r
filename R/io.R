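# Readers and writers for the delimited-text formats the package exchanges:
# beta matrices (probes x samples), the 13-column sample-annotation table, and
# probe-annotation tables. TSV is the default; comma-separated files are
# detected from the header line.

#' The canonical sample-annotation column set
#'
#' Column names of the standardised annotation table: one row per array, all
#' text except `AGE` (non-negative number or missing). `ID` is the unique
#' sample identifier (a GEO accession for GEO deposits), `GSE` the experiment
#' label used to recognise arrays processed together, `SEX` the deposited sex,
#' `SEX_PRED` the sex predicted from the methylation data, and `ADDITIONAL` a
#' free-text spill-over field.
#'
#' @format character vector of 13 column names.
#' @export
ANNOTATION_COLUMNS <- c(
  "ID", "SAMPLE_NAME", "GSE", "LINEAGE", "TISSUE", "TISSUE_SUBTYPE",
  "TRANSFORMED", "DISEASE", "DISEASE_SUBTYPE", "SEX", "SEX_PRED", "AGE",
  "ADDITIONAL"
)

#' Missing-value tokens accepted by the readers
#' @keywords internal
DEFAULT_MISSING_TOKENS <- c("", "NA", "NaN", "null")

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a beta-value matrix from delimited text
#'
#' The file must have a header row of sample IDs and a first column of probe
#' IDs; remaining cells are beta values or a missing token. Tab- and
#' comma-delimited files are both accepted (detected from the header line).
#'
#' @param path path to a delimited text file.
#' @param missing_tokens character vector of cell values treated as missing.
#' @return numeric matrix (probes x samples) with `NA` for missing cells.
#' @export
read_beta_matrix <- function(path, missing_tokens = DEFAULT_MISSING_TOKENS) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in header of ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          data.table = TRUE, check.names = FALSE)
  probe_ids <- dt[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  n <- nrow(dt)
  m <- matrix(NA_real_, nrow = n, ncol = length(sample_ids),
              dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- dt[[j + 1L]]
    miss <- cell %in% missing_tokens
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(parsed))
    if (length(bad))
      stop(sprintf("non-numeric value %s at row %d, column %s of %s",
                   dQuote(cell[bad[1]]), bad[1], sample_ids[j], path),
           call. = FALSE)
    parsed[miss] <- NA_real_
    m[, j] <- parsed
  }
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix as delimited text
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces every double bit-exactly, and repeated write/read/write
#' cycles are byte-identical.
#'
#' @param m numeric beta matrix (probes x samples, `NA` missing).
#' @param path output path.
#' @param sep field separator (`"\t"` default).
#' @param missing_token text written for missing cells.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, sep = "\t", missing_token = "NA") {
  validate_beta_matrix(m)
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  chr[is.na(m)] <- missing_token
  lines <- c(
    paste(c("probe_id", colnames(m)), collapse = sep),
    if (nrow(m) > 0)
      paste(rownames(m), apply(chr, 1L, paste, collapse = sep), sep = sep)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.normalise_missing <- function(x, missing_tokens) {
  x <- as.character(x)
  x[is.na(x) | x %in% missing_tokens] <- NA_character_
  x
}

#' Read and validate a sample-annotation table
#'
#' The header must contain all 13 canonical columns (see
#' [ANNOTATION_COLUMNS]), matched case-insensitively; extra columns are
#' preserved after the canonical ones. Missing tokens are normalised to `NA`,
#' `AGE` parsed as a non-negative number, and `SEX`/`SEX_PRED` must be
#' `male`, `female`, or missing (matched case-insensitively).
#'
#' @param path path to a delimited annotation file.
#' @param missing_tokens character vector of cell values treated as missing.
#' @return a `data.frame` with canonical column names, one row per sample.
#' @export
read_annotation <- function(path, missing_tokens = DEFAULT_MISSING_TOKENS) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          data.table = FALSE, check.names = FALSE)
  idx <- match(toupper(ANNOTATION_COLUMNS), toupper(names(dt)))
  absent <- ANNOTATION_COLUMNS[is.na(idx)]
  if (length(absent))
    stop("annotation file is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  extra <- setdiff(seq_along(dt), idx)
  out <- dt[, c(idx, extra), drop = FALSE]
  names(out)[seq_along(ANNOTATION_COLUMNS)] <- ANNOTATION_COLUMNS
  for (col in names(out))
    out[[col]] <- .normalise_missing(out[[col]], missing_tokens)
  if (any(is.na(out$ID) | !nzchar(out$ID)))
    stop("annotation rows with empty ID", call. = FALSE)
  if (anyDuplicated(out$ID))
    stop("duplicate sample ID(s) in annotation: ",
         paste(unique(out$ID[duplicated(out$ID)]), collapse = ", "),
         call. = FALSE)
  for (col in c("SEX", "SEX_PRED")) {
    v <- tolower(out[[col]])
    bad <- !is.na(v) & !v %in% c("male", "female")
    if (any(bad))
      stop(sprintf("invalid %s value(s): %s", col,
                   paste(unique(out[[col]][bad]), collapse = ", ")),
           call. = FALSE)
    out[[col]] <- v
  }
  age <- suppressWarnings(as.numeric(out$AGE))
  if (any(!is.na(out$AGE) & is.na(age)))
    stop("non-numeric AGE value(s): ",
         paste(unique(out$AGE[!is.na(out$AGE) & is.na(age)]), collapse = ", "),
         call. = FALSE)
  if (any(age < 0, na.rm = TRUE))
    stop("negative AGE value(s)", call. = FALSE)
  out$AGE <- age
  out
}

#' Write a sample-annotation table
#' @param ann annotation `data.frame` as returned by [read_annotation()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, sep = "\t") {
  data.table::fwrite(ann, path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a probe-annotation table
#'
#' Requires columns `probe_id`, `chromosome` and `position` (case-insensitive).
#' Positions are 1-based. Probe IDs must be unique, positions positive.
#'
#' @param path path to a delimited file.
#' @return a `data.frame` with columns `probe_id`, `chromosome`, `position`.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  idx <- match(c("probe_id", "chromosome", "position"), tolower(names(dt)))
  if (anyNA(idx))
    stop("probe annotation must have columns probe_id, chromosome, position",
         call. = FALSE)
  out <- dt[, idx, drop = FALSE]
  names(out) <- c("probe_id", "chromosome", "position")
  out$probe_id <- as.character(out$probe_id)
  out$chromosome <- as.character(out$chromosome)
  out$position <- as.integer(out$position)
  validate_probe_annotation(out)
  out
}

#' @rdname read_probe_annotation
#' @param ann a probe-annotation `data.frame`.
#' @export
validate_probe_annotation <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("probe_id", "chromosome", "position") %in% names(ann)))
  if (anyDuplicated(ann$probe_id))
    stop("duplicate probe ID(s) in probe annotation", call. = FALSE)
  if (any(is.na(ann$position) | ann$position < 1))
    stop("probe positions must be positive 1-based integers", call. = FALSE)
  invisible(ann)
}

#' Genomic regions and region/probe lookup
#'
#' `genomic_region()` builds a 1-based, fully-inclusive region;
#' `parse_region()` parses UCSC-style text such as
#' `"chr1:67,217,505-67,219,505"` (thousands separators allowed).
#'
#' @param chromosome chromosome name, e.g. `"chr1"`.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return an object of class `genomic_region`.
#' @export
genomic_region <- function(chromosome, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.character(chromosome) || length(chromosome) != 1 || !nzchar(chromosome))
    stop("chromosome must be a non-empty string", call. = FALSE)
  if (is.na(start) || is.na(end) || start < 1 || end < 1)
    stop("region bounds must be positive 1-based integers", call. = FALSE)
  if (start > end)
    stop("region start must not exceed end", call. = FALSE)
  structure(list(chromosome = chromosome, start = start, end = end),
            class = "genomic_region")
}

#' @rdname genomic_region
#' @param text region in `"chrN:start-end"` form.
#' @export
parse_region <- function(text) {
  stripped <- gsub(",", "", trimws(text), fixed = TRUE)
  m <- regmatches(stripped,
                  regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", stripped))[[1]]
  if (length(m) != 4)
    stop("cannot parse region ", dQuote(text),
         "; expected \"chrN:start-end\"", call. = FALSE)
  genomic_region(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("%s:%s-%s\n", x$chromosome,
              format(x$start, big.mark = ","), format(x$end, big.mark = ",")))
  invisible(x)
}

#' Probes falling inside a genomic region
#'
#' Region bounds are inclusive on both sides. Results are ordered by position
#' (ties by probe ID).
#'
#' @param probe_ann probe-annotation `data.frame`
#'   (see [read_probe_annotation()]).
#' @param region a `genomic_region`, or region text accepted by
#'   [parse_region()].
#' @return character vector of probe IDs (possibly empty).
#' @export
probes_in_region <- function(probe_ann, region) {
  if (is.character(region)) region <- parse_region(region)
  stopifnot(inherits(region, "genomic_region"))
  hit <- probe_ann$chromosome == region$chromosome &
    probe_ann$position >= region$start & probe_ann$position <= region$end
  hit[is.na(hit)] <- FALSE
  sel <- probe_ann[hit, , drop = FALSE]
  sel$probe_id[order(sel$position, sel$probe_id, method = "radix")]
}
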