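# Differentially methylated position (DMP) calling: per-probe one-way ANOVA
# F-test across sample groups, Benjamini-Hochberg FDR correction, and
# directional-concordance scoring of discovery calls in an independent
# validation cohort. Computation is vectorised across probes; stats::aov on a
# handful of probes serves as the cross-check in the test suite.

#' Call differentially methylated positions by F-test
#'
#' Each probe gets a one-way analysis-of-variance F statistic across the
#' sample groups, its p-value, and a Benjamini-Hochberg adjusted q-value over
#' all tested probes (computed with [stats::p.adjust]). Probes with any
#' missing value are skipped and listed in attribute `"skipped_probes"`. A
#' probe with zero within-group variance but unequal group means gets
#' `F = Inf`, `p = 0`, and is flagged in the `zero_variance` column.
#'
#' @param m beta matrix.
#' @param groups named vector mapping every sample of `m` to a group label;
#'   at least two groups with at least two samples each.
#' @param q_threshold significance cut-off on the q-value (default 0.01).
#' @return a `data.frame` with one row per tested probe: `probe_id`, one
#'   `mean_<group>` column per group, `mean_diff` (second group minus first,
#'   two-group designs only), `f_stat`, `p_value`, `q_value`, `significant`,
#'   `zero_variance`. The group-label ordering is attached as attribute
#'   `"groups"`.
#' @export
call_dmps <- function(m, groups, q_threshold = 0.01) {
  validate_beta_matrix(m)
  if (is.null(names(groups)))
    stop("groups must be a named vector (sample -> group)", call. = FALSE)
  absent <- setdiff(colnames(m), names(groups))
  if (length(absent))
    stop("samples without group label: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  g <- factor(groups[colnames(m)])
  counts <- table(g)
  if (length(counts) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(counts < 2))
    stop("every group needs at least two samples; too small: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  complete <- rowSums(is.na(m)) == 0
  skipped <- rownames(m)[!complete]
  X <- m[complete, , drop = FALSE]
  n <- ncol(X)
  k <- length(counts)
  ind <- stats::model.matrix(~ g - 1)            # samples x groups indicator
  gmeans <- X %*% ind %*% diag(1 / as.numeric(counts))
  colnames(gmeans) <- levels(g)
  mu <- rowMeans(X)
  ssb <- drop((gmeans - mu)^2 %*% as.numeric(counts))
  sst <- rowSums((X - mu)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  zero_var <- ssw == 0
  f[zero_var & ssb > 0] <- Inf
  f[zero_var & ssb == 0] <- 0
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(probe_id = rownames(X), stringsAsFactors = FALSE)
  for (lv in levels(g)) res[[paste0("mean_", lv)]] <- gmeans[, lv]
  res$mean_diff <- if (k == 2) gmeans[, 2] - gmeans[, 1] else NA_real_
  res$f_stat <- f
  res$p_value <- p
  res$q_value <- q
  res$significant <- q < q_threshold
  res$zero_variance <- zero_var
  rownames(res) <- NULL
  attr(res, "groups") <- levels(g)
  attr(res, "skipped_probes") <- skipped
  attr(res, "q_threshold") <- q_threshold
  res
}

#' Directional concordance of discovery DMPs in a validation cohort
#'
#' For each absolute-beta-difference filter `t`, the significant discovery
#' DMPs with `|mean_diff| > t` (all significant DMPs when `t = 0`) are looked
#' up in the validation matrix, the validation group-mean difference is
#' computed with the same group orientation, and the fraction of probes whose
#' validation difference has the same strict sign as the discovery difference
#' is reported. A validation difference of exactly 0 counts as discordant.
#' Probes absent from the validation matrix (or not computable there) are
#' excluded and counted in `n_missing`.
#'
#' @param discovery DMP table from [call_dmps()] on a two-group design.
#' @param validation_beta beta matrix of the validation cohort.
#' @param validation_groups named vector mapping validation samples onto the
#'   same two group labels as the discovery design.
#' @param filters ascending thresholds on the discovery `|mean_diff|`.
#' @return a `data.frame` with one row per filter: `filter`, `n_dmps`,
#'   `n_missing`, `fraction_concordant`.
#' @export
concordance <- function(discovery, validation_beta, validation_groups,
                        filters = c(0, 0.1, 0.2)) {
  stopifnot(is.data.frame(discovery),
            all(c("probe_id", "mean_diff", "significant") %in% names(discovery)))
  glev <- attr(discovery, "groups")
  if (is.null(glev) || length(glev) != 2)
    stop("concordance requires a two-group discovery design", call. = FALSE)
  validate_beta_matrix(validation_beta)
  gv <- factor(validation_groups[colnames(validation_beta)], levels = glev)
  if (anyNA(gv))
    stop("validation samples with unknown or unmapped group label",
         call. = FALSE)
  if (any(table(gv) < 1))
    stop("validation cohort must contain both discovery groups", call. = FALSE)
  sig <- discovery[discovery$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    stop("no significant discovery DMPs to validate", call. = FALSE)
  present <- sig$probe_id %in% rownames(validation_beta)
  V <- validation_beta[sig$probe_id[present], , drop = FALSE]
  m1 <- rowMeans(V[, gv == glev[1], drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(V[, gv == glev[2], drop = FALSE], na.rm = TRUE)
  vdiff <- m2 - m1
  computable <- is.finite(vdiff)
  out <- lapply(sort(filters), function(t) {
    keep <- if (t == 0) rep(TRUE, nrow(sig)) else abs(sig$mean_diff) > t
    kp <- keep[present] & computable
    n_missing <- sum(keep) - sum(kp)
    disc_sign <- sign(sig$mean_diff[present][kp])
    val_sign <- sign(vdiff[kp])
    conc <- val_sign != 0 & val_sign == disc_sign
    data.frame(filter = t, n_dmps = sum(kp), n_missing = n_missing,
               fraction_concordant = if (sum(kp)) mean(conc) else NA_real_)
  })
  do.call(rbind, out)
}

#' Write a DMP table as TSV
#' @param dmps DMP table from [call_dmps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmp_table <- function(dmps, path) {
  data.table::fwrite(dmps, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
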