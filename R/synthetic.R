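# Synthetic 450K-style beta matrices with the structure the pipeline assumes:
# a bimodal baseline concentrated near 0 and 1, tissue clusters with
# beta-scale differential effects on a subset of probes, probe-specific
# study (batch) shifts on the logit scale, logit-scale within-group noise,
# missing cells, a chrX block carrying an X-inactivation sex signature, and
# optional M-value corruption of whole samples for QC testing. Effects and
# noise are applied on the logit scale and squashed back, which respects the
# [0, 1] bound without truncation artefacts.

.logit <- function(p) log(p / (1 - p))

#' Configuration for the synthetic methylation generator
#'
#' Defaults describe a desk-scale heterogeneous cohort: 20,000 probes, three
#' tissues of 12 samples each drawn from four studies (crossed with tissue),
#' differential methylation of effect size 0.3 (beta scale) on 10% of
#' autosomal probes, probe-specific study shifts of s.d. 0.1 and within-group
#' noise of s.d. 0.05 (both logit scale), and 1% missing cells.
#'
#' @param n_probes total probe count (chrX block included).
#' @param tissues named integer vector: samples per tissue.
#' @param n_studies number of studies (batches), crossed with tissue.
#' @param batch_sd s.d. of the probe-specific per-study logit shift.
#' @param diff_fraction fraction of autosomal probes that are
#'   tissue-differential.
#' @param effect_size beta-scale difference between the low and high tissue
#'   level of a differential probe, in (0, 1).
#' @param noise_sd logit-scale s.d. of per-cell noise.
#' @param missing_prob per-cell missingness probability.
#' @param oor_sample_fraction fraction of samples whose values are replaced by
#'   M-values (out of \[0, 1\]), for QC tests.
#' @param n_sex_probes number of chrX probes carrying the sex signature.
#' @param female_fraction probability a sample is female.
#' @param seed integer seed; the generator is fully determined by it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_probes = 20000,
                             tissues = c(Blood = 12, Brain = 12, Liver = 12),
                             n_studies = 4,
                             batch_sd = 0.1,
                             diff_fraction = 0.1,
                             effect_size = 0.3,
                             noise_sd = 0.05,
                             missing_prob = 0.01,
                             oor_sample_fraction = 0,
                             n_sex_probes = 200,
                             female_fraction = 0.5,
                             seed = 1) {
  stopifnot(n_probes >= 1, length(tissues) >= 1, all(tissues >= 1),
            !is.null(names(tissues)), n_studies >= 1, batch_sd >= 0,
            diff_fraction >= 0, diff_fraction <= 1,
            effect_size > 0, effect_size < 1, noise_sd >= 0,
            missing_prob >= 0, missing_prob <= 1,
            oor_sample_fraction >= 0, oor_sample_fraction <= 1,
            n_sex_probes >= 0, n_sex_probes < n_probes,
            female_fraction >= 0, female_fraction <= 1)
  structure(list(n_probes = as.integer(n_probes), tissues = tissues,
                 n_studies = as.integer(n_studies), batch_sd = batch_sd,
                 diff_fraction = diff_fraction, effect_size = effect_size,
                 noise_sd = noise_sd, missing_prob = missing_prob,
                 oor_sample_fraction = oor_sample_fraction,
                 n_sex_probes = as.integer(n_sex_probes),
                 female_fraction = female_fraction, seed = as.integer(seed)),
            class = "synthetic_config")
}

# bimodal baseline mixture: low (Beta(2,18)), high (Beta(18,2)), and a small
# intermediate component; clamped away from 0/1 so the logit is finite.
.baseline_betas <- function(n) {
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  b <- numeric(n)
  b[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 18)
  b[comp == 2] <- stats::rbeta(sum(comp == 2), 18, 2)
  b[comp == 3] <- stats::rbeta(sum(comp == 3), 2, 2)
  pmin(pmax(b, 0.001), 0.999)
}

#' Generate a synthetic methylation cohort
#'
#' Produces a beta matrix together with the annotation tables the pipeline
#' consumes and the ground truth the tests score against. Identical seeds give
#' bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return list with `beta` (probes x samples matrix), `annotation` (13-column
#'   sample table), `probes` (probe annotation: probe_id, chromosome,
#'   position), and `truth` (list of `sample` and `probe` data frames: tissue,
#'   study, sex and corruption per sample; differential status, per-tissue
#'   mean levels and sex-signature membership per probe).
#' @export
simulate_methylation <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .simulate_methylation_impl(config))
}

.simulate_methylation_impl <- function(cf) {
  n_samples <- sum(cf$tissues)
  tissue <- rep(names(cf$tissues), cf$tissues)
  # round-robin study assignment within tissue, so study is crossed with
  # tissue rather than confounded with it
  study <- unlist(lapply(cf$tissues, function(n)
    rep_len(seq_len(cf$n_studies), n)), use.names = FALSE)
  sex <- ifelse(stats::runif(n_samples) < cf$female_fraction,
                "female", "male")
  sample_ids <- sprintf("SYN%04d", seq_len(n_samples))
  study_ids <- sprintf("GSE9%04d", study)

  probe_ids <- sprintf("cgs%06d", seq_len(cf$n_probes))
  n_auto <- cf$n_probes - cf$n_sex_probes
  chromosome <- c(rep(paste0("chr", 1:22), length.out = n_auto),
                  rep("chrX", cf$n_sex_probes))
  position <- integer(cf$n_probes)
  for (ch in unique(chromosome)) {
    ix <- which(chromosome == ch)
    position[ix] <- 10000L + 997L * seq_along(ix)
  }

  # per-tissue mean levels
  base <- .baseline_betas(cf$n_probes)
  tiss_names <- names(cf$tissues)
  TM <- matrix(base, nrow = cf$n_probes, ncol = length(tiss_names),
               dimnames = list(probe_ids, tiss_names))
  # tissue-differential probes need at least two tissues to differ between
  n_diff <- if (length(tiss_names) >= 2) round(cf$diff_fraction * n_auto) else 0L
  diff_idx <- sort(sample.int(n_auto, n_diff))
  if (n_diff > 0) {
    lo <- stats::runif(n_diff, 0.05, 0.95 - cf$effect_size)
    hi <- lo + cf$effect_size
    for (r in seq_len(n_diff)) {
      lev <- sample(c(TRUE, FALSE), length(tiss_names), replace = TRUE)
      while (all(lev) || all(!lev))
        lev <- sample(c(TRUE, FALSE), length(tiss_names), replace = TRUE)
      TM[diff_idx[r], ] <- ifelse(lev, hi[r], lo[r])
    }
  }

  # chrX sex signature: males mostly-unmethylated promoter pattern, females
  # intermediate through X inactivation
  x_idx <- which(chromosome == "chrX")
  x_male <- pmin(pmax(stats::rbeta(length(x_idx), 2, 12), 0.001), 0.999)
  x_female <- pmin(pmax(stats::rnorm(length(x_idx), 0.5, 0.05), 0.35), 0.65)

  # cell-level means on the logit scale
  mu_logit <- .logit(TM[, tissue, drop = FALSE])
  if (length(x_idx)) {
    mu_logit[x_idx, sex == "male"] <- .logit(x_male)
    mu_logit[x_idx, sex == "female"] <- .logit(x_female)
  }
  # probe-specific study shifts
  B <- matrix(stats::rnorm(cf$n_probes * cf$n_studies, 0, cf$batch_sd),
              nrow = cf$n_probes)
  mu_logit <- mu_logit + B[, study, drop = FALSE]
  noise <- matrix(stats::rnorm(cf$n_probes * n_samples, 0, cf$noise_sd),
                  nrow = cf$n_probes)
  beta <- stats::plogis(mu_logit + noise)
  dimnames(beta) <- list(probe_ids, sample_ids)

  # M-value corruption of whole samples (out-of-range QC targets)
  n_oor <- round(cf$oor_sample_fraction * n_samples)
  oor <- rep(FALSE, n_samples)
  if (n_oor > 0) {
    oor[sample.int(n_samples, n_oor)] <- TRUE
    beta[, oor] <- log2(beta[, oor] / (1 - beta[, oor]))
  }

  if (cf$missing_prob > 0) {
    mask <- stats::runif(length(beta)) < cf$missing_prob
    beta[mask] <- NA_real_
  }

  annotation <- data.frame(
    ID = sample_ids,
    SAMPLE_NAME = paste0("synthetic ", tolower(tissue), " sample ",
                         seq_len(n_samples)),
    GSE = study_ids,
    LINEAGE = NA_character_,
    TISSUE = tissue,
    TISSUE_SUBTYPE = NA_character_,
    TRANSFORMED = NA_character_,
    DISEASE = NA_character_,
    DISEASE_SUBTYPE = NA_character_,
    SEX = sex,
    SEX_PRED = NA_character_,
    AGE = round(stats::runif(n_samples, 20, 80)),
    ADDITIONAL = NA_character_,
    stringsAsFactors = FALSE
  )
  probes <- data.frame(probe_id = probe_ids, chromosome = chromosome,
                       position = position, stringsAsFactors = FALSE)
  probe_truth <- data.frame(probe_id = probe_ids,
                            differential = seq_len(cf$n_probes) %in% diff_idx,
                            sex_probe = chromosome == "chrX",
                            stringsAsFactors = FALSE)
  for (tn in tiss_names) probe_truth[[paste0("mean_", tn)]] <- TM[, tn]
  sample_truth <- data.frame(sample_id = sample_ids, tissue = tissue,
                             study = study_ids, sex = sex,
                             out_of_range = oor, stringsAsFactors = FALSE)
  list(beta = beta, annotation = annotation, probes = probes,
       truth = list(sample = sample_truth, probe = probe_truth),
       config = cf)
}

#' Generate two-channel intensities consistent with a synthetic cohort
#'
#' Inverts the beta formula: for each generated beta b, the channels are
#' `I_M = b * (T + offset)` and `I_U = T - I_M` (clipped at 0), with
#' `T = total_intensity_scale`, so [compute_beta()] with the same offset
#' recovers b up to a worst-case error of `offset / (T + offset)` (from
#' clipping near b = 1); generated baselines stay below 0.999, so recovery is
#' exact to floating-point at `T = 1e5`.
#'
#' @param config a [synthetic_config()].
#' @param total_intensity_scale total channel intensity T (default 1e4).
#' @param offset beta-formula offset, matching [compute_beta()].
#' @return list with `intensity` (an [intensity_matrix()]) and `beta` (the
#'   betas the intensities encode).
#' @export
generate_intensity <- function(config = synthetic_config(),
                               total_intensity_scale = 1e4, offset = 100) {
  if (!is.numeric(total_intensity_scale) || total_intensity_scale <= 0)
    stop("total_intensity_scale must be positive", call. = FALSE)
  if (config$oor_sample_fraction > 0)
    stop("intensity generation requires oor_sample_fraction = 0", call. = FALSE)
  sim <- simulate_methylation(config)
  b <- sim$beta
  M <- b * (total_intensity_scale + offset)
  U <- pmax(total_intensity_scale - M, 0)
  M[is.na(b)] <- NA_real_
  U[is.na(b)] <- NA_real_
  list(intensity = intensity_matrix(M, U), beta = b)
}
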