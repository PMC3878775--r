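# Small fixtures built in code. Matrices are probes x samples with NA for
# missing cells.

tiny_beta <- function(values, n_probes, n_samples,
                      probe_ids = sprintf("cg%03d", seq_len(n_probes)),
                      sample_ids = sprintf("S%02d", seq_len(n_samples))) {
  matrix(values, nrow = n_probes, ncol = n_samples,
         dimnames = list(probe_ids, sample_ids))
}

# deterministic pseudo-random beta matrix
random_beta <- function(n_probes, n_samples, seed = 1, missing_prob = 0) {
  withr::with_seed(seed, {
    m <- tiny_beta(runif(n_probes * n_samples), n_probes, n_samples)
    if (missing_prob > 0)
      m[runif(length(m)) < missing_prob] <- NA_real_
    m
  })
}

# a fully-connected neighbour graph at uniform distance, for tests where the
# neighbourhood should be "everyone else"
full_graph <- function(m, distance = 1) {
  ids <- colnames(m)
  d <- matrix(distance, length(ids), length(ids), dimnames = list(ids, ids))
  diag(d) <- 0
  k_nearest(d, k = length(ids) - 1)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# brute-force oracles ---------------------------------------------------

# textbook Euclidean distance by double loop (no missing data)
oracle_euclidean <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (p in seq_len(nrow(m))) s <- s + (m[p, i] - m[p, j])^2
    d[i, j] <- sqrt(s)
  }
  d
}

# classical full-cohort quantile normalisation: every sample mapped rank-wise
# onto the mean of the sorted columns
oracle_full_qn <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# Benjamini-Hochberg step-up by its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[o[i]] * n / i)
    q[o[i]] <- running
  }
  q
}

# exhaustive average-linkage agglomeration on a distance matrix
oracle_average_linkage <- function(d) {
  clusters <- as.list(seq_len(ncol(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- mean(d[clusters[[a]], clusters[[b]]])
      if (h < best_h) { best_h <- h; best <- c(a, b) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}
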