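# k-NN imputation, neighbourhood quantile normalisation, mask-and-impute
# validation

test_that("knn_impute averages neighbour values with the stated weights", {
  # three samples; S01 missing at cg001
  m <- tiny_beta(c(NA, 0.5, 0.2, 0.5, 0.4, 0.5), 2, 3)
  d <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
              dimnames = list(colnames(m), colnames(m)))
  g <- k_nearest(d, k = 2)
  # uniform: (0.2 + 0.4) / 2
  expect_equal(knn_impute(m, g, "uniform")["cg001", "S01"], 0.3)
  # inverse distance: (0.2/1 + 0.4/3) / (1 + 1/3)
  expect_equal(knn_impute(m, g, "inverse_distance")["cg001", "S01"],
               (0.2 + 0.4 / 3) / (1 + 1 / 3))
  # values 0 and 1 at distances 1 and 3 give 1/4 (spec of the weight rule)
  m2 <- m; m2["cg001", "S02"] <- 0; m2["cg001", "S03"] <- 1
  expect_equal(knn_impute(m2, g, "inverse_distance")["cg001", "S01"], 0.25)
  # observed cells pass through bit-exactly
  out <- knn_impute(m, g)
  expect_identical(out["cg002", ], m["cg002", ])
})

test_that("zero-distance neighbours get the maximum finite weight", {
  m <- tiny_beta(c(NA, 0.5, 0.2, 0.5, 0.8, 0.5), 2, 3)
  d <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(colnames(m), colnames(m)))
  g <- k_nearest(d, k = 2)
  # S02 at d=0 takes weight max(1/2) = wait: weights {max finite, 1/2}
  expect_equal(knn_impute(m, g)["cg001", "S01"],
               (0.2 * 0.5 + 0.8 * 0.5) / (0.5 + 0.5))
  # all neighbours at distance zero -> uniform among them
  d0 <- matrix(0, 3, 3, dimnames = dimnames(d))
  g0 <- k_nearest(d0, k = 2)
  expect_equal(knn_impute(m, g0)["cg001", "S01"], 0.5)
})

test_that("imputation falls back to the probe mean and reports dead probes", {
  m <- tiny_beta(c(NA, 0.5, NA, 0.5, 0.3, 0.5, NA, 0.5), 2, 4)
  d <- matrix(1, 4, 4, dimnames = list(colnames(m), colnames(m))); diag(d) <- 0
  g <- k_nearest(d, k = 1)  # S01's single neighbour S02 is missing at cg001
  out <- knn_impute(m, g)
  expect_equal(out["cg001", "S01"], 0.3)  # mean over S03 (only observed)
  m2 <- m; m2["cg001", ] <- NA            # whole probe missing
  out2 <- knn_impute(m2, g)
  expect_true(all(is.na(out2["cg001", ])))
  expect_equal(nrow(attr(out2, "unimputed")), 4L)
  expect_true(all(!is.na(out)))
  expect_error(knn_impute(m[, 1:3], g), "graph")
})

test_that("imputed values stay inside the unit interval", {
  sim <- simulate_methylation(synthetic_config(n_probes = 2000,
                                               missing_prob = 0.05, seed = 5))
  g <- build_neighbor_graph(sim$beta, k = 10, n_probes = 1000, seed = 1)
  out <- knn_impute(sim$beta, g)
  expect_false(anyNA(out))
  expect_true(min(out) >= 0 && max(out) <= 1)
})

test_that("neighbourhood QN maps a sample onto the mean of sorted vectors", {
  # sample (0.1, 0.2, 0.3) with single neighbour (0.3, 0.4, 0.5) -> shifted
  # halfway: (0.2, 0.3, 0.4)
  m <- tiny_beta(c(0.1, 0.2, 0.3, 0.3, 0.4, 0.5), 3, 2)
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(colnames(m), colnames(m)))
  g <- k_nearest(d, k = 1)
  out <- neighborhood_quantile_normalize(m, g)
  expect_equal(unname(out[, "S01"]), c(0.2, 0.3, 0.4))
  expect_equal(unname(out[, "S02"]), c(0.2, 0.3, 0.4))
  # a sample identical to all its neighbours is a fixed point
  m2 <- tiny_beta(rep(c(0.1, 0.6, 0.9), 3), 3, 3)
  out2 <- neighborhood_quantile_normalize(m2, full_graph(m2))
  expect_equal(out2, m2)
  expect_error(neighborhood_quantile_normalize(tiny_beta(c(NA, 1), 1, 2),
                                               full_graph(m)),
               "knn_impute")
})

test_that("QN preserves within-sample ranks and is permutation-equivariant", {
  m <- random_beta(100, 6, seed = 8)
  g <- build_neighbor_graph(m, k = 3, n_probes = 100, seed = 1)
  out <- neighborhood_quantile_normalize(m, g)
  for (s in colnames(m))
    expect_equal(stats::cor(m[, s], out[, s], method = "spearman"), 1)
  # permuting probe order permutes the output identically
  perm <- withr::with_seed(2, sample(nrow(m)))
  g2 <- g; g2$probe_ids <- NULL
  out_perm <- neighborhood_quantile_normalize(m[perm, ], g2)
  expect_equal(out_perm, out[perm, ])
})

test_that("shared global neighbourhood reduces QN to the classical procedure", {
  for (seed in 1:3) {
    m <- random_beta(50, 7, seed = seed)
    out <- neighborhood_quantile_normalize(m, full_graph(m))
    expect_equal(out, oracle_full_qn(m), tolerance = 1e-12)
  }
})

test_that("tied input values receive the mean reference at their ranks", {
  m <- tiny_beta(c(0.2, 0.2, 0.8, 0.1, 0.3, 0.9), 3, 2)
  out <- neighborhood_quantile_normalize(m, full_graph(m))
  # ref = rowMeans(sorted) = (0.15, 0.25, 0.85); S01 ties at ranks 1,2
  expect_equal(unname(out[, "S01"]), c(0.2, 0.2, 0.85))
})

test_that("mask-and-impute validation is seeded and honours its bounds", {
  sim <- simulate_methylation(synthetic_config(n_probes = 2000, seed = 4))
  g <- build_neighbor_graph(sim$beta, k = 10, n_probes = 1000, seed = 1)
  r1 <- validate_imputation(sim$beta, g, n_mask = 100, n_repeats = 5, seed = 7)
  r2 <- validate_imputation(sim$beta, g, n_mask = 100, n_repeats = 5, seed = 7)
  expect_identical(r1, r2)  # bit-reproducible
  expect_true(all(r1$per_repeat$fraction_within_tol >= 0 &
                    r1$per_repeat$fraction_within_tol <= 1))
  # tol = 1 accepts everything
  rt <- validate_imputation(sim$beta, g, n_mask = 50, n_repeats = 2,
                            tol = 1, seed = 1)
  expect_equal(rt$mean_fraction, 1)
  # data where every sample equals its neighbours imputes perfectly
  mm <- tiny_beta(rep(seq(0.05, 0.95, length.out = 20), 4), 20, 4)
  rp <- validate_imputation(mm, full_graph(mm), n_mask = 5, n_repeats = 3,
                            seed = 1)
  expect_equal(rp$mean_fraction, 1)
  expect_error(validate_imputation(mm, full_graph(mm), n_mask = 100,
                                   n_repeats = 2, seed = 1),
               "n_mask")
})
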