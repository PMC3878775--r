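# repository build, query semantics, region summaries

make_repo_inputs <- function(dir, seed = 1) {
  sim <- simulate_methylation(synthetic_config(n_probes = 60,
                                               tissues = c(Blood = 3,
                                                           Brain = 3),
                                               n_sex_probes = 10,
                                               missing_prob = 0.05,
                                               seed = seed))
  half <- split(colnames(sim$beta), rep(1:2, each = 3))
  paths <- c(file.path(dir, "beta1.tsv"), file.path(dir, "beta2.tsv"))
  write_beta_matrix(sim$beta[, half[[1]]], paths[1])
  write_beta_matrix(sim$beta[, half[[2]]], paths[2])
  ann_path <- file.path(dir, "ann.tsv")
  write_annotation(sim$annotation, ann_path)
  probe_path <- file.path(dir, "probes.tsv")
  data.table::fwrite(sim$probes, probe_path, sep = "\t", quote = FALSE)
  list(sim = sim, beta_paths = paths, ann = ann_path, probes = probe_path)
}

test_that("repository build merges studies and round-trips through the store", {
  dir <- withr::local_tempdir()
  inp <- make_repo_inputs(dir)
  store <- file.path(dir, "store")
  repo <- build_repository(inp$beta_paths, inp$ann, inp$probes, store)
  expect_equal(ncol(repo$beta), 6L)
  expect_identical(repo$beta, inp$sim$beta)
  reopened <- open_repository(store)
  expect_identical(reopened$beta, repo$beta)
  expect_equal(reopened$annotation, repo$annotation)
  # full extraction round-trips the stored matrix exactly
  expect_identical(getbeta(repo, colnames(repo$beta), rownames(repo$beta)),
                   repo$beta)
})

test_that("overlapping samples across inputs are a conflict error", {
  dir <- withr::local_tempdir()
  inp <- make_repo_inputs(dir)
  expect_error(build_repository(c(inp$beta_paths[1], inp$beta_paths[1]),
                                inp$ann, inp$probes),
               "more than one input")
})

test_that("probe sets are resolved to their intersection", {
  dir <- withr::local_tempdir()
  inp <- make_repo_inputs(dir)
  m2 <- read_beta_matrix(inp$beta_paths[2])
  write_beta_matrix(m2[1:50, , drop = FALSE], inp$beta_paths[2])
  expect_message(
    repo <- build_repository(inp$beta_paths, inp$ann, inp$probes),
    "intersection")
  expect_equal(nrow(repo$beta), 50L)
  expect_equal(repo$meta$n_dropped_probes, 10L)
})

test_that("samples missing from the annotation abort the build", {
  dir <- withr::local_tempdir()
  inp <- make_repo_inputs(dir)
  ann <- read_annotation(inp$ann)
  write_annotation(ann[-1, ], inp$ann)
  expect_error(build_repository(inp$beta_paths, inp$ann, inp$probes),
               "lack an annotation")
})

test_that("getbeta honours request order and rejects unknown ids", {
  dir <- withr::local_tempdir()
  inp <- make_repo_inputs(dir)
  repo <- build_repository(inp$beta_paths, inp$ann, inp$probes)
  samples <- c("SYN0004", "SYN0001")
  probes <- c("cgs000010", "cgs000003", "cgs000001")
  sub <- getbeta(repo, samples, probes)
  expect_equal(dimnames(sub), list(probes, samples))
  expect_equal(sub, repo$beta[probes, samples])
  # permuting the request permutes the result identically
  sub2 <- getbeta(repo, rev(samples), rev(probes))
  expect_identical(sub2, sub[rev(probes), rev(samples)])
  # empty probe request gives a 0-row matrix
  expect_equal(dim(getbeta(repo, samples, character(0))), c(0L, 2L))
  expect_error(getbeta(repo, samples, "cg_nonexistent"), "cg_nonexistent")
  expect_error(getbeta(repo, c("nosuch", samples), probes), "nosuch")
})

test_that("region queries return position-ordered probes", {
  dir <- withr::local_tempdir()
  inp <- make_repo_inputs(dir)
  repo <- build_repository(inp$beta_paths, inp$ann, inp$probes)
  pa <- repo$probes
  chr1 <- pa[pa$chromosome == "chr1", ]
  rg <- sprintf("chr1:%s-%s", min(chr1$position), max(chr1$position))
  sub <- getbeta_region(repo, c("SYN0001", "SYN0002"), rg)
  expect_equal(rownames(sub),
               chr1$probe_id[order(chr1$position, chr1$probe_id)])
  expect_equal(nrow(getbeta_region(repo, "SYN0001", "chrZ:1-100")), 0L)
})

test_that("region summaries equal a brute-force group-by mean", {
  dir <- withr::local_tempdir()
  inp <- make_repo_inputs(dir)
  repo <- build_repository(inp$beta_paths, inp$ann, inp$probes)
  pa <- repo$probes
  chr2 <- pa[pa$chromosome == "chr2", ]
  rg <- sprintf("chr2:%d-%d", min(chr2$position), max(chr2$position))
  summ <- region_tissue_summary(repo, rg, group_by = "TISSUE")
  tissue <- stats::setNames(repo$annotation$TISSUE, repo$annotation$ID)
  for (r in seq_len(nrow(summ))) {
    v <- repo$beta[summ$probe_id[r],
                   names(tissue)[tissue == summ$group[r]]]
    expect_equal(summ$n[r], sum(!is.na(v)))
    if (summ$n[r] > 0) expect_equal(summ$mean_beta[r], mean(v, na.rm = TRUE))
    else expect_true(is.na(summ$mean_beta[r]))
  }
  expect_false(is.unsorted(summ$position))
  expect_error(region_tissue_summary(repo, rg, group_by = "NOPE"), "column")
})

test_that("annotation filtering is exact-match conjunctive", {
  dir <- withr::local_tempdir()
  inp <- make_repo_inputs(dir)
  repo <- build_repository(inp$beta_paths, inp$ann, inp$probes)
  blood <- filter_samples(repo, c(TISSUE = "Blood"))
  expect_equal(nrow(blood), 3L)
  expect_true(all(blood$TISSUE == "Blood"))
  both <- filter_samples(repo, c(TISSUE = "Blood",
                                 SEX = blood$SEX[1]))
  expect_true(all(both$SEX == blood$SEX[1]))
  expect_error(filter_samples(repo, c(NOPE = "x")), "column")
})
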