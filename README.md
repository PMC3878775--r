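# betaharmony

Tools for combining Illumina HumanMethylation450-style DNA-methylation
**beta matrices** from many independent studies into one harmonised,
queryable resource. The intended user is a bioinformatician assembling
public 450K deposits (GEO-style series matrices, TCGA-style intensity
tables) for meta-analysis, who needs the deposits cleaned, completed,
comparably normalised, and honestly diagnosed for batch structure before
any biology is read off them.

## What it does

Betas are the methylated fraction at each CpG probe,

    beta = I_M / (I_M + I_U + 100)

with `I_M`, `I_U` the methylated/unmethylated channel intensities. Around
that quantity the package provides, in pipeline order:

1. **Ingest & QC** — `compute_beta()` from two-channel intensities;
   `filter_out_of_range()` drops arrays deposited as M-values (any value
   outside [0, 1]); `filter_unannotated()` drops arrays without a record in
   the 13-column standardised annotation table; `predict_sex()` labels
   samples from the chrX intermediate-methylation signature of
   X inactivation.
2. **Neighbourhoods** — `build_neighbor_graph()` finds each sample's 25
   nearest neighbours by Euclidean distance on a random 10,000-probe
   subsample (missingness-rescaled, deterministic tie-breaking);
   `neighbor_stability()` checks the neighbour sets barely depend on the
   subsample.
3. **Imputation** — `knn_impute()` fills missing betas from the
   neighbours' values (inverse-distance weighting by default);
   `validate_imputation()` masks 1,000 observed probes of a random sample,
   re-imputes, and scores recovery within 0.2 absolute beta, 100 times.
4. **Normalisation** — `neighborhood_quantile_normalize()` quantile-maps
   each array onto the mean sorted distribution of itself plus its 25
   neighbours, so heterogeneous tissues are never forced onto one global
   distribution.
5. **Batch diagnostics** — `banded_distance()` restricts the distance to
   probes with absolute beta differences in a band such as [0, 0.1);
   `hierarchical_cluster()` + `label_purity()` show that small differences
   cluster samples by *experiment* while 0.2–0.3 differences cluster by
   *tissue*.
6. **DMP calling & validation** — `call_dmps()` per-probe one-way F-tests
   with Benjamini–Hochberg q-values; `concordance()` scores the sign
   agreement of discovery calls in an independent cohort, per
   effect-size filter.
7. **Repository & query** — `build_repository()` merges per-study matrices
   into an exact-round-trip store; `getbeta(repo, samples, probes)`,
   `getbeta_region(repo, samples, "chr1:67,217,505-67,219,505")`,
   `region_tissue_summary()`, `filter_samples()`.
8. **Synthetic data** — `simulate_methylation(synthetic_config())`
   generates cohorts with bimodal betas, tissue clusters, study batch
   shifts, missingness and a sex signature, plus the ground truth, so the
   whole pipeline is testable offline.

A command line wrapping the same functions ships as
`inst/cli/betaharmony` (verbs `simulate`, `qc`, `neighbors`, `normalize`,
`validate-imputation`, `batch-diagnostics`, `dmp`, `concordance`, `build`,
`get`, `summary`, `samples`); see `?run_cli`.

## Worked example

```r
library(betaharmony)

# a synthetic cohort: 20,000 probes, 3 tissues x 12 samples, 4 studies
sim <- simulate_methylation(synthetic_config(seed = 1))
dim(sim$beta)
#> [1] 20000    36

# QC, neighbourhood graph, imputation, normalisation
qc  <- filter_out_of_range(sim$beta)
g   <- build_neighbor_graph(qc$beta, k = 25, n_probes = 10000, seed = 1)
imp <- knn_impute(qc$beta, g)
nrm <- neighborhood_quantile_normalize(imp, g)

# how well does neighbour imputation recover held-out values?
validate_imputation(qc$beta, g, n_mask = 1000, n_repeats = 100, seed = 1)
#> imputation_validation: 100 repeats x 1000 masked probes, tol 0.2
#>   mean fraction within tol:   1.0000
#>   pooled fraction within tol: 1.0000
```

The two fractions are the share of artificially masked beta values
re-imputed to within 0.2 of their true value — per-repeat mean and pooled
over all 100,000 masked cells. On this cleanly clustered synthetic cohort
recovery is essentially perfect; on real heterogeneous deposits the same
experiment is reported in the high-90% range.

```r
# differential methylation between two groups, then batch-aware caution
groups <- setNames(sim$truth$sample$tissue, sim$truth$sample$sample_id)
dmps <- call_dmps(nrm[, groups %in% c("Blood", "Brain")],
                  groups[groups %in% c("Blood", "Brain")])
head(dmps[dmps$significant, c("probe_id", "mean_diff", "q_value")])
```

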