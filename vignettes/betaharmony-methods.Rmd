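---
title: "Methods: harmonising heterogeneous 450K beta matrices"
author: "betaharmony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonising heterogeneous 450K beta matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaharmony)
```

## The problem

Public repositories hold tens of thousands of Illumina HumanMethylation450
arrays, deposited by hundreds of independent studies. Most deposits are beta
values — the methylated fraction at each CpG,
$\beta = I_M / (I_M + I_U + 100)$, where $I_M$ and $I_U$ are the methylated
and unmethylated channel intensities and the offset of 100 regularises
low-intensity probes. Combining these deposits into one analysable matrix
runs into four obstacles that this package addresses in order:

1. **Heterogeneous deposits.** Some arrays are deposited as M-values
   (logit-scale, unbounded) rather than betas, and some have no usable sample
   annotation. `filter_out_of_range()` removes any array carrying a value
   outside the closed interval $[0, 1]$; `filter_unannotated()` removes
   arrays without an annotation record. Values exactly 0 or 1 are legitimate
   betas and are kept.
2. **Missing values.** Probes that fail to register above background are
   deposited as missing. Across thousands of samples almost every probe is
   missing somewhere, so complete-case analysis collapses.
   `knn_impute()` fills each missing cell from the sample's nearest
   neighbours.
3. **Distribution shifts.** Arrays from different studies and tissues have
   visibly different beta distributions, so classical full-cohort quantile
   normalisation would erase real tissue differences.
   `neighborhood_quantile_normalize()` instead normalises each array only
   against its own 25 nearest neighbours.
4. **Batch effects.** Even after normalisation, small methylation differences
   align with the depositing experiment rather than biology.
   `banded_distance()` plus `label_purity()` quantify this, and
   `call_dmps()`/`concordance()` show why effect-size filters matter when
   interpreting differences found in public data.

## Neighbourhoods

All neighbourhood operations use Euclidean distance between samples on a
random subsample of 10,000 probes (one shared subsample per graph build;
drawing all ~450k probes would cost far more and, as the stability check
shows, changes nothing). With missing data, the squared differences are
summed over pairwise-complete probes and rescaled by $P / n_{ij}$ (total
subsampled probes over shared probes), keeping distances comparable across
pairs with different missingness. Pairs sharing no probe are incomparable and
rank last. Each sample's $k = 25$ nearest neighbours (ties broken
lexicographically by sample ID, so results are order-invariant and fully
deterministic) define its neighbourhood for both imputation and
normalisation. `neighbor_stability()` rebuilds the graph under different
probe subsamples and reports the mean Jaccard overlap of neighbour sets; on
clustered data it is close to 1, which is what justifies using a single
subsample.

## Imputation

A missing beta at probe $p$ in sample $s$ is the weighted mean of the
neighbours' values at $p$, over neighbours observed there. Inverse-distance
weights are the default ($w = 1/d$; zero-distance neighbours receive the
largest finite weight present, or uniform weights if all distances are zero);
uniform weighting is available. If every neighbour is missing at $p$ the
probe's mean over all other samples is used; if the probe is missing
everywhere the cell stays missing and is reported. Observed values are never
altered, and imputed values are clipped to $[0, 1]$.

`validate_imputation()` measures accuracy exactly the way it is quoted:
repeatedly mask 1,000 observed probes of a randomly chosen sample, re-impute
them from the 25 nearest neighbours (without normalisation), and record the
fraction recovered within 0.2 absolute beta. Both the mean of the per-repeat
fractions and the pooled fraction over all masked cells are reported.

## Neighbourhood quantile normalisation

For sample $s$, the reference distribution is the element-wise mean of the
sorted value vectors of $\{s\} \cup \text{neighbours}(s)$ — 26 arrays at the
default $k$. The sample's values are replaced rank-wise by the reference;
tied input values receive the mean of the reference values at the rank
positions the tie group occupies. Including the sample itself makes the map a
contraction toward the neighbourhood rather than an outright replacement,
and normalising every sample against its own neighbourhood means no single
global distribution is imposed. Within-sample ranks are preserved exactly,
and when every sample shares one global neighbourhood the procedure reduces
to classical full-cohort quantile normalisation (a test asserts this
equivalence to 1e-12). Imputation runs first; normalisation requires a
complete matrix.

## Banded batch diagnostics

The banded distance between two complete samples keeps only probes whose
absolute beta difference lies in $[\ell, h)$ and returns the root mean square
of those differences. Design choices, made where the construction was open:

* **Half-open bands** $[\ell, h)$ so that the standard bands 0–0.1, 0.1–0.2,
  0.2–0.3 partition cleanly; the upper edge is closed only at $h = 1$ so the
  full range can be covered.
* **Count normalisation**: dividing by the in-band count makes bands with
  very different probe counts comparable; only the qualitative cluster
  structure is interpreted, not absolute heights.
* **Empty bands give distance 0**: two samples with *no* differences at a
  given scale are maximally similar at that scale.
* Average linkage is the default for the subsequent `hierarchical_cluster()`.

`label_purity()` cuts the dendrogram into $k$ clusters and reports purity and
the adjusted Rand index against any annotation label. On synthetic data with
study shifts of s.d. 0.1 (logit) and tissue effects of 0.25 (beta), the
$[0, 0.1)$ band clusters by study and the $[0.2, 0.3)$ band by tissue — the
signature of batch effects dominating small differences.

Sex-chromosome probes are excluded before computing banded distances in the
package's own diagnostics: the X-inactivation signature puts opposite-sex
pairs of the *same* tissue into the 0.2–0.3 band, and under count
normalisation a handful of chrX probes would weigh as much as hundreds of
tissue probes. Dropping sex chromosomes before cross-sample clustering is
standard practice in methylation QC for the same reason.

## DMP calling and concordance

`call_dmps()` computes a per-probe one-way ANOVA F statistic across groups
(vectorised over probes; `stats::aov` on single probes is the test oracle),
with Benjamini–Hochberg adjusted p-values ("q-values" in the common usage of
this literature) and a default significance threshold of $q < 0.01$. Probes
with missing values are skipped and reported. Zero within-group variance
with unequal means yields $p = 0$ and a flag.

`concordance()` takes the significant discovery DMPs, optionally filtered to
$|\Delta\beta| > t$ for each threshold $t$ (the filter applies to the
*discovery* difference, strict inequality; $t = 0$ keeps all significant
calls), and reports the fraction whose validation-cohort mean difference has
the same strict sign. A validation difference of exactly zero counts as
discordant (conservative). Filtering on effect size raises concordance —
the reason small methylation differences found in public data should be
interpreted cautiously.

## The synthetic generator

`simulate_methylation()` emulates the structure the pipeline assumes, with
all randomness drawn from one seed:

* **Bimodal baseline**: probe means from a mixture of Beta(2, 18),
  Beta(18, 2) (45% each) and Beta(2, 2) (10%), clamped to [0.001, 0.999] —
  the characteristic two-peak methylation marginal (well under 30% of values
  fall in (0.3, 0.7)).
* **Tissue structure**: a configurable fraction of autosomal probes (default
  10%) is differential; each such probe gets a low and a high level separated
  by the effect size (default 0.3 beta) and a random, non-constant
  assignment of tissues to levels.
* **Batch structure**: studies are crossed with tissue (round-robin), and
  each probe × study combination receives an additive logit-scale shift of
  s.d. 0.1 by default — probe-specific, shared by all samples of the study,
  which is what makes same-study samples cluster in the small-difference
  band.
* **Noise**: per-cell logit-scale Gaussian noise, s.d. 0.05 by default.
  Effects and noise are applied on the logit scale and squashed back through
  the logistic, respecting $[0, 1]$ without truncation artefacts.
* **Sex signature**: a block of chrX probes (default 200) with
  mostly-unmethylated levels in males and intermediate levels
  (X inactivation) in females, enabling `predict_sex()` tests.
* **Missingness** (default 1% of cells) and optional whole-sample M-value
  corruption for QC tests.

Defaults describe a desk-scale cohort: 20,000 probes, three tissues of 12
samples each from four studies — large enough that 25-NN neighbourhoods span
tissues, small enough that the full mask-and-impute validation (100 repeats
of 1,000 probes) runs in well under a minute.

What the generator does **not** model: Infinium I/II probe-type chemistry,
realistic intensity noise, correlated missingness (failed probes cluster by
array region in reality), age or disease effects, and cell-composition
mixtures. Passing tests on this generator therefore demonstrate that the
algorithms recover the structure they target under clean clustered
heterogeneity — not that real GEO/TCGA deposits meet these accuracy numbers.

## Sex prediction

The annotation schema records a predicted sex per sample. The rule used
here: mean beta over annotated chrX probes in $[0.3, 0.7]$ → female
(X inactivation leaves female chrX intermediate), otherwise male; fewer than
10 usable chrX probes → undetermined. The bounds are parameters; the
defaults recover the generating label on >95% of synthetic samples.

## Numerical and degenerate-input conventions

* Distances are computed by cross-product identities; tiny negative rounding
  residues are clamped to zero before the square root (oracle agreement to
  1e-12 against a brute-force double loop).
* Matrix writers emit 17 significant digits, so write/read round trips are
  bit-exact and repeated writes are byte-identical; the repository store is
  built on the same writers.
* Single-sample matrices give empty neighbour lists with a warning; `k`
  exceeding $n - 1$ is clamped; an all-dropped QC result is an empty matrix
  plus a report, not an error.
* Unknown IDs in repository queries are a hard error listing every offender;
  silent dropping would corrupt downstream meta-analyses.
* Genomic coordinates are 1-based and fully inclusive; region text accepts
  thousands separators; probes are located by single position (strand is
  ignored).

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from code:
the full-parameter imputation validation runs on the default 20,000 × 36
cohort; DMP parameter recovery on 10,000 probes with 20 samples per group;
banded-distance diagnostics on 3,000-probe, 32-sample cohorts over five
seeds; oracle equivalences on matrices of at most 10 samples. These sizes
were chosen as the smallest at which the clustered structure is
unambiguous.

## Known limitations

* The neighbour graph is exact ($O(n^2)$ distances); the package targets
  desk scale (hundreds to a few thousand samples), not repository scale.
* Imputation quality degrades when a sample's neighbourhood spans tissues
  and the probe is tissue-differential; with 36 samples and $k = 25$ this
  bias is visible but bounded (inverse-distance weighting keeps it small).
* DMP calling is positionwise with no covariate adjustment or
  cell-composition deconvolution.
* QC is array-level only: no detection-p filtering, probe masking, or
  intensity-level normalisation (two-channel information is usually absent
  from public beta deposits).
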