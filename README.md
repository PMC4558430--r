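# crvnet

Differential protein–protein interaction (PPI) network markers from
expression data, scored by carcinogenesis relevance values (CRV).

## What this solves, and for whom

Carcinogenesis rewires protein interactions, not only protein abundances.
Given (i) an expression table whose samples are labeled cancer (split into
early and late clinical stages) or normal and (ii) an undirected PPI edge
list keyed by gene symbol, `crvnet` reverse-engineers a refined interaction
network per condition, contrasts cancer against noncancer, and ranks each
protein by how much its interaction neighborhood changes. It is aimed at
systems-biology analyses of staged tumor cohorts (e.g. TCGA RNA-seq with
BioGRID interactions, pre-mapped to one symbol namespace) and at method
work on differential-network statistics.

## The method

Each target protein *i* follows the linear association model on per-gene
z-scores,

    x_i[n] = Σ_j α_ij x_j[n] + ω_i[n],

over its PPI neighbors *j* in the analysis pool. The pipeline:

1. **Pool**: per-gene two-group ANOVA (cancer vs normal, raw values),
   Bonferroni-adjusted p < 0.01; screened proteins without measured PPI
   partners are dropped and measured one-hop neighbors added.
2. **Identification**: per protein, no-intercept least squares (the
   Gaussian MLE), model order chosen by AIC `n·ln(RSS/n) + 2m` over
   correlation-ranked nested models, coefficients pruned by two-sided
   t-test (p ≥ 0.05 removed), estimates symmetrized by larger magnitude.
   One noncancer matrix `A_N`; cancer matrices `A_C^k` for early, late and
   the pooled total stage.
3. **CRV**: `D^k = A_C^k − A_N`; `CRV_i = Σ_j |d_ij|`.
4. **Significance**: degree-preserving rewiring null (double edge swaps,
   observed |d| multiset reassigned; default 1e5 replicates);
   `p = (1+r)/(N+1)`; significant at p ≤ 0.01. Core markers = significant
   in both stages; the rest are stage-specific.

A seeded synthetic-data generator (stationary Gaussian of the association
model, spectral radius capped, contaminated candidate edges) makes the
whole pipeline testable without external data.

## Worked example

```r
library(crvnet)

cfg <- simulation_config(seed = 1L, n_early = 200L, n_late = 200L,
                         n_normal = 200L, noise_sd = 0.5)
ds  <- generate_dataset(cfg)
g   <- build_candidate_network(rownames(ds$expression$early), ds$candidate_edges)
A_N <- identify_network(z_transform(ds$expression$normal), g, condition = "normal")
A_C <- identify_network(z_transform(ds$expression$early),  g, condition = "cancer-early")
D   <- differential_network(A_C, A_N)
crv <- compute_crv(D)
p   <- permutation_pvalues(g, D, n_perm = 10000, seed = 2L)

expr_all <- cbind(ds$expression$early, ds$expression$normal)
tab <- marker_table(crv, p, expr_all,
                    colnames(ds$expression$early),
                    colnames(ds$expression$normal))
head(tab, 5)
#>   protein    crv p_value cancer_avg_exp control_avg_exp log2_fc marker_class
#> 1    P031 1.2089 0.02630          436.0           289.9  0.5887         none
#> 2    P002 1.1081 0.04830          427.6           296.0  0.5305         none
#> 3    P050 1.0843 0.05389          418.5           293.9  0.5102         none
#> 4    P007 0.9765 0.36296          429.7           291.4  0.5604         none
#> 5    P018 0.9030 0.25987          426.3           298.4  0.5144         none
sum(tab$protein[1:5] %in% ds$truth$early)
#> [1] 5
```

All five top-CRV proteins are truly rewired ones: `crv` measures each
protein's total change in association ability between the cancer and
normal networks, `p_value` its rank against degree-preserving rewirings,
and `log2_fc` the ordinary expression fold change (computed from raw
averages, independent of the network statistic).

The package also ships a small table of published liver-cancer marker rows
(`inst/extdata/hcc_marker_rows.tsv`); recomputing `log2_fold_change()`
from its printed average-expression pairs reproduces every printed
fold-change value at 2-decimal precision.

## Analysis workflow

`analysis/01_simulate.R` … `06_highpower_run.R` run the full narrative:
simulate the emulated study design (19 early / 18 late / 24 normal
samples), select the pool, identify the four networks (normal, early,
late, total), compute CRVs with permutation p-values, classify markers,
evaluate against the generator's ground truth, and repeat the pipeline at
a well-powered scale (200 samples per condition). Each script writes its
tables under `results/`.

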