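# targetrank

Prioritization of cell-surface immunotherapy targets from cancer expression
data.

CAR-T cells, antibody-drug conjugates and therapeutic antibodies all need a
target protein that is highly and homogeneously expressed on tumor cells,
minimally expressed in normal tissues, and confidently localized to the cell
surface. Given a genes×samples expression matrix (surface proteomics or
RNA-seq) for a cancer phenotype, `targetrank` joins per-gene expression
summaries with quantitative annotation features — normal-tissue expression,
surface-localization evidence, tumor dependency, therapeutic availability —
and compresses them into one ranked score per gene. It is written for
translational researchers triaging screening hits into a short validation
list.

## The model

Each feature column is rescaled to [0, 1] (rank percentile or min–max),
missing values are imputed (zero / neutral / min / median), a one-parameter
monotone curving transform is applied, and genes are scored by the
normalized weighted average

```
s_g = Σ_i w_i · x_gi^exp(c_i) / Σ_i |w_i|
```

where `w_i` is a signed feature weight (negative for lower-is-better
features such as normal-tissue expression) and `c_i` the curve parameter
(`c = 0` identity; `c > 0` accentuates differences among high values,
`c < 0` among low ones). Rankings are evaluated by mean average precision
(MAP) against known-positive targets (genes with approved or clinical-stage
therapy records in the phenotype) and known-negative targets (genes whose
phenotype records were all discontinued). The weights and curves are fitted
by maximizing MAP: sequential forward selection with per-coordinate Brent
refinement, followed by a real-coded genetic algorithm with periodic
Nelder-Mead sub-optimization — against one phenotype or several at once
("multi-cancer").

## Worked example

The package ships a toy neuroblastoma ("nbl") project with eight genes and
five snapshot tables:

```r
library(targetrank)
toy <- system.file("extdata", "toy", package = "targetrank")
built <- config_projects(read_project_config(file.path(toy, "project.yaml")))
proj <- built$projects$nbl
rep <- score_genes(proj$fm, catalog = built$catalog, labels = proj$labels)
print(rep, n = 8)
#> <tr_report> 8 genes, phenotype 'nbl', MAP = 1.0000 (labeled_only)
#>    gene  score rank percentile
#> 1  GPC2 0.6122    1     100.00
#> 2   ALK 0.4918    2      85.71
#> 3   MYC 0.2949    3      71.43
#> 4  CD19 0.2612    4      57.14
#> 5  EGFR 0.2612    5      42.86
#> 6  ACTB 0.2133    6      28.57
#> 7  DLL3 0.1980    7      14.29
#> 8 GAPDH 0.1888    8       0.00
```

GPC2 and ALK — the two genes with active nbl drug records — rank first and
second: both are highly expressed in the tumor samples, low in the
normal-tissue table, and carry strong surface evidence. MYC is highly
expressed and a strong dependency but has no surface evidence; ACTB/GAPDH
are high everywhere (no tumor specificity). The attached MAP = 1.0 says the
known positives outrank the known negatives (DLL3 and EGFR, whose nbl
records were discontinued); `labeled_only` is the negative-aware evaluation
mode.

Fitting weights and curves on the built-in synthetic benchmark (1000 genes,
2 phenotypes, 10 planted ideal targets each):

```r
fix <- build_fixture(fixture_config(decoy_fraction = 0, seed = 7))
projects <- fixture_projects(fix)
objective(default_catalog(), projects)
#> [1] 0.83378
fit <- tr_fit(projects, seed = 7)
print(fit)
#> <tr_fit> multi_cancer over 2 project(s) [pheno1, pheno2], seed 7
#>   MAP: default 0.8338 -> SFS 1.0000 -> GA 1.0000
#>   selected features: dependency_mean
```

Default parameters already rank the planted targets well (MAP 0.834); the
fitted parameters recover them perfectly. `coef(fit)` returns the fitted
weight/curve vector, `predict(fit, project)` scores new data with it, and
`plot(fit)` draws the optimization trace.

A thin command-line wrapper over the same functions lives at
`inst/cli/targetrank.R`:

```sh
Rscript inst/cli/targetrank.R score    -c project.yaml -o report.tsv
Rscript inst/cli/targetrank.R optimize -c project.yaml -o params_opt.yaml --seed 7
Rscript inst/cli/targetrank.R fixture  -o fixture/ --n-genes 1000 --seed 7
```

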