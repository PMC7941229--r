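# tmeclass

Tumour-microenvironment-based molecular subtyping of high-grade serous
ovarian cancer (HGSOC) expression cohorts, for computational biologists who
want the full discovery-to-validation workflow as reusable, tested R
functions rather than a one-off analysis.

Bulk HGSOC tumours are mixtures of tumour cells, infiltrating immune cells
and stroma. `tmeclass` virtually microdissects a gene × sample expression
matrix by **consensus non-negative matrix factorization** (cNMF): X ≈ WH
with non-negative program loadings W and per-sample usages H, fitted by
multiplicative updates minimizing ‖X − WH‖²_F, the rank chosen by a
Gaussian-residual BIC, and stability assessed by a consensus matrix over
random restarts. Samples are assigned to their arg-max factor; factors
whose members carry significantly elevated **immune enrichment scores**
(IES, single-sample GSEA of an immune signature) form the immune class,
which **stromal enrichment scores** (SES) refine into an
*activated-immune* and a *CAFs-immune* (carcinoma-associated fibroblast)
subtype, the remainder being *inactivated-immune*. Pairwise differential
expression derives disjoint subtype marker templates that project into new
cohorts by **nearest-template prediction** (cosine distance on z-scored
expression, significance by size-matched random gene sets). Around the
classifier sit the characterization analyses: TMB and cytolytic activity,
96-channel mutation-signature deconvolution by non-negative least squares,
broad copy-number burden, promoter CpG-island silencing calls
(Δβ + expression anti-correlation), Kaplan-Meier/log-rank and Cox outcome
contrasts, exact r×c Fisher tests of clinical covariates, and ridge-based
IC50 imputation from a reference cell-line panel.

Because the original cohorts are large controlled-access downloads, the
package ships a **synthetic multi-omic cohort generator** with planted
ground truth (latent expression programs, three subtypes, immune-correlated
methylation silencing, subtype-dependent mutation burden/signatures/
survival/copy number). Every stage is tested end to end against that
ground truth; see `vignettes/tme-subtyping-methods.Rmd` for the model, the
generator's assumptions, and what the recovery results do and do not show
about real data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
300-sample, 2,000-gene cohort (`Rscript analysis/01_simulate.R` …
`08_report.R`). The core discovery step in code:

```r
library(tmeclass)

cfg  <- cohort_config(seed = 101)          # 300 samples, 2,000 genes, k = 5
gen  <- generate_expression(cfg)           # cohort + ground-truth manifest

disc <- run_discovery(gen$cohort,
                      immune_set  = gen$truth$marker_sets$immune_signature,
                      stromal_set = gen$truth$marker_sets$stromal_signature,
                      k_range = 2:8, n_restarts = 8, seed = 11,
                      out_dir = "results/discovery")

table(disc$labels$labels$subtype)
adjusted_rand_index(disc$labels$labels$subtype,
                    gen$truth$subtype[disc$labels$labels$sample])
```

On this cohort the run prints:

```
Chosen rank: 5
Cophenetic correlation: 0.997
  activated        CAFs inactivated
        115          60         125
ARI against planted subtypes: 0.943
```

BIC recovers the planted rank 5; the consensus partition is essentially
deterministic (cophenetic 0.997); and the two-tier classification matches
the planted subtypes at ARI 0.94. Projecting the derived templates into an
independently simulated cohort (`analysis/03_validate.R`) classifies 99.3%
of samples correctly, with IES and SES differing across predicted subtypes
at Kruskal-Wallis p ≈ 2×10⁻⁴⁸ and 8×10⁻⁴³, and the subclass map matching
each training subtype to its validation counterpart (Bonferroni p = 0.018).
Downstream, the immune class shows the planted genomic phenotype — median
TMB 2.45 vs 1.26 mut/Mb, higher cytolytic activity, lower broad copy-number
burden (all rank-test p < 10⁻⁴²) — the CAFs subtype has the worst survival
(CAFs vs rest HR = 1.94, 95% CI 1.38–2.73; activated vs CAFs pairwise
log-rank p = 1.0×10⁻⁴), all 50 planted silenced genes are recovered with no
false calls, and the five imputed drugs reproduce the planted resistance
ordering activated < inactivated < CAFs.

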