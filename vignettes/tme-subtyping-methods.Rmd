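---
title: "Methods: tumour-microenvironment-based subtyping of HGSOC expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumour-microenvironment-based subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tmeclass)
```

# Overview

`tmeclass` implements a tumour-microenvironment (TME) based molecular
subtyping workflow for bulk expression cohorts of high-grade serous ovarian
cancer (HGSOC), together with the downstream immunogenomic, epigenetic,
survival and drug-response analyses that characterize the subtypes. The
workflow has two tiers:

1. **Class discovery.** Consensus non-negative matrix factorization (cNMF)
   virtually microdissects the cohort into latent expression programs;
   samples are assigned to their dominant factor and factors are grouped
   into an *immune* and a *non-immune* class by their members' immune
   enrichment scores (IES).
2. **Subtype refinement.** Within the immune class, stromal enrichment
   scores (SES) split factors dominated by carcinoma-associated fibroblasts
   (*CAFs-immune*) from the remaining *activated-immune* factors; the
   non-immune class becomes *inactivated-immune*.

A marker-gene classifier derived by pairwise differential expression then
projects the three subtypes into independent cohorts by nearest-template
prediction (NTP). Because the real cohorts behind this design are large
controlled-access downloads, the package ships a synthetic multi-omic
cohort generator with planted ground truth; every pipeline stage is
exercised and tested end to end against that ground truth.

# The factor model

Expression is modelled on the linear (FPKM-like) scale as a non-negative
product $X \approx WH$ with $W$ (genes × k) the program loadings and $H$
(k × samples) the per-sample program usage. `nmf_factorize()` minimizes the
squared Frobenius reconstruction error by Lee–Seung multiplicative updates,
which preserve non-negativity and never increase the objective; iteration
stops when the relative objective change falls below `tol` (default `1e-5`)
or after `max_iter` sweeps (default 200). $W$ columns are rescaled to unit
L2 norm with the compensation absorbed into $H$, so factor usage is
comparable across factors. Before factorization each gene row is scaled to
unit maximum (`prepare_nmf_input()`): this tames the FPKM dynamic range
while keeping non-negativity, and makes every gene contribute comparably to
the fit.

**Consensus.** `consensus_nmf()` repeats the factorization from random
initializations (default 10 restarts), assigns every sample to its arg-max
factor per restart, and records the fraction of restarts in which each
sample pair co-assigns. The cophenetic correlation between `1 - C` and the
cophenetic distances of its average-linkage dendrogram summarizes stability
(1 for perfectly reproducible partitions). Downstream assignment uses the
lowest-error restart.

**Rank selection.** The factorization rank is chosen by a Gaussian-residual
BIC, $\mathrm{BIC}(k) = NM\,\ln(\mathrm{RSS}_k/NM) + k(N+M)\ln(NM)$, over a
scan range (default 2–8), taking the best-restart residual per rank.
Reconstructions below a relative error of $10^{-9}$ are treated as exact so
that noiseless low-rank inputs tie at the floor and the tie breaks toward
the smaller rank.

**Factor classification.** For each factor, a one-sided Mann–Whitney test
compares the member samples' IES against all other samples; the factor is
*immune* iff p < `alpha` **and** the member median IES exceeds the cohort
median. Among immune factors the same rule applied to SES marks *CAFs*
factors; remaining immune factors are *activated* and non-immune factors
*inactivated*. `alpha` defaults to 0.001 at cohort scale (n ≈ 300); the
test-suite's 90-sample fixtures use `alpha = 0.05` because an ~18-member
CAFs factor gives the rank test limited power at that size. Factors with
fewer than three members are flagged unclassifiable and their members take
the subtype of the nearest classified factor centroid in (IES, SES) space;
all ties break deterministically toward the lowest factor index and are
logged.

# Enrichment scoring

`ssgsea()` implements single-sample gene-set enrichment: per sample, genes
are ranked descending by expression (average ranks on ties) and the score
is the summed difference between the weighted in-set and unweighted
out-of-set cumulative distributions, with rank-weight $r^\alpha$ and
$\alpha = 0.25$ by default. Scores are rank-based, hence invariant to any
strictly monotone per-sample transform, and optionally normalized by the
global score range. The implementation is cross-checked in the tests
against an independent loop-based oracle to $10^{-9}$.

IES and SES are ssGSEA scores of an immune and a stromal signature;
defaults ship as editable GMT files (`inst/extdata/`), and the synthetic
cohorts carry their own planted marker sets. Cell-type abundance is scored
as the arithmetic mean of log2(x+1) expression over marker genes — a
deliberate, documented approximation to population-specific marker-panel
scoring rather than a port of published coefficient tables. Cytolytic
activity is the geometric mean of GZMA and PRF1 (offset 0.01, the
convention of the cytolytic-activity literature), and the M1/M2 ratio uses
an $\epsilon = 10^{-6}$ guard.

# The subtype classifier

`differential_expression()` uses two-sided Mann–Whitney tests per gene on
log2 expression with Benjamini–Hochberg correction; a gene is significant
iff q < 0.05 and |log2FC| exceeds the fold-change threshold. A gene is a
marker of a subtype only when it is significantly over-expressed against
*each* other subtype separately, which makes the three marker lists
disjoint by construction. The package default fold-change threshold for
template derivation is 0.4 (exposed in every call): the synthetic cohorts'
compartment fold-changes are moderate by construction (for example the
effector-gene contrast between the two immune subtypes is ≈ 0.5 on the
log2 scale), and a threshold of 1 would leave the activated subtype without
markers. On real data this threshold should be revisited; it is a tuning
parameter, not a constant of the method.

`ntp_classify()` standardizes each gene (z-score across samples), builds a
0/1 indicator template per subtype over the union of marker genes, and
assigns each sample to the subtype with the smallest cosine distance.
Significance comes from size-matched random gene-set draws (default 1,000):
p is the add-one-corrected fraction of random templates at least as close,
BH-adjusted across samples. `subclass_map()` quantifies cross-cohort
subtype correspondence by the Spearman correlation of subtype centroids
over the shared gene space, with a permutation null over sample labels and
Bonferroni correction over the subtype grid.

# Immunogenomics, epigenetics, outcome statistics, drug response

* **TMB** counts non-synonymous variants (configurable classification set)
  per megabase, default exome size 38 Mb.
* **Mutation signatures**: 96-channel trinucleotide spectra are deconvolved
  against a reference signature matrix by non-negative least squares
  (Lawson–Hanson, via `pracma::lsqnonneg`); exposures are reported as
  fractions. A synthetic, clearly-labelled 3-signature reference ships for
  testing; real analyses should supply a COSMIC-format matrix.
* **Broad CNA burden** is the fraction of chromosome arms beyond ±0.3.
* **Group-wise mutated-gene enrichment** is a frequency-based Fisher-exact
  screen (minimum 5 mutated samples per tested gene, BH-corrected); it is
  not a background-corrected driver caller.
* **Epigenetic silencing**: one promoter CpG-island probe per gene (highest
  tumour variance); a gene is *silenced* iff Δβ (tumour − normal) ≥ 0.2
  with BH q < 0.05 **and** the β–expression Spearman correlation across
  tumours ≤ −0.3 with BH q < 0.05; *activated* with all signs reversed. The
  thresholds are exposed; the compound rule makes calls monotone in each
  threshold. Anti-correlation is evaluated within tumours (no
  tumour-adjacent expression is assumed to exist).
* **Outcome statistics** wrap the standard implementations behind one
  validated interface: `survival::survdiff`/`coxph` (Breslow ties; Wald
  CIs) for log-rank and Cox, `stats::fisher.test` for the exact r×c test
  (probability-ordering two-sided convention; margin-preserving Monte Carlo
  with add-one correction for large tables), and `wilcox.test` /
  `kruskal.test` / `p.adjust` for the rank statistics. Fully tied inputs
  return p = 1 with a warning rather than an error.
* **Drug response**: ridge regression of log IC50 on z-scored panel
  expression, computed in the dual so cost scales with the number of cell
  lines, with leave-one-out CV over a 13-point log-spaced λ grid
  (10⁻²–10⁴). Cohort expression is first rank-mapped onto the panel's
  per-gene empirical quantiles — the cross-platform homogenization step —
  then pushed through the linear model. Rank-mapping discards the cohort's
  absolute scale by design; with very small cohorts the empirical quantile
  transform is coarse.

# The synthetic cohort: what it emulates and what it does not

Every sample is a *composition* over `k_true` latent programs
(`k_true - 2` tumour programs plus one immune and one stromal program).
Immune and stromal fractions are set first — baseline fractions 0.10 and
0.12 multiplied by `immune_effect` (immune subtypes) and `stromal_effect`
(CAFs) — and the tumour programs absorb the remainder, so infiltration
dilutes tumour purity exactly as in bulk tumours. At the default effects
(5 and 4.5) the dominant compartment is the tumour program for inactivated
samples (purity ≈ 0.78), the immune program for activated samples
(immune fraction ≈ 0.5) and the stromal program for CAFs samples (stromal
fraction ≈ 0.54); at effect 1 all subtypes share one composition, giving a
clean null. A log-normal infiltration jitter (sd 0.12) gives the scores
realistic within-subtype spread.

The immune gene block is split into *effector* genes (pure immune program —
the IFN/cytolytic axis that separates activated from CAFs tumours) and
*interface* genes that cross-load 0.5× on the stromal program (chemokines
and antigen-presentation genes that stroma also expresses). In the CAFs
subtype the expanding stroma mildly crowds the immune fraction
(factor `1 − 0.085·(stromal_effect − 1)`). This is what lets the CAFs
subtype carry near-activated immune enrichment (as the biology demands)
while still having activated-specific markers for the classifier.

Gene-level structure (program membership, the effector/interface split,
per-gene FPKM-like magnitudes) is seeded by the cohort *dimensions* alone:
independently generated cohorts of the same shape share a "genome
annotation", which is what makes cross-cohort classifier projection
meaningful. Sample-level randomness follows the configured seed, and every
generator is bit-reproducible. Two effector genes are named GZMA and PRF1
so the cytolytic-activity score runs on synthetic data unmodified.

The other layers are generated conditionally on the planted subtype:
methylation β values with planted promoter-island hypermethylation
(tumour mean ≈ 0.62 vs normal ≈ 0.15) whose expression suppression decays
exponentially in β (so the anti-correlation survives the composition-driven
expression variance); Poisson mutation burdens with subtype-specific means
and signature mixtures; exponential survival times (baseline median 36
months, subtype hazard multipliers 1 / 2 / 1.4) under independent uniform
censoring; subtype-conditional clinical covariates; and broad arm-level
copy-number calls with lower alteration probability in immune subtypes.

**What passing tests do and do not show.** The synthetic transcriptome has
exactly `k_true` latent axes, so *every* gene set's ssGSEA score carries
weak composition signal — randomly relabelled gene sets collapse toward the
null rather than vanishing identically, and permutation nulls at small n
have heavier tails than on high-dimensional real data. Real cohorts add
platform effects, gene–gene correlation beyond the planted programs,
copy-number-driven expression, and labels that are not generated by the
model being fitted. Recovery results on the synthetic cohort therefore
validate the *mechanics* of the pipeline (identifiability under the stated
model, calibration of the statistics, determinism), not its field accuracy.

# Problem sizes and numerical choices

The recovery experiments run at the study scale the design calls for:
n = 300 samples × 2,000 genes for discovery and projection (10 seeds,
consensus over 8 restarts), with rank selection exercised on a
1,000-gene × 200-sample planted-rank cohort, the silencing analysis on
500 genes × 200 tumours + 20 normals, and the drug-response mechanism on
150-sample cohorts against 50-line panels — sizes chosen so the whole
recovery suite runs in minutes on one core while leaving each statistical
check comfortably powered. Calibration checks use 1,000 null simulations
(rank tests, log-rank), 200 replicates (Cox coverage) and 50 replicates
(Cox recovery at n = 400).

Numerical guards worth knowing about: multiplicative updates add
`.Machine$double.eps` to denominators; all-zero NMF input rows are an
error; an all-zero H column names the unassignable sample; β values within
±0.001 of [0, 1] are clamped and anything further out is rejected with the
probe and sample named; Fisher tables with all-zero rows/columns are
reduced before testing; and the exact Fisher path falls back with an
instructive error when enumeration is infeasible, pointing to the Monte
Carlo method.

# Known limitations

* The factor→class decision rule (rank test + median rule) is one of
  several defensible conventions; the per-factor report keeps the grouping
  auditable.
* Marker-mean cell-type scores are a coarse abundance proxy; they are not
  calibrated across populations.
* The mutated-gene screen has no background mutation model; it will flag
  frequently mutated long genes on real data.
* The MSI score is an expression-based proxy over a user-supplied gene
  set, not a sequence-derived MSI caller.
* pRRophetic-style IC50 imputation inherits the panel's biases; the
  quantile-mapping step assumes the cohort and panel measure comparable
  transcriptomes.
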