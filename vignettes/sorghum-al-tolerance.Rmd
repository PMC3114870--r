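---
title: "Aluminum tolerance and population structure in sorghum: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aluminum tolerance and population structure in sorghum: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorgal)
library(dplyr)
```

# Scope

`sorgal` implements, as one tested pipeline, the computational analyses used
to dissect aluminum (Al) tolerance across a cultivated-sorghum diversity
panel: hydroponic root-growth tolerance indices and their multivariate
summary, SSR diversity and kinship, Bayesian admixture clustering with
model-order diagnostics, gene-action and backcross linkage analysis at a
major tolerance locus, and a structured-association stage built on the Q+K
unified mixed model. Because panels of this kind are rarely deposited, the
package ships a synthetic-data generator that emulates the study design with
known ground truth, so every downstream stage is testable end to end.

# Tolerance indices

Al toxicity in acid (pH < 5) nutrient solution inhibits root elongation.
Tolerance is quantified from per-plant root lengths measured at the end of a
one-day acclimation (`ilc`), and after 1, 3 and 5 days under control or Al
treatment (`flc`, `flAl`):

* **RNRG** (relative net root growth, %): the ratio of mean net growth under
  Al to mean net growth in control, `100 * mean(flAl_d - ilc) /
  mean(flc_d - ilc)` at `d` = 3 or 5 days. The ratio is of treatment means,
  not a mean of per-plant ratios, because Al-treated and control plants are
  distinct individuals.
* **IRG** (induction of root growth): the day 3→5 growth rate divided by the
  day 1→3 rate, after averaging lengths over plants. Al tolerance in sorghum
  is inducible: tolerant genotypes speed up after two to three days of
  exposure, so IRG > 1 flags induction and IRG = 1 a constant rate.
* **RRG** (relative root growth, %): a per-plant index for segregating
  families, where a genetically identical control plant does not exist:
  growth during five days of Al exposure relative to the plant's own
  projected control growth, `100 * (flAl - flc) / ((flc - ilc) * 5)`: the
  numerator is the growth during the Al phase, the denominator the one-day
  control growth projected over the same five days. This reading is the
  package's documented convention.
* **VRD** (visual root damage): the mean of independent ordinal scores of
  root-apex damage, 1 (heavily damaged) to 5 (undamaged).

Accessions are classed **sensitive** (RNRG5d < 30%), **tolerant**
(RNRG5d > 80%) or **intermediate** otherwise. The defining inequalities are
strict on both sides, which leaves exact 30 and 80 unassigned; the package
deterministically classes boundary values intermediate.

Accession means are grouped with the **Scott–Knott** likelihood-ratio
procedure: sort the means, find the contiguous 2-partition maximising the
between-group sum of squares `B0`, and declare heterogeneity when
`lambda = pi/(2*(pi-2)) * B0 / sigma0^2` exceeds the chi-squared critical
value with `k/(pi-2)` degrees of freedom, where `sigma0^2` pools the spread
of the node's means with the ANOVA error variance `MSE/r` weighted by its
degrees of freedom. The recursion continues on both halves until no split is
significant, and letters are assigned in mean-sorted order. Ties in `B0` are
broken toward the leftmost split. Note a consequence of the statistic: as
`MSE → 0` every distinct pair of means eventually becomes significant, so
"obvious" two-cluster configurations are only recovered as exactly two
groups at realistic error variances; the test suite checks the procedure
against an exhaustive contiguous-partition oracle instead of fixed
partitions.

The three indices (RNRG3d, RNRG5d, IRG) are summarised by PCA on
standardized variables — an eigendecomposition of their 3×3 correlation
matrix. Signs are fixed deterministically (the largest-magnitude loading in
each component is made positive) — an arbitrary convention, but one
reproducibility requires. With all loadings positive, PC1 acts as a general
tolerance axis; PC2 contrasts the induction response with net growth.

# SSR diversity, PIC and kinship

Allele statistics are computed over observed allele copies only; loci with
every cell missing are excluded with a warning and no imputation is
performed anywhere. The diversity statistic reported as **PIC** is
`1 - sum(p_i^2)` — gene diversity computed from squared allele frequencies.
The Botstein correction term is deliberately not applied; the output labels
the formula used. Rare alleles are summarised with a strict < 0.10
minor-frequency threshold.

Kinship is the **proportion of shared alleles**: per pair of accessions, the
multiset intersection of the two diploid allele pairs, divided by 2 and
averaged over jointly non-missing loci. Multiset counting handles
homozygotes and heterozygotes uniformly (A/A vs A/B shares one copy of two).
A pair with no jointly genotyped locus raises an error rather than an
imputed value.

Because allele sizes for the same allele differ between laboratories,
`harmonize_allele_sizes()` estimates a per-marker integer offset as the
modal difference of both labs' calls on shared control lines, requires a
configurable modal consistency (default 0.8, failures flagged and left
unadjusted), and applies the offset to the full panel. The operation is
idempotent.

# Admixture model

`fit_admixture()` implements the Bayesian admixture model for multi-allelic
markers by Gibbs sampling: each accession has a membership vector `Q` over
`k` clusters (Dirichlet prior with fixed parameter `alpha`, default 1), each
cluster holds per-locus allele-frequency vectors `P` (Dirichlet prior
`lambda = 1`), and the latent cluster of origin `Z` of every allele copy is
sampled from the product of `Q` and `P` terms. One deliberate deviation from
the well-known STRUCTURE software: the **correlated allele frequencies**
prior is replaced by independent per-cluster Dirichlet priors. At the
differentiation levels this package targets (F of ~0.3) the independent
prior is adequate, and the model is labelled explicitly in every fit object.
`alpha` is fixed, not sampled, and configurable.

`Ln P(D)` is estimated as `mean(lnL) - var(lnL)/2` over post-burn-in sweeps
— the estimator documented for the original software. It sits below the
plug-in maximum log-likelihood by roughly the number of free parameters,
which the k = 1 closed-form test accounts for. Model order is examined with
the **Evanno** statistic: `delta_k` is the mean absolute second difference of
`Ln P(D)` across replicate runs divided by the standard deviation of
`Ln P(D)` at that k; endpoints carry no value and zero-sd cases surface as
warnings, never as silent drops. Cluster labels are aligned across runs by
greedy matching on membership-column correlation. The final choice of k is
deliberately not automated: `delta_k`, the assigned-membership fraction and
the interpretability of clusters are all reported.

Default MCMC settings are desk-scale (burn-in 2,000, 10,000 sweeps,
configurable): on a 254-accession, 38-locus panel a run takes tens of
seconds, and membership recovery on differentiated panels reaches mean
absolute error well under 0.1. The test suite and the acceptance script use
500/2,500 sweeps, which the recovery experiments show is already sufficient
at these problem sizes.

# Gene action and linkage

With `TT`, `tt` and `Tt` the RRG means of the tolerant parent, the common
sensitive recurrent parent and their F1, the dominance and additive effects
are `d = Tt - (TT + tt)/2` and `a = (TT - tt)/2`, and the degree of
dominance is `d/a`: −1 means the F1 equals the sensitive parent, 0 the
midparent, +1 the tolerant parent. Categories follow the published bins
exactly, including which boundaries are closed: recessive (`d/a <= -0.7`),
partially recessive (open interval), additive (`[-0.3, +0.3]` closed),
partially dominant (open), dominant (`d/a >= +0.7`). The ratio is reported
unclamped so over/under-dominance is visible.

Backcross linkage uses `LOD = (n/2) * log10(RSS0/RSS1)` with significance at
LOD ≥ 3. Interval mapping is **Haley–Knott regression**: at each grid
position, the probability that a progeny is heterozygous at the QTL given
its two flanking markers is computed with Haldane-converted distances (no
interference; Haldane is the assumption-free default where no map function
is prescribed), and RRG is regressed on that probability. For
backcross families at these effect sizes, Haley–Knott is equivalent to full
mixture-likelihood maximization — the test suite verifies the single-marker
LOD against a brute-force two-component normal likelihood oracle, and that
the interval-mapping LOD at a marker position equals the single-marker LOD
there. A zero-length interval reduces to the single-marker test by
construction.

# Structured association

The subpopulation comparisons use the Kruskal–Wallis test (unequal group
sizes and variances make ANOVA assumptions untenable) followed by a
Dunn-style non-parametric **lsd** on mean ranks,
`z_(1-alpha/2) * sqrt(N(N+1)/12 * (1/n_i + 1/n_j))`, at alpha = 0.05 with no
multiplicity adjustment. Letters are
assigned by insert-and-absorb, so non-transitive pairwise patterns are
encoded faithfully.

The core model is `y = Q nu + Z u + e` with `Var(u) = 2 K Vg` (K the
shared-allele kinship) and `Var(e) = R V_R`, `R = diag(1/n_obs)` since each
phenotype is a mean of `n_obs` plants. After simultaneous diagonalization,
the likelihood is profiled over the single ratio `Vg/V_R` on a log grid with
golden-section/parabolic refinement (relative tolerance 1e-8), components
constrained non-negative. Both ML and REML likelihoods are reported, but
**BIC uses the ML likelihood** (`-2 lnL + p log n`, `p` = fixed effects + 2):
the compared models differ in fixed effects, for which REML likelihoods are
not commensurable. This is a deliberate design choice of the package.

Sequential exclusion drops one membership column for the rows-sum-to-one
dependency (configurable; by default the column with the smallest
single-column OLS R² against the trait), fits the complete model and every
one-column-reduced model, and ranks BIC increases: the subpopulation whose
removal raises BIC most captures the largest share of the trait variation.
The variance explained by structure alone is reported as the OLS R² of the
trait on all included membership columns — a deterministic surrogate for
stepwise maximum-R² selection, labelled as such in output.

Reported p-values for contingency tests are only checkable when the degrees
of freedom travel with the statistic — mismatched chi²/p pairs are a common
literature defect — so the package always reports the df it used alongside
the statistic and the expected table.

# The synthetic generator

`simulate_study_panel()` encodes the study conditions: 254 fully homozygous
(inbred) accessions in six subpopulations of sizes 47, 58, 23, 43, 54 and
29; 38 multi-allelic SSR loci; Balding–Nichols differentiation with
`F = 0.3` (subpopulation frequencies drawn Dirichlet around an ancestral
vector with concentration `(1-F)/F`, giving across-subpopulation variance
`F p (1-p)`); membership rows drawn with concentration 0.05 plus a unit on
the home subpopulation, so most accessions are near-pure with occasional
admixture; and a rare biallelic major tolerance locus with tolerant-allele
frequencies (0.10, 0.04, 0.13, 0.02, 0.00, 0.17) — enriched in
subpopulations 1, 3 and 6, absent from 5, expected panel-wide tolerant
share ~6%. Locus alphabet sizes are drawn Poisson(17) truncated to [2, 29],
which yields ~12–13 *observed* alleles per locus in a panel of this size
with a large rare-allele fraction; the distinction matters because rare
alleles of large alphabets go unseen.

Root growth is piecewise linear in two day segments: control plants grow at
a per-plant rate (mean 1 cm/day, sd 0.15) from a ~3 cm acclimation length;
under Al the rate is multiplied by `m1` in days 0–3 and `m2` in days 3–5,
per tolerance genotype — `TT`: 0.75 then 1.00 (the induction dynamic,
IRG ≈ 1.33, RNRG5d ≈ 85%), `tt`: 0.30 then 0.20 (RNRG5d ≈ 26%, IRG ≈ 0.67).
This is the minimal dynamic that makes RNRG3d, RNRG5d and IRG all
informative. Gaussian measurement noise (sd 0.25 cm) is added to recorded
lengths only; pre-noise trajectories are monotone. Backcross families
segregate 1:1 at the locus with flanking markers derived through
independent Haldane recombination, and progeny RRG is the genotype mean
plus noise with the Tt mean at midparent + `(d/a)·a`.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: the tolerance locus is single and biallelic, so
the synthetic panel is essentially bimodal and the sizeable intermediate
class of real panels (minor loci, allelic series at the major locus) appears
only through noise; loci are unlinked apart from the explicit
flanking-marker geometry (no linkage disequilibrium, no coalescent
history); allele frequencies are independent across clusters (no shared
drift); and measurement error is homoscedastic Gaussian. Consequently the
synthetic sensitive fraction (~90%) corresponds to the real panel's
sensitive-plus-intermediate share rather than its sensitive share alone,
and induction (IRG > 1) concentrates almost entirely in the tolerant
genotype.

# Numerical choices and degenerate inputs

* All stochastic operations take an explicit seed and restore the caller's
  RNG state; pipeline runs with equal configurations are bit-identical.
* Degenerate denominators (zero control net growth, zero day-1→3 growth,
  `flc = ilc`) raise classed errors rather than returning infinities.
* Frequency vectors are validated to sum to 1 within 1e-9 (generator) or
  1e-6 (user input); Q-matrix rows read from CSV warn beyond 1e-3.
* The kinship eigendecomposition clamps eigenvalues at zero and rejects
  matrices negative beyond `1e-6` of the spectral radius; collinear fixed
  designs raise rank-deficiency errors instead of silently dropping terms.
* Scott–Knott ties in `B0` go to the leftmost split; chi-squared quantiles
  with fractional degrees of freedom come from `qchisq` directly.

# Problem sizes

The shipped defaults are chosen so the full synthetic pipeline (254
accessions, 38 loci, k = 6 clustering at 500/2,500 sweeps, three backcross
families, the association stage) completes in well under a minute on one
CPU, and the complete test suite — including a 150-accession membership
recovery run, 200 BIC signal simulations and a 2,000-replicate
Kruskal–Wallis calibration — in about a minute. The acceptance script runs
the same stages plus an Evanno scan in roughly two minutes.
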