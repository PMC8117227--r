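---
title: "Association mapping in structured breeding populations: models and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association mapping in structured breeding populations: models and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasim)
```

## The problem

Genome-wide association scans in livestock and aquaculture populations are
run on sets of close relatives: full-sib fish families, beef cattle lines
bred from a handful of selected sires, dairy bulls evaluated through their
daughters. Relatedness generates phenotypic covariance that a single-SNP
regression misattributes to whichever markers happen to differentiate
families, producing spurious associations. `gwasim` provides a controlled
environment to study this: a forward-in-time simulator that builds exactly
such structured populations with known causal loci, four association
methods that differ only in how they model relatedness, and an evaluation
layer that counts true and false discoveries against the simulated truth.

The four methods are:

* **SSA-NoCor** — ordinary least squares of the phenotype on each SNP
  dosage, $y = 1\mu + x_i g_i + e$, no relatedness correction. The baseline
  that the other methods improve on.
* **EMMAX** — per-SNP generalized least squares under
  $V = G\sigma^2_a + I\sigma^2_e$, where $G$ is the marker-sample-mean
  centered genomic relationship $G = \tfrac1k \sum_i (x_i - \bar
  x_i)(x_i-\bar x_i)'$ and the variance components are estimated once on
  the null model (no SNP) and reused for every SNP — the defining EMMAX
  approximation.
* **GBLUP-GWAS** — fit the animal model by Henderson's mixed-model
  equations with the blended VanRaden matrix
  $G = \lambda G_0 + \beta I$, $G_0 = MM'/(2\sum p_i(1-p_i))$
  ($\lambda = 0.95$, $\beta = 0.05$), then back-solve all SNP effects at
  once, $\hat g = \lambda \tfrac{1}{2\sum pq} M'G^{-1}\hat a$, with
  per-SNP variances
  $\mathrm{Var}(\hat g) = (\lambda\tfrac{1}{2\sum pq})^2\,
  M'G^{-1}(G\hat\sigma^2_a - C^{22})G^{-1}M$
  taken from the animal block $C^{22}$ of the MME inverse.
* **ssGWAS** — the same back-solving applied to a single-step model whose
  relationship matrix merges pedigree and genomic information,
  $H^{-1} = A^{-1} + \mathrm{scatter}(G^{-1} - A_{22}^{-1})$, so phenotypes
  of non-genotyped relatives contribute; the genetic-base scalar
  $\delta = 1 - \tfrac{0.5}{n^2}(\sum A_{22} - \sum G)$ enters the
  back-solving as $\hat g = \lambda\delta \tfrac{1}{2\sum pq}
  M'G^{-1}\hat a_{22}$.

All four report the same per-SNP record — effect, standard error, and the
two-sided normal-reference p-value $p_i = 2(1-\Phi(|\hat g_i /
sd(\hat g_i)|))$ — so that discovery counts are like-for-like. Using the
normal reference for the least-squares scan too is a deliberate
harmonization; at the sample sizes involved the difference from the t
reference is negligible.

## Conventions the formulas leave open

A handful of choices had to be fixed where the formulas above admit more
than one reading; they are collected here because they affect numerical
results.

* **$C^{22}$ scale.** The back-solved variance needs $G\hat\sigma^2_a -
  C^{22}$ to be positive semidefinite, which holds when $C^{22}$ is the
  prediction-error covariance of the animal solutions, i.e. the MME-inverse
  animal block multiplied by $\sigma^2_e$. `solve_mme()` returns it on that
  scale.
* **The marker matrix in the variance formula.** The per-SNP variance is a
  $k \times k$ object; the design matrix of the phenotype model cannot
  appear inside it. The centered marker matrix $M$ does: the implemented
  form is the standard prediction-error-variance back-transformation.
* **$\delta$ before tuning.** For single-step runs $G$ is additionally
  tuned so its mean diagonal and mean off-diagonal equal those of
  $A_{22}$ (solving the two-coefficient system $a + bG$). Because the tuned
  matrix matches $A_{22}$'s averages by construction, computing $\delta$
  *after* tuning would force $\delta = 1$ identically and make the
  adjustment vacuous; $\delta$ is therefore evaluated between $A_{22}$ and
  the blended-but-untuned $G$, the matrix that actually carries the base
  difference. Note that $\delta$ rescales the effect and its standard error
  identically, so p-values are invariant to this choice — only the
  reported effect scale depends on it.
* **Variance components.** The pipeline estimates $\sigma^2_a, \sigma^2_e$
  by exact REML on the analysis set's own kinship (below), or takes the
  simulation's generating values (`vc = "true"`). For single-step runs on
  populations whose genotyped animals carry no own records (dairy), the
  REML set is empty and the generating values are used.
* **Deregression.** Daughter equivalents use the ratio form
  $DE = rel/(1-rel)$; $DE_{prog} = rel_{EBV}/(1-rel_{EBV}) - DE_{PA}$, and
  $DRP = PA + (EBV - PA)(DE_{prog}+DE_{PA}+1)/DE_{prog}$. Animals with
  $DE_{prog} \le 0$ carry no progeny information beyond the parent average
  and are excluded. Parent-average reliability is the standard
  approximation $(rel_{sire}+rel_{dam})/4$. Deregressed proofs enter the
  downstream scans unweighted, matching the unweighted phenotype models
  above. A note on validation: the daughter mean regresses on the
  *transmitted half* of the sire's breeding value, so the expected slope
  of daughter means on sire DRP is 1/2 (attenuated further by DRP noise),
  and that is what the test suite checks.

## REML

`reml_estimate()` maximizes the exact restricted likelihood through the
spectral decomposition of the kinship among recorded animals: with
$K = UDU'$ the likelihood profiles down to a one-dimensional function of
$h^2$, maximized by Brent search on $(0,1)$. This is preferred over EM
iteration because it is exact, deterministic, fast at the sample sizes
used ($n \le$ a few thousand), and structurally incapable of negative
estimates — boundary cases (pure noise, or no residual variance) land on
the interval ends rather than diverging.

## The simulator

The generator mirrors a two-phase design used widely in livestock
simulation studies.

**Historical phase.** Every locus starts at allele frequency 0.5 (placed
exactly: each locus receives `round(2N * 0.5)` copies at random
haplotypes), and the population follows a size trajectory under random
union of gametes with recurrent mutation (allele flips at $2.5\times
10^{-5}$ per locus per haplotype per generation, applied to SNPs and QTN
alike). Recombination is Poisson with no interference: crossover counts
per chromosome are Poisson(length/100), positions uniform. This phase
generates the baseline linkage disequilibrium and drifts frequencies away
from 0.5. Presets: fish 5,000 declining linearly to 3,100 over 200
generations (the trajectory shape is not specified by the design the
presets emulate; linear decline is assumed); cattle 1,000 growing to
50,000 over 1,000 generations then contracting to 23,000 over another
1,000. The proportion of males is 32% (fish) and 3,000/23,000 (cattle)
in every historical generation.

**Recent designs.** Three species presets create the population structure
of interest:

* *Fish*: 20 sires and 20 dams drawn from the historical pool, five
  generations of random selection, culling and mating, then one large line
  of 20 full-sib families (litter 100). The random-mating generations use
  random union of gametes — both parents drawn independently per offspring
  — which is the mechanism whose effective population size equals the
  design's nominal $N_e = 4N_mN_f/(N_m+N_f) = 40$; the final line keeps
  one-sire-per-dam litters because the resulting full-sib blocks are the
  population structure this preset exists to create. Both sexes are
  phenotyped; the 40 parents plus a random half of the offspring are
  genotyped (2,040 records, 1,040 genotyped at full size).
* *Beef*: random mating at scale (200 sires x 10,000 dams), then five
  lines of 10 sires + 500 dams selected on EBV in ranked blocks so the
  lines differ genetically, two generations of within-line truncation
  selection (the design this emulates states the goal — maximally
  different lines — but not the generation count), then the lines pooled
  into one randomly mated line for five generations. The last generation
  and its parents are genotyped; females of the last two pooled
  generations carry records. The trait is sex-limited.
* *Dairy*: 10 generations of EBV selection (pedigree BLUP on all female
  records, true variance ratio) with greedy inbreeding-minimizing mate
  allocation: dams in random order are assigned to the least-related sire
  with remaining capacity, relatedness tracked by a generation-recursive
  coancestry matrix. Only the sires of the seventh generation are
  genotyped; all females carry records, giving each genotyped sire about
  ten phenotyped daughters.

**Trait.** One QTN per chromosome at the midpoint (kept out of the SNP
panel and out of the association input). Absolute effects are
gamma(shape 0.40) draws with random sign — the gamma is positive-only, so
a random sign per QTN is the natural completion — rescaled so the variance
of the total QTN contribution among the recent population's founders
equals $h^2/(1-h^2)$ times the residual variance (fixed at 1). Phenotypes
are mean (1.0) + TBV + standard normal residual; heritabilities 0.25
(fish), 0.30 (beef), 0.35 (dairy); cattle traits are sex-limited.

**Seeds.** One scenario seed expands into independent sub-stream seeds for
the historical and recent stages, so each stage is separately
reproducible; identical seeds give byte-identical output.

## Scale

The full-size beef and dairy scenarios (historical populations to 50,000
individuals, 65,000 loci, 2,000 generations) are deliberately out of desk
range. The desk-scale presets (`scaled_down = TRUE`, the default) divide
population sizes and the SNP panel by 10 and historical generations by 4.
Three exceptions are intentional. The fish nuclei stay intact — 20 x 20
in the small series, 200 x 200 in the large — because the nucleus defines
each design's effective population size and family structure; the litter
is divided instead (an early draft collapsed the large nucleus to 20 x 20,
which turns the "large" analogue into a literal copy of the small
population and reproduces the small population's false-positive behavior
rather than the large one's). The large-series fish historical sizes are
divided by 4 rather than 10 so the terminal generation can still seed 200
sires and 200 dams. And the scaled dairy preset uses 200 sires (not 100)
so that each genotyped sire keeps roughly ten phenotyped daughters, the
condition that defines the deregression setting. The small fish preset is desk-scale even at full
size (about two minutes), and the package's reproduction script runs it
unscaled. Replicated studies in the tests and the acceptance script use
five replicates per scenario, matching the study design the presets
emulate.

## The evaluation layer

Significance uses 0.05 with Bonferroni correction over the retained SNPs.
A significant SNP within 2 cM (inclusive) of a same-chromosome QTN is a
true positive, otherwise a false positive; counting is per significant
SNP, not per QTN window — the only reading consistent with counts that
exceed the number of QTN. ROC curves sweep the threshold over the sorted
p-values with the same window defining positives; the trapezoidal area
equals the Mann-Whitney statistic, an identity the tests assert. LD decay
is the squared genotypic correlation of dosage pairs binned by map
distance; PCA of $G$ is its eigendecomposition with scores scaled by
square-root eigenvalues. Method comparisons across replicates use paired
t-tests at 0.05.

**Effective population size.** $\Delta F = (F_n - F_{n-1})/(1-F_{n-1})$
from the pedigree-based inbreeding means per generation, and
$N_e = 1/(2\overline{\Delta F})$. Two estimator details matter in small
populations. First, the founder-to-first span is excluded: pedigree
founders are assumed unrelated, so its $\Delta F$ is structurally zero — a
truncation artifact, not a property of the design. Second, the remaining
spans are averaged arithmetically *including* any non-positive ones:
truncating them would condition on upward noise and bias $N_e$ downward
(by roughly 10% at nucleus sizes). With both choices, pedigree-only Monte
Carlo of the fish nucleus centers the estimator on the analytic 40 — the
test suite replays this check over 40 pedigree replicas.

## Quality control

Three rules, in order: remove monomorphic SNPs; remove SNPs with minor
allele frequency strictly below 0.05; remove SNPs whose observed
heterozygote frequency deviates from the Hardy-Weinberg expectation $2pq$
by more than 0.15. The deviation rule is the heterozygosity-vs-$2pq$
reading of "deviation between observed and expected frequencies", the
convention of the software family this emulates; both thresholds are
strict inequalities, so values exactly at a threshold are kept. QC uses
genotyped animals only. On the scaled beef panel this retains about 89% of
SNPs, in line with the 58,000/65,000 retention the full-size cattle
panels show.

## What the generator does and does not emulate

The simulator reproduces the *stated parameters* of the study designs —
trajectories, nucleus sizes, selection and mating rules, genome layout,
mutation, heritabilities — not the internal algorithms of any particular
simulation package. Consequences worth knowing:

* Replicates here are fully independent: each draws its own historical
  population and its own QTN effects. Discovery *counts* therefore vary
  substantially across replicates (the top QTN's variance share under
  gamma(0.40) ranges from ~0.2 to ~0.8), and their 5-replicate means are
  reproducible only as distributions, not as point values. (Simulation
  reports in which between-replicate SDs are a small fraction of the
  counts are typically sharing one historical/effect draw across
  replicates.) The robust signatures —
  near-zero false positives for the kinship-corrected methods, an excess
  of false over true positives for the uncorrected scan, rank agreement
  between EMMAX and GBLUP-GWAS, and the equivalence of the deregressed
  and single-step paths — reproduce here, while absolute true-positive
  counts sit below a well-tagged single-draw optimum.
* Generations are strictly non-overlapping; dam culling across
  generations is not modelled (dams are replaced from female offspring
  each generation).
* No genotyping errors, missingness, or call-rate structure: QC's
  missingness rules are out of scope, and the deviation rule does most of
  its work only in strongly drifted or family-structured panels.
* Sex is assigned in balanced halves (per line, where lines must supply
  fixed quotas of parents), not as independent Bernoulli draws.

## Degenerate inputs and numerical choices

Monomorphic SNPs inside an analysis set are flagged and assigned p = 1
rather than dropped, so output rows stay aligned with the panel.
Back-solved variances that lose positivity to floating-point cancellation
are clamped to a tiny positive value and flagged (`var_clamped`), letting
full-panel scans complete; a zero standard error passed directly to the
p-value transform is an error instead. Dense symmetric solves go through
Cholesky factorization; the single-step system is assembled sparse
(pedigree A-inverse by Henderson's rules with Meuwissen-Luo inbreeding)
with the genomic correction in the genotyped block, and $C^{22}$ is
extracted by multi-right-hand-side solves on the genotyped columns.
$A_{22}$ for large pedigrees is obtained by sparse solves of the A-inverse
rather than a dense tabular pass. The tuning system $a + bG$ aborts when
$G$'s mean diagonal equals its mean off-diagonal (no information to
separate the coefficients); blending should precede inversion, and the
error message says so.

## Limitations

Single-trait, additive-only genetics; no dominance, epistasis, or
genotype-by-environment terms. The EMMAX implementation is the
fixed-variance-components approximation, not per-SNP exact REML. PEV-based
reliabilities use the full MME inverse and are not approximated, which
caps practical pedigree sizes at a few tens of thousands of animals —
appropriate for the desk-scale presets, not for national evaluations.
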