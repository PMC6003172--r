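---
title: "Single-step genomic evaluation with a major gene: models, weights and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation with a major gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette describes the models implemented in **singlestep**, the
numerical choices behind them, and what the bundled population simulator
does and does not emulate. The running context is a dairy-goat-style
evaluation of milk protein content, a highly heritable trait
(h&sup2; &asymp; 0.5) that is partly controlled by a single multi-allelic
casein locus explaining roughly 40% of the additive genetic variance, with
repeated lactation records on females and genotypes concentrated on males.

## The repeated-records animal model

All single-trait evaluations solve the same mixed model

$$\mathbf{y} = \mathbf{X\beta} + \mathbf{Zu} + \mathbf{Wp} + \mathbf{e},$$

where $\mathbf{y}$ holds one row per lactation, $\mathbf{\beta}$ the fixed
environmental effects (herd-year, parity, and any further factor columns
the caller names), $\mathbf{u} \sim N(0, \mathbf{K}\sigma^2_u)$ the
additive genetic effects of *all* pedigree animals,
$\mathbf{p} \sim N(0, \mathbf{I}\sigma^2_p)$ permanent-environment effects
of the phenotyped females, and
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$. The relationship matrix
$\mathbf{K}$ is $\mathbf{A}$ (pedigree BLUP) or $\mathbf{H}$ (single-step
methods). Variance components are *inputs*
(`variance_components()`), parameterised by heritability (default 0.5) and
repeatability (default 0.6) on a phenotypic variance in squared trait
units; REML estimation is deliberately out of scope.

Identifiability of the fixed part uses an explicit intercept plus a
set-to-zero (drop-first) constraint on every factor, so solutions are
reproducible and constrained levels are reported with estimate exactly 0.
Henderson's equations are assembled sparsely (`Matrix`); systems up to
20,000 equations are solved by sparse Cholesky factorisation, larger ones
by Jacobi-preconditioned conjugate gradients with relative-residual
tolerance $10^{-10}$. The direct and iterative paths agree to $10^{-8}$ on
shared fixtures, and every fit records its final normal-equation residual.

## Pedigree algebra

`a_inverse()` builds $\mathbf{A}^{-1}$ directly by Henderson's rules with
the exact inbreeding correction: animal $i$ contributes $1/d_i$ on its
diagonal with $d_i = 0.5 - 0.25(F_s + F_d)$ the Mendelian sampling
variance (an unknown parent behaves as $F = -1$). Inbreeding coefficients
come from the Meuwissen-Luo L-vector recursion, so
$\mathrm{diag}(\mathbf{A}) = 1 + F$ holds exactly rather than assuming
$F = 0$. Unknown parents are founders of a single base population:
unknown-parent groups change the $\mathbf{H}^{-1}$ algebra and are
orthogonal to the methods compared here, so they are not implemented.
Dense relationship blocks among chosen animals ($\mathbf{A}_{22}$) use the
tabular method restricted to the animals' ancestors.

## Genotypes, QC and the genomic relationship matrix

Dosage matrices (0/1/2, missing allowed) are read from a PLINK
`.raw`-style table or an additive-dosage CSV, with a `.map` or CSV map;
VCF input is optional. QC applies the standard chip filters in a fixed
order — SNP call rate &ge; 0.95, MAF &ge; 0.01, Hardy-Weinberg
goodness-of-fit $\chi^2 \le 24$, animal call rate &ge; 0.99 — because the
order changes the survivor set; the `QcReport` records thresholds, per-filter
removals and identities so the order is auditable. With a breed grouping,
SNP filters run independently per breed and a SNP must pass in every
breed. Remaining missing dosages are imputed to $2p$ (zero after
centering).

The genomic matrix is

$$\mathbf{G} = 0.95\,\frac{\mathbf{MDM}'}{2\sum_i p_i(1-p_i)} + 0.05\,\mathbf{A}_{22},$$

with $\mathbf{M}$ the column-centered dosage matrix (animals by SNPs),
$\mathbf{D}$ a diagonal weight matrix (identity for ssGBLUP) and $p_i$
allele frequencies of the current genotyped set. Blending guarantees
$\lambda_{\min}(\mathbf{G}) \ge 0.05\,\lambda_{\min}(\mathbf{A}_{22}) > 0$;
the raw cross-product is always singular when frequencies are estimated
from the data (the ones vector is in its null space). $\mathbf{H}$ itself
is never formed; the evaluations use the standard identity

$$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
  \begin{pmatrix} 0 & 0 \\ 0 & \mathbf{G}^{-1} - \mathbf{A}_{22}^{-1} \end{pmatrix},$$

with dense work confined to the genotyped block. Tests verify the dense
inverse of this $\mathbf{H}^{-1}$ against the explicit four-block
$\mathbf{H}$ formula.

## SNP variance weighting (WssGBLUP)

GEBV of the genotyped animals are decomposed into SNP effects

$$\hat{\mathbf{a}} = \frac{1}{k}\,\mathbf{D}\mathbf{M}'\,\mathbf{G}^{*-1}\hat{\mathbf{u}}_g,
\qquad k = 2\sum_i p_i(1-p_i),$$

where $\mathbf{G}^{*}$ is the blended weighted matrix actually used in the
evaluation — not a pseudo-inverse of the raw $\mathbf{MDM}'$, which is
singular whenever SNPs outnumber genotyped animals. With no blending and
full row rank this reduces to the classical
$\mathbf{DM}'[\mathbf{MDM}']^{-1}\hat{\mathbf{u}}_g$ and
$\mathbf{M}\hat{\mathbf{a}}$ reproduces $\hat{\mathbf{u}}_g$ exactly. The
variance weight of SNP $i$ is $2\hat{a}_i^2 p_i(1-p_i)$, and the weight
vector is rescaled after every transformation so its sum equals the SNP
count (the total marker variance is conserved across iterations).

Iteration 0 is the unweighted evaluation ($\mathbf{D} = \mathbf{I}$); each
subsequent iteration back-solves, reweights, rebuilds $\mathbf{G}^{*}$ and
re-solves, and every iteration's solutions and weights are kept so the
accuracy-vs-iteration curve can be drawn. The *reported* iteration
defaults to one reweighting — ssGBLUP run twice, once to derive the
weights and once with them. At the simulation scale used here (about 500
genotyped animals and 2000 SNPs) validation accuracy peaks at that first
reweighting and declines with further iterations, because the squared-effect
weights amplify estimation noise faster than signal once the locus is
captured.

Two windowed variants smooth the weights over non-overlapping runs of
consecutive SNPs in map order: every SNP in a window receives the window's
maximum (Max) or sum (Sum) of weights, followed by re-normalisation.
Windows restart at chromosome boundaries — letting a window straddle
chromosomes would tie weights of unlinked SNPs — and the last window on a
chromosome may be shorter. Smoothing is applied at every iteration (a
single application can be had by running one iteration). No cap is placed
on individual weights.

## TABLUP: evaluation on a SNP subset

`select_snps()` ranks SNPs by a weight vector (ties broken by map order)
and keeps the top- or bottom-$k$; `exclude_chromosome()` drops a whole
chromosome. `tablup()` rebuilds $\mathbf{G}$ from the subset with equal
weights, recomputing allele frequencies and the scaling constant $k$ on
the subset so the matrix stays on the relationship scale for any subset
size, and then runs the ordinary single-step evaluation. Selecting the
full map reproduces ssGBLUP exactly, which is tested.

## The gene-content multi-trait model

To use major-locus genotypes directly, the protein trait is evaluated
jointly with six gene-content traits, one per casein allele
($A, B, C, E, F, O$): the content $y_a \in \{0, 1, 2\}$ is the number of
copies of allele $a$, observed for genotyped animals and missing (handled
by equation deletion, not imputation) for the rest. Each content trait has
a mean-only fixed part. The 7-trait genetic covariance is
$\mathbf{K} \otimes \mathbf{H}$; the default constructor derives
$\mathbf{K}$ from a single-locus model with allele frequencies $p_a$ and
substitution effects $\alpha_a$:

$$\mathrm{Var}(u_a) = 2p_a(1-p_a), \quad
  \mathrm{Cov}(u_a, u_b) = -2p_ap_b, \quad
  \mathrm{Cov}(u, u_a) = 2p_a(\alpha_a - \bar\alpha),$$

with $\bar\alpha = \sum_b p_b\alpha_b$ and
$\mathrm{Var}(u) = \sigma^2_{\mathrm{poly}} + \sum_a \alpha_a\,2p_a(\alpha_a-\bar\alpha)$.
Because contents sum to 2, the gene block is singular (the ones vector has
eigenvalue 0); a small ridge (default $10^{-6}$) on its diagonal makes the
system factorisable without materially changing the solutions. Gene
content is noise-free in principle, so its residual variance is a small
positive fraction (default $10^{-3}$) of the genetic variance, purely for
numerical identifiability; as it shrinks, fitted contents converge to the
observations. A user-estimated $\mathbf{K}$ can be supplied instead of the
constructor. With all cross-covariances zero the protein equations
decouple and the model reproduces ssGBLUP exactly — the key internal
consistency check. Predicted contents $\hat\mu_a + \hat u_{a,i}$ are
returned for every animal, giving locus information for the ungenotyped.

## Validation: DYD, accuracy, and comparing correlations

`split_validation()` reproduces the sire-validation design: genotyped
males born in the validation year range are candidates, and *all* records
of their daughters are removed from the training data. For each daughter,
the yield deviation is her record-mean of
$y - \mathbf{x}'\hat\beta - \hat p$; her sire's daughter yield deviation is
the EDC-weighted mean of $2\,\mathrm{YD}_d - \hat u_{\mathrm{dam}(d)}$.
Two simplifications are deliberate: EDC is the daughter's record count
(the reliability-based formula would need a full reliability machinery; a
user-supplied EDC column is accepted), and the correction terms come from
the full-data *pedigree* BLUP run, matching the convention that DYD derive
from the official, pedigree-based evaluation. Accuracy is the Pearson
correlation of GEBV with DYD over the validation sires. Accuracies of two
methods on the same sires are compared with Williams' t,

$$t = (r_{12}-r_{13})\sqrt{\frac{(n-1)(1+r_{23})}
 {2|R|\,\tfrac{n-1}{n-3} + \bar r^2 (1-r_{23})^3}}, \qquad df = n-3,$$

with $|R|$ the determinant of the 3x3 correlation matrix. Its null
rejection rate is verified by simulation to sit near the nominal 5%.
`compare_scenarios()` stars differences at the 5, 3 and 1 percent
thresholds.

## The population simulator

`sim_population()` generates the structure the estimators assume, so the
whole pipeline is testable without proprietary data:

* **Pedigree** — two breeds, a founder year, then overlapping generations:
  each year a few young sires (at most 3 years old, mirroring progeny
  testing) and a larger set of dams are sampled per breed and mated at
  random; offspring are female with probability 0.7. Defaults give about
  1,400 animals with roughly 500 SNP-genotyped (all males plus 10% of
  females) and 800 casein-genotyped.
* **Genomes** — founder haplotypes come from a first-order copying chain
  (allele at a marker copies the previous marker with probability 0.95,
  otherwise drawn at the marker's frequency), the simplest mechanism with
  tunable LD decay; a coalescent simulator would add realism the methods
  do not consume. Meiosis uses Poisson crossovers (Haldane) on a 1-Morgan
  chromosome. The major locus sits at its map position and travels on the
  same gametes, so family LD is automatic.
* **The casein locus** — founder haplotypes are ordered by a
  geometrically-weighted score of the 25 nearest flanking SNPs (decay
  0.75, nearest SNP heaviest) and the six alleles fill contiguous blocks
  of that order matching breed-specific frequencies (allele $A$
  predominant in one breed; $A$, $E$, $F$ frequent in the other). This
  makes the flanking region strongly associated with the locus, the
  architecture that SNP-weighting methods exploit. The two genotypes never
  observed in the real population ($FO$, $OO$) are excluded: offending
  founder draws are redrawn and an offending transmission switches the
  gamete's locus allele to the parent's other haplotype.
* **Phenotypes** — true breeding values are a polygenic part (i.i.d.
  normal effects on a random 10% of SNPs) plus the locus value
  $\sum_a \alpha_a y_a$. The locus effects are rescaled so the locus
  explains exactly the target fraction (default 0.40) of the realized
  additive variance — solving a quadratic that accounts for the
  polygene-locus covariance induced by shared haplotypes — and the total
  is scaled to $h^2 \sigma_P^2$. Each female gets 1-3 lactations,
  $y = \mu_b + \mathrm{herd\,year} + \mathrm{parity} + u + p + e$, with
  herd-year effects at 0.35 of the phenotypic SD. Per-breed means are set
  to $\sigma_y / \mathrm{CV}_b$ (targets 0.11 and 0.09) so both breeds hit
  their coefficient of variation with common variance components.

The simulator does **not** model selection (mating is random given the age
windows), genotyping error, chip ascertainment (causal SNPs are on the
chip), imputation scenarios, or unknown-parent-group structure. Passing
tests therefore demonstrate internal consistency of the estimators under
the stated architecture, not performance on a national dataset.

## Problem sizes and what the replicated study shows

The test suite runs the comparative study at desk scale: 20 independent
populations of ~1,400 pedigree animals, ~500 genotyped, 2,000 SNPs on 5
chromosomes, training on sires born in years 0-5 and validating ~40
genotyped sires born in years 6-10 through their daughters' DYD. At this
scale the qualitative results are stable and fast to reproduce: genomic
information adds roughly 10 accuracy points over pedigree BLUP, removing
the causal chromosome from $\mathbf{G}$ costs about 5 points, and the
locus-flanking SNPs carry several times the average variance weight.

Two effects the full-scale study reports are *at the resolution limit*
here, and honesty about that matters: the mean advantage of WssGBLUP over
ssGBLUP is a fraction of an accuracy point (within replicate noise), and
the top-50 weighted SNPs concentrate on the causal chromosome at about
half the top-50 rather than a clear majority. Both sharpen with more
genotyped animals; with ~500 the back-solved squared effects are noisy
enough that polygenic and null SNPs compete with the locus's tag SNPs.

## Known limitations

* Variance components are inputs; no REML.
* EDC is a record count, not a reliability-based contribution.
* The default gene-content covariance is a single-locus construction; a
  covariance estimated from data can and should be supplied when
  available.
* The solver targets desk-to-moderate scale (sparse Cholesky below 20,000
  equations, PCG above); a national evaluation would need out-of-core
  iteration on data.
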