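---
title: "Single-step genomic evaluation with SNP and haplotype relationship matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation with SNP and haplotype relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ssgblup)
```

This vignette documents the statistical models, algorithms, and numerical
choices in `ssgblup`. Chunks are shown but not evaluated; the README contains
a fully executed worked example, and `scripts/acceptance.R` reproduces every
numerical claim the package makes.

## 1. Animal models

All analyses assume known variance components (supplied via `var_comp()` or
the built-in trait table `trait_vc()`) and fit one overall mean plus optional
user-supplied fixed effects; phenotypes are expected to be pre-corrected for
contemporary groups (section 4). Three model classes are available through
`ssgblup(..., model = )`:

**Additive** (e.g. yearling fibre diameter):

$$y = X\beta + Z u + e, \qquad u \sim N(0, K\sigma^2_u),\ e \sim N(0, I\sigma^2_e)$$

**Repeatability** (number of lambs born, repeated parities): adds a permanent
environmental effect per animal with records,

$$y = X\beta + Z u + W p + e, \qquad p \sim N(0, I\sigma^2_{pe}).$$

**Maternal** (body weights): adds a maternal genetic effect $m$ on the dam and
a maternal permanent environment $q$,

$$y = X\beta + Z u + Z_2 m + Z_2 q + e, \qquad
m \sim N(0, A\sigma^2_m),\ q \sim N(0, I\sigma^2_q),$$

with the direct–maternal genetic covariance fixed at zero, and records of
animals with unknown dams dropped (the maternal incidence cannot be formed
for them). The maternal additive effect always uses the pedigree matrix
$A$, even in genomic runs: maternal effects are expressed through dams, which
are mostly non-genotyped, so a genomic maternal structure is not identifiable
from the data this package targets.

$K$ is $A$ (pedigree BLUP) or $H$ (single-step); the mixed-model equations
only ever require $K^{-1}$, which stays sparse in both cases.

## 2. Relationship matrices

`build_nrm()` implements the tabular method; `inbreeding()` uses the
Meuwissen–Luo algorithm ($O(n \cdot \text{depth})$, no dense matrix);
`nrm_inverse()` uses Henderson's rules *with* inbreeding, i.e. Mendelian
sampling variance $d_i = 0.5 - 0.25(f_s + f_d)$ (0.75 or 1 with one/both
parents unknown). Unknown parents are unrelated, non-inbred base animals; no
genetic groups are fitted.

`vanraden_g()` builds $G = \tilde M \tilde M' / (2\sum_j p_j(1-p_j))$ where
$\tilde M$ centres dosages by $2p_j$ (allele frequencies computed from the
genotyped set itself) and missing dosages are set to the centred mean (zero).
`blend_g()` returns $G_w = \alpha G + (1-\alpha) A_{22}$; blending guarantees
invertibility and controls how much weight the marker information gets.

`h_inverse()` assembles the single-step inverse in two sparse parts:

$$H^{-1} = A^{-1} +
\begin{bmatrix} 0 & 0 \\ 0 & \tau (\alpha G + (1-\alpha)A_{22})^{-1} - \omega A_{22}^{-1} \end{bmatrix}$$

with defaults $\tau = \omega = 1$. At $\alpha = 0$ the correction block is
skipped entirely and single-step collapses exactly to pedigree BLUP — this
identity is verified to $10^{-6}$ on 2,000-animal populations for all three
model classes in the test suite. The genotyped-block pieces ($A_{22}$ and its
inverse) come from `extract_a22()`, which prunes the pedigree to ancestors of
the genotyped set before inverting. Correctness of the whole construction is
checked against a dense conditional-multivariate-normal $H$ oracle and, for
$A$ itself, against Monte-Carlo gene dropping.

## 3. Haplotype blocks and pseudo-SNPs

`ld_r2()` computes $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$ from *phased
haplotype* frequencies with pairwise deletion of missing phase — not from the
genotype correlation, which conflates linkage and Hardy–Weinberg departure.

`build_haploblocks()` uses a deterministic greedy contiguous clustering per
chromosome: seed at the leftmost unassigned adjacent pair with
$r^2 \ge$ threshold, extend rightwards while the candidate's *mean* $r^2$
with current block members stays at or above the threshold and the block is
within `window_markers`; blocks have at least two markers; everything else is
a non-clustered SNP (NCSNP). This replaces interval-search block finders with
something reproducible and order-independent; raising the threshold can never
increase the clustered-marker count (a property test).

`pseudo_snp_encode()` turns each block into one column per distinct haplotype
allele, coded 0/1/2 copies, ordered by descending allele frequency; within a
block each fully phased individual's row sums to exactly 2 (two chromosomes),
and missing phase propagates to NA. `pseudo_snp_qc()` applies MAF/call/HWE
filters to pseudo-SNP columns while passing NCSNP columns through; the merged
matrix feeds `vanraden_g()` unchanged, so "HAP-BLUP" differs from "H-BLUP"
only in the dosage matrix behind $G$.

## 4. Phenotype preparation

The pipeline order is fixed: `preadjust()` (fixed-effect pre-adjustment,
either user-supplied coefficients or internal least squares) → ±3 SD
`phenotype_qc()` → `make_contemporary_groups()` (flock × year × season × sex ×
management × age windows: 70-day bins, 35-day for post-weaning weight,
anchored at the earliest birth date in each flock-year-season cell) →
small/invariant-group filters → `correct_for_cg()` (subtract group means, add
back the grand mean). Birth weight ignores the record date for age binning;
number of lambs born keeps parity as a repeated-record index.

## 5. Mixed-model equations and accuracy

`ssgblup()` assembles Henderson's MME with `Matrix` sparse classes and solves
by sparse Cholesky (default). Prediction error variances are obtained by
solving for selected columns of the inverse coefficient matrix only — the
full inverse is never formed — giving theoretical accuracies
$\sqrt{1 - \mathrm{PEV}_i /((1+f_i)\sigma^2_u)}$ (`theoretical_accuracy()`,
clamped at the ceiling, with a `squared` option). A matrix-free
preconditioned-conjugate-gradient solver (`method = "pcg"`, Jacobi
preconditioner, `hinv_matvec()` for the $H^{-1}$ product) handles systems too
large to factor, but then PEV are unavailable by construction. Solutions from
the two solvers agree to $10^{-5}$ in the tests, and the direct solver agrees
with a dense GLS oracle to $10^{-6}$.

## 6. Forward validation (LR method)

`split_whole_partial()` builds the whole/partial data pair: partial data drop
records made after the cutoff date, all records of focal animals, and records
of their progeny. Focal animals are genotyped, born after the cutoff, and
linked to the whole data through own or progeny phenotypes. `lr_statistics()`
then computes, over focal animals,

* accuracy: $\mathrm{cov}(\hat u_w, \hat u_p) / ((1-\bar F)\sigma^2_u)$
  (optionally its square root),
* bias: $\overline{\hat u_p} - \overline{\hat u_w}$,
* dispersion: $\mathrm{cov}(\hat u_w,\hat u_p)/\mathrm{var}(\hat u_p) - 1$
  (0 means no inflation).

These satisfy exact identities used as tests: identical predictions give zero
bias and dispersion, doubling the partial predictions gives dispersion −0.5,
and all statistics are shift-equivariant. `connectedness_ved()` supplies a
variance-of-estimated-differences diagnostic for whether focal cohorts are
comparable. `scenario_grid()` + `run_evaluation()` sweep the 13-scenario
design (A-BLUP; H-BLUP at α ∈ {0.95, 0.50}; HAP-BLUP at five LD thresholds ×
two α) across traits.

## 7. The simulator and its realism

`simulate_population()` gene-drops a closed population: discrete generations,
balanced sexes, random mating; markers on a Morgan map with Haldane (Poisson)
recombination; founder haplotypes drawn in linkage equilibrium at uniform
frequencies; a marker-disjoint QTL set whose effects are rescaled so the
founder-generation additive variance equals $\sigma^2_u$ exactly; phenotypes
with contemporary-group structure, known injected fixed effects, and
model-appropriate extras (repeated parities, maternal effects).

Two realism limits matter and are deliberate:

* **LD is drift-only.** With linkage-equilibrium founders, adjacent-marker
  $r^2$ after 6–8 generations is small unless the effective size is small and
  the map short. Populations simulated with many founders and ~0.3 M
  chromosomes form essentially no haploblocks at $r^2 \ge 0.15$; configurations
  like 60 founders × 0.05 M chromosomes form blocks at 0.15 and rarely at
  0.35. Tests of blocking behaviour therefore use planted-LD fixtures with
  known $r^2$, and simulated-population block tests use LD-rich
  configurations. Real populations with ancestral LD sustain much higher
  thresholds; the algorithm itself is threshold-agnostic.
* **No selection.** Matings are random, so LR bias should be centred on zero
  — which is what the acceptance script verifies over 20 replicates (with
  moderate population sizes, about 800 animals and 200 genotyped per
  replicate, chosen by this package purely for runtime). Under selection,
  single-step results depend on model completeness in ways the simulator does
  not reproduce.

## 8. Limitations

* Variance components are inputs, never estimated (no REML).
* Phasing is assumed done upstream; unphased data support QC, $G$, and
  SNP-based single-step, but not haplotype blocking.
* Single trait at a time; no direct–maternal covariance; no genetic groups;
  no weighted (marker-variance) single-step.
* The exact Hardy–Weinberg test enumerates heterozygote counts and is meant
  for marker QC, not for very large allele counts per locus.
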