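---
title: "Dissecting genome-methylome interactions in nuclear pedigrees with pedmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting genome-methylome interactions in nuclear pedigrees with pedmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedmeth)
```

## The problem

Genetic polymorphisms shape DNA methylation in two mechanistically distinct
ways: a SNP inside a CG dinucleotide removes the methyltransferase substrate
on one allele outright, while a regulatory SNP nearby shifts — or
destabilizes — the methylation level of intact CpGs in *cis*. Population
designs see these effects through different lenses. `pedmeth` implements
four complementary family-based analyses over one shared data model (a CpG
× sample methylation-fraction matrix with read depths, a SNP × sample
dosage matrix, and a nuclear-family pedigree):

1. **Mid-parent-offspring (MPO) regression** — per CpG, the child's
   methylation level is regressed on the mean of the two parents' levels
   across trios; the slope estimates the narrow-sense heritability
   $h^2$. This sees *any* heritable signal, whatever its genetic mechanism.
2. **cis-mQTL mapping** — per (CpG, SNP) pair within 1 Mb, least-squares
   regression of methylation on additive allele dosage, with an empirical
   p-value from family-aware permutation.
3. **Allele-specific methylation (ASM)** — within one heterozygous
   individual, a 2×2 table of allele × methylation state over read
   fragments that span both the SNP and a CpG, tested with Fisher's exact
   test.
4. **Variance-QTL (vSNP/VMR) detection** — per (CpG, SNP) pair, the
   *variance* of methylation within each genotype class is regressed on
   genotype; runs of adjacent, consistently associated CpGs form variably
   methylated regions (VMRs), grouped into clusters.

A synthetic cohort generator with recorded ground truth makes each stage
testable by parameter recovery without any external data.

## Statistical models and conventions

### Mid-parent-offspring heritability

For CpG $j$ and trio $t$, let $y_t$ be the child's methylation fraction and
$x_t = (m_t^{father} + m_t^{mother})/2$ the mid-parent value, using only
trios where all three members have a valid call. The OLS slope of
$y \sim x$ is $\hat h^2$, with a two-sided t-test on the slope. A CpG is
called *heritable* when $\hat h^2 > 0.2$ (strict), at least 10 informative
trios contributed, and the Benjamini–Hochberg q-value is below 0.05. BH is
applied across **all** CpGs with a defined p-value, not only the
$h^2 > 0.2$ candidates — the conservative order; the alternative (filter
first, adjust after) can be obtained by subsetting before
`call_heritable_cpgs()`. Trios that share parents enter as independent
points; with 52 trios from 22 families this ignores the slight dependence
between siblings, matching how such pooled designs are usually analyzed.

Quantitative-genetics caveat, stated openly: the regression of offspring on
mid-parent estimates $h^2$ for an additive trait, but measurement noise in
the parents attenuates the slope. With read depth $D$ the binomial
measurement variance at latent level $\ell$ is $\ell(1-\ell)/D$; the
parameter-recovery tests compare $\hat h^2$ against the *attenuated*
closed-form expectation
$\beta^2 pq \,/\, (\beta^2 pq + (\sigma_e^2 + \sigma_m^2)/2)$
rather than against 1.

### SNP-CpGs

A CpG whose C position or C+1 position (the G) coincides with a polymorphic
SNP is flagged as a SNP-CpG: its heritability is a direct substrate effect,
not regulation. The flag requires polymorphism in the cohort but does not
re-check family specificity. On synthetic data the flag is exact, because
the generator only ever places a SNP on a CpG dinucleotide when the
configuration says it destroys that CpG.

### cis-mQTL scan

Methylation is regressed on dosage (0/1/2 alternate alleles) for every pair
within the 1 Mb window (inclusive, on |SNP pos − CpG pos|). Pairs with
fewer than 3 complete observations or constant genotype are skipped. The
empirical p-value is the plain fraction of permutations whose |t| exceeds
the observed |t| (an optional $(k+1)/(n+1)$ smoothing flag exists); with
`n_perm = 0` only asymptotic p-values are reported. q-values are BH over
all tested pairs, computed from the empirical p when available.

The permutation respects the pedigree: whole-family phenotype blocks are
permuted among families of identical size, then member labels are shuffled
within each family, preserving familial correlation under the null. This is
a stand-in for PLINK's QFAM procedure, whose exact between/within
decomposition is not reproduced here; the two are not asserted equivalent.

### ASM

Fragments are counted into one 2×2 table per (sample, SNP, CpG) triple —
each CpG on a fragment is tested separately. The two-sided Fisher p uses
the point-probability rule. An event requires $p < 0.001$ and an absolute
allelic methylation difference $\Delta > 0.2$, both strict. Tables with
fewer than 5 fragments on either allele are untestable by default
(configurable down to 1): a $\Delta$ computed from 2 reads is noise.
Detection power is depth-limited in a way worth quantifying: at allele
methylation probabilities 0.9 vs 0.1, exact enumeration over binomial
outcomes gives detection probabilities of 0.93 at 15 fragments per allele
and 0.999 at 25. The demo cohort's default of ~10 fragments per allele
therefore sits on the steep part of the power curve, and its ASM detection
rate (~0.3) is the honest value for that depth, not a defect.

### vSNPs and VMRs

For a (CpG, SNP) pair, the sample variances of methylation within the
three genotype classes are regressed on the codes 0/1/2. Three points and
two coefficients leave a single residual degree of freedom, so the per-CpG
t-score is extremely heavy-tailed under the null (P(|t| > 2) ≈ 0.36).
Specificity comes from the run requirement, not the per-CpG test: a VMR
needs at least 5 consecutive analyzed CpGs, spaced ≤ 200 bp, all reaching
|t| ≥ `vmr_t_min` with the same slope sign. A same-sign 5-run has null
probability ~2×10⁻⁴ per 8-CpG window, which is what keeps the
permutation-estimated false-positive rate low. `vmr_t_min` defaults to 2.0
on that reasoning; `calibrate_t_min()` instead walks a cutoff grid until
the permutation FPR drops below a target (default 10%), for datasets where
the default is mis-calibrated. Groups need ≥ 3 samples (a variance needs 2;
3 adds stability), group variances are unweighted in the regression, and
"adjacent" means consecutive among *analyzed* CpGs. The FPR permutation
shuffles whole sample columns (the simplest exchangeable null, preserving
each CpG's marginal distribution).

VMR clusters merge spans within 100 kb edge-to-edge (inclusive);
overlapping VMRs driven by different vSNPs merge, matching the intent that
a cluster describes a genomic region of genetically unstable methylation
rather than one association.

### Preprocessing

Cells below 10× depth become missing; sites with valid calls in fewer than
80% of samples are dropped (inclusive thresholds, so exactly 80% stays);
variable sites require a sample SD (n−1 denominator) of at least 0.1
(0.3 for "highly variable"). Sex chromosomes are excluded by default.
Missingness is evaluated *after* depth masking. All thresholds live in
`analysis_config()`, which a unit test pins to these values.

## The synthetic cohort generator

`simulate_cohort()` draws founder genotypes allele-wise from Hardy–Weinberg
proportions and transmits one uniformly chosen allele per parent per SNP,
so simulated trios are Mendel-consistent by construction.
`simulate_methylome()` builds, per sample and CpG,

latent = baseline + Σ β·dosage (cis effects)
         + family-shared noise (one draw per family per CpG)
         + residual noise whose SD may depend on the genotype at a vSNP,

clamps to [0, 1] (there is no canonical generative model for bounded
methylation fractions; clamping keeps the subsequent binomial sampling
valid), scales by (2 − dosage)/2 at CpG-destroying SNPs, and observes
Binomial(depth, latent)/depth with Poisson per-cell depths.
`read_depth = Inf` bypasses read sampling for analytic tests. Each stage
uses its own seeded RNG stream, so adding CpGs never perturbs genotype
draws. `simulate_allelic_fragments()` emits fragments only at heterozygous
(sample, SNP) pairs, with a fair allele draw and Bernoulli methylation at
the allele-specific probability recorded in the ground truth.

The canonical demo cohort (`simulate_study_cohort()`) mirrors the target
study design — 22 nuclear families, 96 samples, 52 parent-child trios. A
published description of "one or two siblings" per family cannot produce 52
children from 22 families, so the generator uses 14 families with two
children and 8 with three, which reproduces both the 96-sample and the
52-trio count. Its effect sizes (cis β = 0.2, family noise SD 0.12, vSNP
class SDs 0.05/0.13/0.22) were chosen from the closed-form marginal SD so
that each effect class clears the SD ≥ 0.1 variable-site filter — a
positive-control design, not an estimate of real effect sizes, which no
desk-scale simulation can supply.

What the generator does **not** emulate: bisulfite conversion error,
imprinting and parent-of-origin effects, linkage disequilibrium between
SNPs, cell-composition heterogeneity, and trans effects. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to everything real data
contains.

## Problem sizes and numerical choices

The shipped tests run the MPO recovery on 200 replicate cohorts (22
families, depth 100), the permutation-calibration check on 1,000
independent null pairs with 500 permutations each, the mQTL power check on
30 replicates at 1,000 permutations, and the VMR recovery on 30 replicates
of 200 samples; the acceptance script uses slightly smaller replicate
counts. These sizes put Monte-Carlo error comfortably inside the asserted
tolerances while keeping a full run in minutes on one core. Exact-test
implementations (Fisher via `stats::fisher.test`, the exact HWE test via a
closed-form log-gamma enumeration over heterozygote counts) are verified
against independent brute-force enumerations — hypergeometric summation and
the heterozygote-count recurrence respectively — to 1e-12 over all tables
with margins ≤ 15. Probability ties in both exact tests are compared with a
tiny relative tolerance (1e-7 / 1e-9) so floating-point rounding cannot
split exact ties.

Degenerate inputs are defined, not accidental: a monomorphic SNP has HWE
p = 1; a zero-margin 2×2 table has Fisher p = 1; a CpG with constant
mid-parent values, or fewer than 3 informative trios, is untestable rather
than 0 or significant; an empty matrix filters to an empty matrix.

## Worked example

```{r example, eval = FALSE}
library(pedmeth)

st  <- simulate_study_cohort(seed = 1)
cfg <- analysis_config(n_perm = 500, seed = 1)
res <- run_pipeline(st, cfg)
res
write_results(res, "pedmeth_out")
```

`run_pipeline()` logs one line per stage (input/output counts) and returns
the per-stage tables; `write_results()` writes them as TSV/BED. The same
objects round-trip through the on-disk formats (`write_study()` /
`load_study()`): VCF for genotypes (GT only, biallelic SNVs), PLINK FAM for
the pedigree, TSV for methylation (per-sample fraction/depth column pairs,
`NA` for missing) and fragments, BED (0-based half-open) for region
annotations, and JSON for the simulation ground truth.

## Known limitations

- The mQTL model is a plain additive OLS; no kinship mixed model is
  offered, so the asymptotic p-values are anti-conservative under family
  structure — that is precisely why the family-aware permutation p exists
  and is the one used for q-values.
- The variance regression treats the three group variances as equally
  precise although group sizes differ; a group-size-weighted variant is
  available behind a flag.
- ASM is tested per CpG; pooling CpGs along a read is a plausible
  alternative reading of read-level ASM and is not implemented.
- Heritability from mid-parent regression assumes additivity; dominance
  and shared environment both load on the slope, which is why the
  family-noise simulation class is deliberately "heritable but
  non-genetic".
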