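---
title: "Two-stage case-control SNP association with haplotype-group pair tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage case-control SNP association with haplotype-group pair tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopair)
```

## The analysis

`haplopair` implements a two-stage association analysis for biallelic SNP
genotypes in a case-control design, of the kind used to look for
medium- and low-penetrance risk variants in small cohorts (a few hundred
cases and controls) where no single marker can be expected to reach
genome-wide significance on its own.

**Stage 1** is a conventional single-SNP scan. After sequential quality
control, each variant is tested under the allelic (multiplicative)
model: every non-missing diploid call contributes two alleles, and the
2×2 table of effect-allele versus other-allele counts in cases versus
controls gives

* the odds ratio $OR = ad/bc$,
* the Woolf confidence interval
  $\exp\!\left(\ln OR \pm z_{\alpha/2}\sqrt{1/a+1/b+1/c+1/d}\right)$, and
* the Pearson $\chi^2$ statistic
  $N(ad-bc)^2 / \big((a{+}b)(c{+}d)(a{+}c)(b{+}d)\big)$ with one degree
  of freedom.

No continuity correction is applied anywhere: the multiplicative model
treats the two alleles of one genotype as independent Bernoulli draws,
and the uncorrected $\chi^2$ is the score test of that model. Both OR
directions are reported (the reciprocal pair), with the pooled-sample
minor allele as the nominal effect allele; an exact frequency tie
designates the reference allele.

**Stage 2** asks whether *pairs* of nominally associated exonic variants,
whose proteins physically interact, carry joint signal. Candidates are
exonic variants with stage-1 $p < 0.05$; each retains the direction of
its risk ("negative") allele, the allele whose stage-1 OR exceeds 1.
Candidates are paired across a protein–protein interaction edge table
(STRING-export dialect; integer scores on the 0–999 scale are divided by
1000) retaining edges with confidence at least 0.700. For each SNP pair,
two models are fitted:

* **Pooled-allele multiplicative model.** Each individual contributes up
  to four alleles — two per locus — classified as negative or positive
  (protective). The pooled 2×2 table (negative vs. positive × case vs.
  control) goes through the same OR / Woolf CI / $\chi^2$ machinery as
  stage 1. An individual missing one locus's call contributes only the
  other locus's two alleles, so group totals need not be multiples of
  four under missingness.
* **Additive (haplotype-group) model.** The nine two-locus genotype
  combinations are partitioned by the total negative-allele count $k$:
  Group I ($k \in \{3,4\}$, negative alleles prevail), Group II
  ($k = 2$, balanced), Group III ($k \in \{0,1\}$, positive alleles
  prevail) — three combinations per group. Only individuals with
  complete genotypes at both loci are classified, since the groups are
  defined on the full four-allele combination. The default contrast is
  Group I versus Group III as a 2×2 table of individuals; `I_vs_rest`
  and `II_vs_III` are available because the literature rarely states its
  baseline and the choice is genuinely open. We default to I vs. III as
  the cleanest "many risk alleles vs. few" comparison; II vs. III is
  useful for checking the additive ordering (the Group II effect should
  lie between Group I's and the null).

Multiple testing is Bonferroni-corrected at both stages. The stage-2
divisor is always the number of pairs actually tested in the scan — not
a number fixed in advance — because the testable pair set depends on
which genes end up with candidate variants.

## Quality control

Filters run in a fixed order, and each variant is attributed to the
*first* filter it fails, so that the staged removal ledger sums exactly
to the input count (`in = non-autosomal + call rate + MAF + HWE + kept`):

| filter | default | note |
|---|---|---|
| autosomes only | on | X/Y/MT labelled variants removed first |
| variant call rate | ≥ 0.99 | at most 1% failed genotyping per variant |
| sample call rate | ≥ 0.95 | samples dropped; earlier stages not recomputed |
| minor allele frequency | ≥ 0.03 | computed on surviving samples |
| Hardy–Weinberg equilibrium | p ≥ 0.05 | Pearson $\chi^2$, df = 1 |

HWE is tested in controls only by default (`hwe_in_controls = TRUE`):
a true disease association distorts genotype proportions in cases, and
filtering on all samples would preferentially discard real signal. The
HWE test is the conventional Pearson $\chi^2$ against $p^2 : 2pq : q^2$
at the estimated allele frequency, not the exact test; a monomorphic
variant is assigned $\chi^2 = 0$, $p = 1$ by convention.

## Linkage disequilibrium

Array genotypes are unphased, so two-locus haplotype frequencies are
estimated by the standard EM algorithm: only the double heterozygote is
phase-ambiguous, and its coupling/repulsion split is updated from the
current frequency estimates (convergence when the largest frequency
change falls below $10^{-8}$, capped at 1000 iterations; the starting
point is the uniform distribution). From the frequencies,
$D = f_{AB} - p_A p_B$, $D' = |D| / D_{max}$, and
$r^2 = D^2/(p_A p_a p_B p_b)$; significance uses
$\chi^2 = n_{chrom} \, r^2$ (df = 1). LD is a population property, so it
is computed in controls by default when phenotypes are supplied. Loci
that are monomorphic in the estimation sample have undefined LD and are
flagged rather than silently dropped.

## The synthetic cohort generator

No genotype-level data ship with the package; `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
and `write_fixtures()` emits the four standard input files (VCF,
phenotype TSV, annotation TSV, PPI TSV) deterministically, byte-identical
under a fixed seed.

Defaults mirror the target study design: 144 cases, 163 controls,
autosomal biallelic SNPs with allele frequencies uniform above a 3%
floor, and 1% per-genotype missingness, completely at random (real
missingness mechanisms are rarely random, but no better mechanism is
identifiable from summary data; the rate is configurable).

**Disease model.** Controls are drawn under Hardy–Weinberg equilibrium
at the per-variant allele frequencies. Cases are drawn by weighted
rejection sampling from a multiplicative risk model:
$P(\text{case} \mid g) = \pi \prod_i OR_i^{\,g_i}$, with baseline
prevalence $\pi = 0.05$ by default and the product running over planted
single-SNP effects and planted pair effects (the pair OR applies per
risk allele counted across both loci). This form was chosen over a
logistic link deliberately: under multiplicative risk, case genotypes
remain in Hardy–Weinberg proportions at a shifted allele frequency and
the planted OR is *exactly* the allelic odds ratio of cases against the
population from which controls are drawn, which makes parameter-recovery
tests sharp. A logistic link attenuates the case-control contrast in a
dose-dependent way and leaves no closed-form target. The model must keep
$\pi \times \max_g \prod OR_i^{g_i} \le 1$; configurations that violate
this, or that cannot plausibly accrue the requested number of cases, are
rejected with an error naming the offending parameter.

**LD blocks** are realized by founder-haplotype copying: within a block
all sites share the first site's allele frequency, and each haplotype's
sites copy a founder allele, being redrawn independently with
probability $1-\sqrt{r^2_{target}}$. This gives expected pairwise
$r^2$ equal to the target and exact duplication (sample $r^2 = 1$) at a
target of 1, which is the regime the LD machinery most needs to
reproduce. The generator does not model recombination maps, population
structure, admixture, or array-intensity artefacts — so passing tests
demonstrate correctness of the statistics under their own assumptions,
not robustness to stratification or batch effects, neither of which the
pipeline corrects for.

For pair effects, note that the pooled-allele OR equals the per-allele
generative OR only when the two loci share an allele frequency; with
unequal frequencies the pooled table blends two different shifted
frequencies and the estimand has no closed form. Recovery simulations
therefore plant pair effects at equal MAFs.

## Numerical choices and edge cases

* 2×2 cells are stored as doubles: products of four margins overflow
  32-bit integers at realistic allele counts.
* `odds_ratio` requires $bc > 0$; a zero denominator cell yields `NA`
  with a warning rather than a continuity-corrected estimate. The Woolf
  CI likewise requires all four cells positive.
* Degenerate $\chi^2$ margins return $\chi^2 = 0$, $p = 1$.
* A variant whose both-direction ORs are exactly 1 cannot be polarized
  into negative/positive alleles and is reported as an error for that
  pair; the scan continues over the remaining pairs.
* PPI edges are undirected: reversed duplicates collapse (keeping the
  higher score), self-edges are dropped, and the 0.700 cutoff is
  inclusive. Gene-symbol matching is exact and case-sensitive; aliasing
  is the annotation file's responsibility.
* Pair output ordering is canonical (gene pair lexicographically, then
  variant position), so results are invariant to input row order.

## Reproducibility

`run_pipeline()` executes QC → allelic scan → Manhattan export →
candidate selection → PPI pairing → pair scan from a single
configuration (constructor or YAML), writes every intermediate table as
TSV, and records counts at every stage — including the exact Bonferroni
divisors used — in `run_summary.json`. Re-running with the same inputs
and configuration reproduces byte-identical tables.

The package's simulation-based checks use deliberately modest problem
sizes chosen to make the sampling distributions sharp where it matters:
calibration of the allelic test on 200 null variants at the default
cohort sizes, and CI coverage of planted effects over replicates of
2000 cases / 2000 controls at two variants, where the standard error of
a coverage estimate over 100 replicates is about 2 percentage points.

## Limitations

The pipeline intentionally reproduces a specific analysis style:
no covariate adjustment, no genomic control or PCA stratification
correction, no genotypic/dominant/recessive single-SNP models, no
phased-haplotype frequency estimation for the pair test (the pooled
table counts alleles, not EM haplotypes), and no interaction term — the
pair models aggregate marginal risk alleles rather than fitting an
epistasis model. These are faithful properties of the method, and
results should be read with them in mind.
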