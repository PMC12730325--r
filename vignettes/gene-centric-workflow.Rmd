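---
title: "Gene-centric burden association and evidence integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric burden association and evidence integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecentric)
```

## The model

Single-variant association scans leave two blind spots that motivate this
package. First, a gene whose damaging alleles are spread over many rare
variants never accumulates enough signal at any one site. Second, recessive
architectures — including compound heterozygotes carrying two *different*
damaging alleles of the same gene — are nearly invisible to per-variant
tests, which only see each site's marginal effect. The gene-centric burden
model addresses both.

Every coding variant $v$ carries a functional-effect score $s_v \in [0,1]$,
where 1 means the protein function is retained (synonymous-like) and 0 means
loss of function. Scores arrive as input (from any variant effect
predictor); the package does not train one. For an individual with
unphased genotype counts $g_v \in \{0,1,2\}$, each alternative-allele copy is
treated as an independent damaging event with probability $q_v = 1 - s_v$.
The number of damaging events in a gene is then Poisson-binomial over the
allele copies, giving

$$P(0) = \prod_v s_v^{g_v}, \qquad
  P(1) = P(0)\sum_v g_v \frac{1-s_v}{s_v},$$

with exact short-circuits when some $s_v = 0$. The *dominant damage
probability* is $1 - P(0)$ (at least one event) and the *recessive damage
probability* $1 - P(0) - P(1)$ (at least two events anywhere in the gene).
Because genotypes are unphased, "two events" deliberately counts compound
heterozygotes as well as homozygotes; treating copies as independent is the
honest model when phase is unknown, and it is what makes recessive DNA-repair
signal detectable at all. The complements $P(0)$ and $P(0)+P(1)$ are the
*effect scores* used in regression — higher means less damage — so a
**negative** association statistic indicates a risk gene.

### The combined test

For each gene the package fits a logistic regression of case status on the
covariates plus both effect scores and compares it with the covariates-only
model by a 2-df likelihood-ratio test (`pwas()`). The 2-df formulation nests
both single-mode tests: a significant result says that one or both burden
components matter. Per-component 1-df Wald statistics are reported alongside,
and for genes passing the Bonferroni-corrected combined threshold an
inheritance mode is inferred: a component counts when its Wald p-value passes
the same corrected threshold; both components give `hybrid`; if neither does
on its own, the smaller component p-value decides. Because the two effect
scores are positively correlated, the conditional Wald tests are what
disambiguate the modes — under a purely dominant architecture the recessive
coefficient is ~0 *given* the dominant one, and vice versa.

Cohen's d (pooled SD, $n-1$ denominators) of the effect scores between cases
and controls is reported as a model-free effect size per mode.

### Degenerate inputs

A gene whose effect scores are constant in the cohort (no damaging variation)
is flagged `zero_variance` with `NA` statistics; complete separation is
flagged `separation`; a component dropped as aliased by the QR decomposition
is flagged. No gene ever raises an error inside the scan loop.

## Surrounding stages

**GWAS coherence filtering.** Summary statistics are mapped onto gene bodies
(BED intervals are 0-based half-open on disk, positions 1-based in
statistics; the conversion happens at the reader boundary). A gene is
retained only when at least 2 significant variants support it and the modal
effect direction holds a fraction `coherence` of them. The source narrative
requires "the vast majority" without quantifying it; the default is 0.75 and
is configurable. Directionality is assessed among significant variants only
(also configurable via the `sig_threshold` argument). MAF filtering folds the
allele frequency (`min(af, 1-af)`). The inflation factor is
$\lambda = \mathrm{median}(\chi^2_{obs})/0.45494$; it is meaningful on a
post-QC scan, so the package's own calibration checks compute it after the
MAF filter — rare-variant Wald statistics at moderate sample size are
conservative and would deflate $\lambda$ spuriously. ChrX/Y are excluded in
coding-gene mode by default.

**Credible sets.** Fine-mapping posteriors (PIPs) arrive as input. The 95%
credible set is the smallest PIP-descending prefix whose cumulative PIP
reaches the target; ties break by position then alleles so output is
deterministic; loci whose total PIP falls short return all variants with an
under-coverage flag. Intergenic sets are annotated with the nearest gene and
the base-pair distance to its closest base.

**Cross-cohort comparison.** Disjoint cohorts are never meta-analysed; the
package matches variants on exact `chrom:pos:ref:alt` keys, applies a single
allele-flip rule (beta negated, AF complemented) for ref/alt-swapped records,
refuses to flip strand-ambiguous A/T and C/G variants, and reports
missingness, sign-concordance and moderate-effect discordance
(|β| > 0.1 in both cohorts by default).

**Evidence integration.** Gene evidence from multiple sources (two cohort
freezes, aggregator score tiers, TWAS, PWAS, gene-level PheWAS) is reduced to
labels `a`–`i` by configurable predicates. Only four label definitions are
stated outright by the compiled evidence table's conventions (`d`: both
freezes + high-confidence aggregator + TWAS; `b`: high-confidence aggregator
+ TWAS without cohort replication; `g`: PWAS; `i`: gene-level PheWAS); the
rest are documented best-guess defaults, and curated tables that already
carry printed labels bypass the predicates entirely. The core-list rule is
deliberately minimal: a gene whose *sole* label is `b` lacks independent
replication and is excluded; everything else is core. The rule is idempotent
and monotone — added evidence can only promote. Overlap statistics use the
exact hypergeometric upper tail with a default universe of 18,053
protein-coding genes (override `N` for other universes); the binomial support
test requires its background rate `p0` explicitly because no universal
default is defensible.

## The synthetic-data generator

The generator exists so every stage is testable without controlled-access
biobank data. It emulates:

* a **rare-skewed allele-frequency spectrum**, Beta(0.3, 3) clipped to
  [0.001, 0.999];
* **founder drift** between two related populations via the Balding–Nichols
  law: given baseline $p$ and divergence $F$, population 2 draws
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, with mean $p$ and variance
  $F\,p(1-p)$. $F = 0.05$ is the default (same order as
  Finnish-vs-European differentiation); $F = 0$ gives identical populations;
* **Hardy–Weinberg genotypes** given each population's frequencies;
* a **functional class mix** of 50% synonymous ($s = 1$), 40% missense
  ($s \sim \mathrm{Beta}(4,1)$, benign-skewed) and 10% loss of function
  ($s \sim U(0, 0.03)$);
* a **logistic liability** whose linear predictor adds, per planted risk
  gene, effect × (dominant or recessive damage probability) — the *same*
  quantities the association stage computes, so parameter recovery is well
  posed — plus sex and two synthetic PCs (log-odds 0.3, 0.15, −0.15) and an
  intercept solved to hit the target case fraction (default 10%, a
  registry-like prevalence for an enriched case/control design).

Recommended planted effects, used by the package's own recovery checks, are
**1.5 log-odds per unit dominant damage** and **3.0 per unit recessive
damage**. Recessive damage events are much rarer (P(≥2 events) is small for
most genes), and high per-genotype penetrance for biallelic damage of a
DNA-repair-like gene is the biologically expected regime, so a larger
per-unit coefficient is both necessary for detectability at realistic cohort
sizes and defensible.

The generator does **not** emulate linkage disequilibrium, imputation error,
genotyping batch structure, X-dosage, or relatedness. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to those real-data complications; in
particular, variant-to-gene mapping on real data inherits all the usual
LD-driven ambiguity that the coherence filters only partially mitigate.

Every stochastic operation takes an explicit seed (derived by fixed offsets
from the configuration seed), and global RNG state is saved and restored, so
identical configurations give byte-identical pipelines.

## Numerical choices

* Damage products accumulate in log space with an underflow floor at
  1e-300; variants with $s_v = 0$ are handled by an exact zero
  short-circuit rather than `log(0)`.
* Wald standard errors come from the pivoted QR of the IRLS fit (dispersion
  fixed at 1), as in `summary.glm`.
* Credible-set ties break by position, then ref, then alt.
* The null median $\chi^2_1$ is taken as `qchisq(0.5, 1)` = 0.4549364.
* `order()`'s stable sort underlies tie behaviour in score-gap ranking.

## Problem sizes used by the packaged checks

The package's own validation suite runs at sizes chosen to make the
statistical claims sharp while remaining routine on a laptop: exhaustive
enumeration against the burden model on 500 random genes of up to 12 allele
copies; 10,000 random PIP vectors plus 1,000 calibrated single-causal loci
for the credible-set contract; 1,000 null cohorts of n = 2,000 for the
type-I error of the combined test; a 50,000-variant permuted-phenotype scan
for the inflation factor; and 20 replicates of a 200-gene, n = 5,000 cohort
with one planted dominant and one planted recessive gene for parameter and
mode recovery.

## Limitations

Scores are taken at face value: a systematically biased variant-effect
predictor biases both burden components. The independence-across-copies
assumption ignores phase, so two damaging alleles in *cis* are
misclassified as compound-heterozygous damage. The evidence-label algebra
reflects one published compilation's conventions; other evidence schemes
need a custom `evidence_config()`. The single-causal posterior used by the
pipeline's demonstration fine-mapping stage is a stand-in — real credible
sets should come from a proper fine-mapping tool and enter through
`read_pip_table()`.
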