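---
title: "Differential transcript usage with usagekit: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential transcript usage with usagekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most genes express several transcript isoforms. Differential gene expression
(DGE) analysis sums them and can miss — or be actively cancelled out by —
*isoform switches*: one transcript's share of the gene's output rises while
another's falls, leaving the total nearly unchanged. Differential transcript
usage (DTU) analysis targets exactly this: for transcript $i$ of gene $j$,
the usage in a sample is

$$ \mathrm{TU}_{i,j} = \frac{t_i}{\sum_{k=1}^{n_j} t_k}, $$

the transcript's count divided by the gene's total, and DTU is a change in
these proportions between conditions. usagekit implements a complete DTU
pipeline for two-group (case–control) bulk RNA-seq with clinical covariates:
expression filtering, two alternative count-model testers, two-stage error
control, cellularity covariates, replication/DGE/biotype characterisation,
pathway clustering, and a ground-truth simulator that exercises every stage.

Counts are accepted as non-negative reals because scaledTPM values — TPM
abundances rescaled by library size, the recommended input scale for usage
models — are fractional. The count likelihoods need integers, so the
statistical modules round to the nearest integer at model entry; this is the
package's own convention and matches common practice for scaled estimated
counts. Usage is undefined where a gene's total is zero; such entries are
flagged `NA`, never imputed, and the expression filter removes the genes
this could affect. Sex chromosomes are excluded at load by default
(`exclude_chrom = c("X", "Y")`), mirroring quantification restricted to
autosomes in mixed-sex cohorts.

## Expression filtering

DTU tests are unstable on weakly expressed transcripts, so a *soft* filter
runs first. With $n = \min(\#\text{controls}, \#\text{cases})$, a transcript
is removed iff strictly more than $n$ samples have fewer than 10 counts, or
strictly more than $n$ samples give it less than 1% of its gene's
expression. The allowance $n$ is recomputed from the sample table, never
hard-coded: a transcript expressed in only one group survives, which matters
because absence in one group may *be* the DTU signal. Genes are then removed
if any single sample has a gene total below 10 counts, or if fewer than two
transcripts survive (usage is undefined for a single transcript).

Two decisions were genuinely open and are fixed here: both criteria share
the same allowance $n$ (the thresholds are stated jointly; symmetric
treatment is the simplest faithful reading), and the 1% criterion is
evaluated on pre-filter usage in a single pass — filtering is not iterated
after transcript removal, and `dtu_filter()` is consequently idempotent,
which the tests assert.

## The Dirichlet-multinomial tester

For gene $j$ with $K$ transcripts, sample $i$'s counts
$y_i \in \mathbb{N}^K$ given the total $m_i$ follow a Dirichlet-multinomial
$\mathrm{DM}(m_i,\, \gamma \pi_i)$ with

$$ \pi_{ik} = \mathrm{softmax}_k(x_i^\top \beta_k), \qquad
   \beta_{\mathrm{ref}} = 0 , $$

where $x_i$ holds the intercept, the condition indicator (control = 0),
RIN, age, sex, and any selected cellularity scores. The precision $\gamma$
captures biological overdispersion relative to the multinomial
($\gamma \to \infty$ recovers it — a numerically verified limit used as an
oracle in the tests). The reference transcript is the one with the largest
mean count; the fit is invariant to this choice, which only aids
conditioning. A ridge penalty $\lambda\lVert\beta\rVert^2$ with
$\lambda = 10^{-6}$ is always on, so separated data (a transcript observed
in one group only) yields finite, converged estimates without any
data-dependent switching. Covariates other than the condition indicator are
standardised; the condition coefficient is unaffected.

**Precision estimation.** A common $\gamma_0$ maximizes the pooled
*Cox–Reid adjusted* profile likelihood over a log-spaced grid refined by
golden-section search; each gene's $\gamma_g$ then maximizes its own
adjusted profile likelihood penalized on the log scale toward
$\log\gamma_0$, with a quadratic penalty worth 10 pseudo-genes — one
pseudo-gene being the curvature of an average gene's adjusted profile
log-likelihood in $\log\gamma$ at the common optimum, so the prior weight
scales with how informative the data actually are about $\gamma$.
The Cox–Reid term ($-\tfrac12\log\det$ of the observed information of
$\beta$) matters: the plain profile likelihood overstates $\gamma$ because
the per-gene coefficients absorb real variation, and that upward bias makes
downstream tests anti-conservative. With the adjustment, simulations at the
package's reference conditions (precision 50, 15 vs 15 samples) recover
$\hat\gamma_0$ within a few percent and give nominal type-I error. The
moderation weight is a stabiliser for small cohorts, not a tuning knob; all
$\gamma$ are bounded to $[10^{-2}, 10^6]$.

**Tests and effect sizes.** The gene-level test is a likelihood-ratio test
dropping the condition column, $\chi^2_{K-1}$. The transcript-level test
collapses the gene to "this transcript vs the rest"; because aggregating
Dirichlet components is again Dirichlet, this is an exact beta-binomial
regression on the logit of the transcript's usage with the same $\gamma$.
Its condition coefficient is the reported effect size, on the natural
log-odds usage scale with positive values meaning increased usage in cases.
(The scale is a package convention; only signs and the exact $K = 2$
antisymmetry — the two effect sizes of a two-transcript gene are equal and
opposite — are comparable across implementations.) For $K = 2$ the
transcript test and the gene test coincide, which the tests assert to
$10^{-6}$.

## The negative-binomial alternative

The second tester models each transcript's count and the remainder of its
gene as two negative-binomial observations per sample (log link), with free
per-sample intercepts absorbing library size and gene expression, a
this-transcript indicator, covariate-by-indicator terms, and a
condition-by-indicator interaction — the DTU effect, tested by a df = 1
LRT. Treating the two counts per sample as independent is an approximation;
the per-sample intercepts absorb the shared total, and the tests verify
that doubling one sample's counts leaves estimates essentially unchanged.
Dispersions are estimated per transcript by Cox–Reid adjusted profile
likelihood and shrunk halfway (log scale) toward a log-linear
mean–dispersion trend fitted across all transcripts; the fixed 0.5 weight
keeps the procedure deterministic. Gene-level p-values aggregate transcript
p-values by Šidák on the minimum, $1 - (1 - \min_k p_k)^K$ — a named
aggregation function was used originally without a printed formula, so the
standard monotone choice is implemented and documented as a divergence
risk. Calibration note: at moderate expression (gene means of a few
hundred counts) this tester runs mildly liberal (empirical type-I around
0.06 at nominal 0.05 in our simulations), a known trait of fixed-dispersion
NB LRTs with many nuisance intercepts; at high expression it is nominal,
and the packaged calibration checks use that regime.

## Two-stage error control

Gene-level p-values are screened by Benjamini–Hochberg at
$\alpha = 0.05$. Within each screened gene, transcript p-values are
adjusted by a Shaffer-modified Holm procedure that exploits the
compositional logic of DTU: proportions sum to one, so a gene with any
differential usage must have at least two non-null transcripts, hence at
most $K - 2$ nulls can be true. The step-down multipliers are

$$ m_j = \max\!\big(1, \min(K - j + 1,\; K - 2)\big), $$

applied to the sorted p-values with a running maximum. The sequence is
derived from that logical constraint and verified in the tests against a
brute-force closed-testing oracle that enumerates all admissible null
configurations. For $K = 2$ the two transcripts form a logical pair: if
either is confirmed both are, the compensating transcript inheriting the
smaller adjusted p. For $K = 3$ all multipliers are 1. A transcript is a
*DTU event* if its within-gene adjusted p is below $\alpha$; a *DTU gene*
has at least one event. Confirmation applies the nominal $\alpha$ within
screened genes, gated by the BH screen at the same level; no stage-2
rescaling by the screened fraction is applied. Ties in p are broken by
transcript id for determinism.

## Cellularity covariates

Bulk brain tissue varies in cell-type composition, which can confound
case–control comparisons. Marker gene profiles (MGPs) summarise each cell
type as the first principal component of its marker genes'
$\log_2(\mathrm{CPM} + 0.5)$ expression (the 0.5 pseudocount is the
package's choice), oriented so that higher scores track higher mean marker
expression. Cell types whose scores differ between groups (two-sided
Wilcoxon rank-sum, $p \le 0.05$ — a rank test avoids distributional
assumptions) are appended to the design. On simulated data without
cellularity confounding, including or excluding MGPs changes fewer than 5%
of called events.

## Downstream characterisation

Replication concordance partitions the transcripts shared by two cohorts
into four categories by nominal significance (neither / discovery-only /
both / replication-only) and reports counts, Pearson correlations of effect
sizes, and percent sign agreement; an exactly-zero effect counts as
disagreement, to avoid inflating concordance. DTU–DGE comparison intersects
DTU genes with an externally supplied gene-level result at FDR < 0.05 and,
for single-event genes, asks whether the DTU and DGE directions agree.
Biotype overrepresentation uses two-sided Fisher exact tests per biotype
with Bonferroni correction over the biotypes tested; two-sided is the
conservative default where the original analyses' sidedness is not
documented.

## Pathway enrichment and kappa clustering

DTU genes are tested against the filtered background with upper-tail
hypergeometric tests per gene set (GMT input, BH within each category,
FDR < 0.05). Significant sets are then de-duplicated by agglomerative
nearest-neighbour merging under Cohen's kappa similarity of gene
memberships, stopping when no inter-cluster $\kappa$ exceeds 0.4. Three
choices had to be fixed: the kappa universe is the union of the significant
sets' genes (using the whole background would inflate the both-absent cell
and with it $\kappa$); cluster-to-cluster similarity uses the union of
member gene sets (a deterministic, monotone linkage); and cluster titles
are chosen deterministically — smallest member p, then larger set, then
lexicographic id — replacing any random tie-breaking, a reproducibility
requirement. Each cluster's p-value aggregates its members by Fisher's
method, $X^2 = -2\sum\ln p_i \sim \chi^2_{2m}$, with p floored at
$10^{-300}$; plain Fisher is used, without dependent-p corrections.
Clusters are reported sorted by aggregated p.

## The simulator

`simulate_dtu()` generates the full input bundle (counts, annotation,
sample table, truth) from a single seed. Gene totals are negative binomial
with log-normal gene means and library factors; the transcript split is
Dirichlet-multinomial with precision $\gamma$ around baseline proportions
drawn from a symmetric Dirichlet. Defaults emulate a small post-mortem
brain cohort: 17 cases / 11 controls, RIN ~ N(7, 1), ages around 72, a
moderate precision of 50, and 10% of genes carrying a switch. A DTU gene's
effect perturbs the two affected transcripts' log-abundances by $+\delta$
and $-\delta$, *renormalised within the pair* so the pair's combined share
— and therefore every other transcript's expected usage — is exactly
unchanged. This mirrors the biology of a compensating isoform switch and
makes "the other transcripts are null" literally true, which the
family-wise error evaluation requires. The realised per-transcript effects
on the transcript-vs-rest log-odds scale (the scale the estimators report)
are stored in the truth table; for a two-transcript gene they equal
$\pm 2\delta$. Sub-seeds for samples, gene structure, effects and counts
are derived from the master seed by a fixed hashing scheme, so components
are individually reproducible.

What the simulator does *not* emulate: read-level error, positional or GC
bias, quantification uncertainty between similar isoforms, batch effects
beyond library size, and correlated gene–gene structure. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not robustness to everything real data can do.

## Numerical choices and problem sizes

Optimization is BFGS with analytic gradients; convergence requires a
gradient max-norm of $10^{-6}$ (looser, $10^{-3}$, inside precision
profiling where only the profile value matters), with warm starts across
the precision grid. Likelihood-ratio statistics in $[-10^{-6}, 0]$ are
clamped to zero. The test-suite simulations use: 500 genes (K = 3,
15 vs 15) for null calibration; 600 genes (K = 4) for the within-gene FWER
bound; 67 two-transcript genes per effect size for recovery; 300 genes for
the end-to-end power/FDR check; the common precision is estimated on the
100 highest-count genes in the larger runs. These sizes are the package's
reference conditions — large enough for the binomial/KS tolerances used,
small enough to run routinely. The acceptance script pools the FWER
simulation over 3 seeded replicates of 600 genes.

## Known limitations

- Precision is gene-wise and untrended; genes with many isoforms may be
  less well served (no per-transcript precision, by design).
- Effect sizes are not shrunk; with few samples, extreme usage switches in
  weakly expressed genes carry wide implicit uncertainty.
- The NB tester's independence approximation is mildly liberal at moderate
  expression (see above).
- Gene sets are consumed as local GMT files; no ontology traversal or
  remote annotation retrieval is performed.
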