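---
title: "Discovering subtype-specific miRNA-mRNA regulatory modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering subtype-specific miRNA-mRNA regulatory modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmodule)
```

## The problem

In heterogeneous diseases such as multiple myeloma, miRNA-mRNA regulation
can differ between molecular subtypes. A module-level view asks: which
sets of miRNAs and mRNAs act together, and under which samples — i.e.
which subtype — do they act? `mirmodule` answers this in two stages:

1. **Comodule discovery.** A ping-pong projection-and-threshold iteration
   over the paired expression matrices finds *comodules*: triples of a
   gene set, a miRNA set and a sample set in which both feature sets are
   coherently expressed across exactly those samples. A comodule whose
   samples all carry one subtype label is *subtype-specific*; otherwise it
   is *heterogeneous*.
2. **Module extraction.** Within each comodule, a constrained
   three-objective genetic algorithm selects the subset of miRNAs and
   mRNAs that is (i) enriched in disease-associated Gene Ontology
   biological processes, (ii) anticorrelated and strongly supported by
   target predictions, and (iii) variable between subtypes. The feasible
   Pareto front of such selections forms the comodule's candidate
   functional regulatory modules; rank aggregation orders them.

## Comodule discovery

Let $E$ ($N_G \times N_C$) and $R$ ($N_D \times N_C$) be the gene and
miRNA expression matrices over common samples. Four standardized copies
are used: $E_G$, $R_D$ (each feature row to mean 0, sd 1) and $E_C$,
$R_C$ (each sample column to mean 0, sd 1). The sample ($n-1$) standard
deviation is used throughout; constant vectors map to all zeros rather
than propagating division by zero.

From a random gene seed $\hat g$ the cycle is

1. sample scores $E_C^\top \hat g$, thresholded at $t_C$;
2. miRNA scores $R_D \hat c$, thresholded at $t_D$;
3. refined sample scores $R_C^\top \hat d$, thresholded at $t_C$;
4. gene scores $E_G \hat{\tilde c}$, thresholded at $t_G$,

with each stage z-scoring its score vector against its own mean and
standard deviation, keeping items with $|z|$ above the threshold, and
rescaling the retained *signed* scores to unit norm. Thresholding is
two-sided deliberately: miRNA expression is negatively correlated with
that of its targets, so coherent modules are mixed-sign and a one-sided
rule would forbid them. The cycle repeats until the three index sets stop
changing and the weights are stationary (change below `convergence_tol`,
default $10^{-6}$); the fixed point is then *verified* by one further
full cycle, and runs that exceed `max_iterations` (default 100), lose a
set entirely, or fail verification are discarded. Every returned comodule
is therefore exactly invariant under one more iteration — a property the
test suite asserts on every run.

### Thresholds

A coherent block occupying a fraction $p$ of an axis can reach a z-score
of at most about $\sqrt{(1-p)/p}$ on that axis (the score vector's own
standard deviation is inflated by the block itself). Feature axes, where
a module occupies $p \approx 0.01$–$0.03$, therefore support strict
thresholds, and strictness is what keeps the expected number of false
selections ($\approx$ axis length $\times$ two-sided tail mass) below
one. The sample axis, with $p \approx 0.1$, caps near $z = 3$ and needs a
looser threshold. The defaults are $t_G = 3.5$, $t_D = 3$, $t_C = 1.8$.
They are tuned to array-scale inputs (thousands of genes, hundreds of
miRNAs, tens of samples); for very different shapes the same z-gap
argument should be re-applied.

Seeding uses `n_seeds` random gene subsets of size `seed_size` (defaults
5000 and 10). Converged comodules are deduplicated at Jaccard > 0.9 on
the union of the three id sets (earlier seed kept), sorted by decreasing
gene-set size, and labelled with their sample category.

## Enrichment statistics

Gene-set enrichment uses the upper-tail cumulative hypergeometric
probability $P(X \ge k)$ for an overlap of $k$ annotated genes in a query
of $n$ from a universe of $N$ with $K$ annotated, computed through the
survival function for numerical stability. The enrichment background is
the set of genes present in the expression matrix: enrichment should be
judged against what was measured. Two corrections appear, matching their
distinct uses:

- disease-associated term identification tests every collection term
  against the disease gene list and applies **Bonferroni** correction
  over the terms tested ($p_{\mathrm{adj}} < 0.05$);
- functional homogeneity of a gene set — is it significantly enriched in
  at least one biological process? — uses **Benjamini-Hochberg** FDR
  across all terms ($q < 0.05$).

Terms with fewer than two universe genes are skipped as untestable, and
query genes outside the universe are ignored, so adding foreign
identifiers never changes a result.

## The three objectives

For a comodule with $m$ miRNAs and $n$ genes, a candidate module is a bit
string of length $m + n$ (miRNAs first; 1 = selected) with $m'$ and $n'$
selected on each side. All three objectives are minimized:

- $FP$: for each of the disease-associated terms, the hypergeometric
  upper-tail p-value of the selected gene set's overlap, Bonferroni
  corrected by the number of disease terms; $FP$ is the minimum. An empty
  selection scores 1.
- $FC = \mathrm{cc}_{\mathrm{mod}} + \mathrm{tc}_{\mathrm{mod}}$, where
  $\mathrm{cc}_{\mathrm{mod}}$ is the mean Pearson correlation over all
  selected (miRNA, gene) pairs across the comodule's samples — a
  coefficient contributes only when its p-value (two-sided t transform,
  $n - 2$ df) is below 0.05, else 0 — and $\mathrm{tc}_{\mathrm{mod}}$ is
  the negated mean target coefficient $t_{ij}$, the fraction of
  prediction sources supporting the pair.
- $FF$: the negated mean of the selected members' between-class variances
  $\sum_c (n_c/N)(\mu_c - \mu)^2$ of expression across subtypes, min-max
  normalized to $[0, 1]$ separately over the comodule's miRNAs and over
  its genes. Per-comodule scaling is used because the genetic algorithm
  only ever compares selections within one comodule; if all variances are
  equal the normalization degenerates and all values map to 0.

Comodules with fewer than three samples get no defined correlations; all
pairs are treated as non-significant, so $FC$ reflects targeting alone.
Correlations, p-values, target coefficients and normalized variances are
precomputed once per comodule (`comodule_context`); the batch evaluator
used by the search is contract-tested to agree with direct per-selection
recomputation.

A selection is *feasible* when $FP < 0.05$ and $m' \ge 1, n' \ge 1$;
infeasible selections are never returned.

## The search

`evolve()` runs an elitist non-dominated-sorting loop (binary tournament
on feasibility-first front rank, then crowding distance; uniform
crossover at rate 0.9; per-bit mutation at $1/(m+n)$), hybridized with
two standard mechanisms that matter at small evaluation budgets:

- an unbounded **archive** of every feasible nondominated individual
  encountered; the returned front is the archive's nondominated set at
  the final generation, deduplicated by bit string and capped at
  `max_front_size` (default 50) by crowding distance;
- interleaved **Pareto local search**: the 1-bit-flip and 1-swap
  neighbourhood of each archive member is evaluated exactly once,
  flood-filling front regions connected by small moves; four random
  immigrants per generation keep global exploration alive after the
  population concentrates.

The hybrid exists because plain non-dominated sorting at population 64
reliably finds the bulk of the front but misses isolated, barely feasible
points ($FP$ just under 0.05) several bit flips away from the rest. On
instances with $m + n \le 14$ the front can be checked against
`brute_force_front()`, which enumerates all $2^{m+n}$ selections; the
acceptance suite requires set-level equality of the objective vectors in
at least 19 of 20 random instances. Initialization draws half the
population uniformly and half sparsely (each bit on with probability
0.15), since observed modules are small subsets of their comodules. Runs
are deterministic given `rng_seed`.

One encoding note: the number of selected members is counted over 1-bits,
and 1 means selected. The alternative convention (0 = selected) is
internally inconsistent with counting $m', n'$ over 1-bits, so the
1 = selected reading is adopted throughout.

## Ranking, networks, and active members

Within each category (one per subtype, plus heterogeneous), every module
gets three ranks — ascending $FP$, $FC$, $FF$, ties as mean ranks — and
the final score $S = \alpha R_1 + \beta R_2 + \gamma R_3$ with
$\alpha = \beta = \gamma = 1/3$ by default. Output is sorted by ascending
$S$: rank 1 on every objective is the best conceivable module, so the
smallest weighted rank sum comes first. Ties break by comodule id and bit
string for reproducibility.

A module's regulatory network connects miRNA $i$ to gene $j$ when the
pair shows a significant negative correlation across the comodule's
samples ($c_{ij} < 0$, $p < 0.05$) *and* at least one prediction source
supports the pair ($t_{ij} > 0$). Members with no qualifying edge are
omitted from the exported node sets. Exports: SIF, GraphML (with node
type and edge attributes), and edge-list TSV, all deterministically
ordered. Per-category frequency tables of module membership (top 15
miRNAs, top 50 genes by default) summarize the most active members.

## The synthetic benchmark generator

`generate_synthetic()` builds every input the pipeline reads, with known
ground truth. Expression is mean structure plus iid Gaussian noise
(`noise_sd`, default 0.5): background cells have mean 0; each planted
comodule adds $+$`effect_size` (default 3) to its genes and
$-$`effect_size` to its miRNAs on its samples, scaled per sample by an
amplitude drawn uniformly from $1 \pm 0.3$ and shared by the whole block.
The amplitude serves a purpose: with it, module pairs are negatively
correlated *within* the module's own samples (module activity varies
between samples), not only across the full sample axis, which is what the
network edge rule and the gated correlation objective measure. Its spread
is a compromise — wider spreads push the weakest sample below the
selection threshold and out of the recovered module.

Default dimensions mirror a desk-scale cohort: 2000 genes, 200 miRNAs, 60
samples in 5 subtypes, 3 planted comodules of 20 genes x 5 miRNAs x 6
samples, each drawn inside a single subtype (block-wise labels give the
planted members high between-class variance, exercising $FF$). Planted
sets are disjoint across comodules.

Each comodule carries a functional core (3 miRNAs x 3 genes) whose pairs
are predicted by all 7 emitted target sources, against a background
prediction rate of 0.01 per source. The core's genes sit in one large
disease-associated term (350 of 2000 genes) and one small "tight" term
(20 genes, not disease-associated); the disease gene list is exactly the
union of the large terms. The sizes are chosen so that, under the default
universe, the feasibility boundary of the module search falls exactly at
the full core gene set: a 2-gene overlap gives Bonferroni-corrected
$p \approx 0.09$ (infeasible), the 3-gene core gives $\approx 0.016$
(feasible), and adding any extra gene pushes it back over 0.05. Every
feasible selection therefore carries exactly the core's genes — the
planted core *is* the optimum by construction, which is what makes
top-rank recovery a well-posed test. The miRNA side is intentionally left
free: any subset of core miRNAs attains the same targeting score, so core
recovery is measured on gene sets.

What the generator does **not** emulate: count distributions (data are
Gaussian, not negative binomial), probe-level artifacts, correlated
backgrounds, identifier mapping noise, or incomplete/biased target
databases. Passing recovery tests on this generator demonstrates that the
implementation does what the method promises under the method's own
assumptions — not that the method is robust to everything real data does.

## Numerical and scale choices

- Degenerate guards: constant vectors standardize to zero, yield empty
  threshold selections, and give $(r, p) = (0, 1)$ in correlations;
  `sd = 0` directions terminate a ping-pong run rather than propagate
  NaN.
- Problem sizes in the test suite are chosen to keep the full suite
  around three minutes: recovery tests run 500 seeds per data set across
  20 generator seeds; oracle comparisons use $m + n \le 14$; the
  edge-validity fixture uses 12-sample modules, where the correlation
  test has power ($|r| > 0.576$ at df 10, versus $|r| > 0.811$ at the
  default 6-sample modules — at the default size, planted-module networks
  are typically empty, an honest consequence of testing correlation on
  four degrees of freedom).
- All randomness flows from explicit integer seeds; the pipeline derives
  per-stage seeds from one top-level seed by fixed offsets, and two runs
  with the same configuration produce byte-identical artifacts.

## Known limitations

- Identifier harmonization (probe-to-gene collapsing, miRNA naming
  conventions across prediction databases) is the caller's
  responsibility; identifiers are matched as exact strings.
- The loader leaves expression values untouched; whether to log-transform
  or quantile-normalize beforehand is a data-preparation decision the
  package does not take.
- Thresholds are not swept: one `ppa_config` is one operating point. A
  grid sweep over $(t_G, t_D, t_C)$ with merged, deduplicated results is
  a natural extension.
- Comodule significance is not assessed beyond downstream enrichment; the
  spurious fixed points that random seeds occasionally produce are left
  to the extraction stage, which discards them when their genes overlap
  no disease term.
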