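# mirmodule

Discovery of subtype-specific miRNA–mRNA functional regulatory modules
from matched miRNA and mRNA expression profiles.

In heterogeneous diseases, miRNA–mRNA regulation can differ between
molecular subtypes. `mirmodule` finds the module-level structure behind
that heterogeneity for anyone with paired expression matrices (genes ×
samples and miRNAs × samples, e.g. a multiple-myeloma cohort with
cytogenetic subtypes), miRNA target predictions, Gene Ontology gene sets,
and a disease gene list.

## Method

**Stage 1 — comodule discovery.** An alternating ping-pong
projection-and-threshold iteration over the two matrices finds
*comodules*: triples (gene set, miRNA set, sample set) in which both
feature sets are coherently expressed across exactly those samples. From
a random gene seed ĝ it cycles

    ĉ  = θ_tC(E_C′ ĝ) → d̂ = θ_tD(R_D ĉ) → ĉ̃ = θ_tC(R_C′ d̂) → ĝ = θ_tG(E_G ĉ̃)

where E_G, R_D are feature-standardized, E_C, R_C sample-standardized
copies, and θ_t z-scores its input and keeps items with |z| > t (signed,
unit-normalized). Cycling continues to a verified fixed point. A comodule
whose samples all share one subtype label is subtype-specific.

**Stage 2 — module extraction.** Within each comodule, a constrained
three-objective genetic algorithm (non-dominated sorting with an archive
and interleaved Pareto local search) selects miRNA/mRNA subsets,
minimizing

- **FP** — minimum Bonferroni-corrected hypergeometric enrichment p of
  the selected genes over the disease-associated GO terms,
- **FC = cc_mod + tc_mod** — mean significant Pearson correlation of
  selected pairs across the comodule's samples, plus the negated mean
  target coefficient t_ij (fraction of prediction sources supporting the
  pair),
- **FF** — negated mean normalized between-class variance of the
  selected members' expression across subtypes,

subject to FP < 0.05 and at least one member on each side. Modules are
then ranked within each subtype category by S = (R1 + R2 + R3)/3 over
the three objective ranks, and each module's bipartite regulatory
network connects pairs with significant negative correlation and target
support.

A synthetic-data generator with planted comodules, planted target
relations and planted enriched gene sets makes the whole pipeline
testable offline, with known ground truth.

## Worked example

```r
library(mirmodule)

# synthetic cohort: 2000 genes x 200 miRNAs x 60 samples, 5 subtypes,
# 3 planted comodules with functional cores
sdat <- generate_synthetic(synth_config(rng_seed = 1))
sdat$pe
#> paired_expression: 2000 genes x 200 miRNAs x 60 samples
#> subtypes: subtype1, subtype2, subtype3, subtype4, subtype5

cms <- run_ppa(sdat$pe, ppa_config(n_seeds = 500, rng_seed = 101))
length(cms)
#> [1] 14
cms[[1]]
#> comodule (seed 5): 20 genes, 5 miRNAs, 6 samples [subtype1]

evaluate_recovery(sdat$truth, cms, "comodules")$recall
#> [1] 1

terms <- disease_go_terms(sdat$go, sdat$disease)
terms[, c("term_id", "k", "K", "n", "N", "p_adj")]
#>    term_id   k   K    n    N         p_adj
#> 1 TERM0001 350 350 1050 2000 1.636371e-111
#> 2 TERM0002 350 350 1050 2000 1.636371e-111
#> 3 TERM0003 350 350 1050 2000 1.636371e-111

ctx <- comodule_context(cms[[1]], sdat$pe, sdat$targets,
                        sdat$go$sets[terms$term_id])
front <- evolve(ctx, ga_config(rng_seed = 7))
ranked <- rank_mfrms(front)
ranked[, c("category", "S", "R1", "R2", "R3", "FP", "FC", "FF",
           "m_sel", "n_sel")]
#>   category   S  R1 R2 R3         FP   FC         FF m_sel n_sel
#> 1 subtype1 1.5 1.5  2  1 0.01596451 -0.5 -0.5398808     2     3
#> 2 subtype1 1.5 1.5  1  2 0.01596451 -1.0 -0.5066716     1     3
```

Reading the output: all 14 fixed points include the three planted
comodules (recall 1); the first is the subtype1-specific planted block.
The three planted disease terms are recovered with overwhelming
enrichment. Extraction on the first comodule yields a two-module Pareto
front, both carrying exactly the planted 3-gene functional core
(`FP = 0.016`); the top-ranked module's coherence `FC = -0.5` improves
sharply on the whole comodule's baseline `FC = -0.105` (from
`evaluate_selection` on the all-ones selection). The `S` tie between the
two front members is broken deterministically.

The one-call version of all stages, plus network and active-member
exports and a manifest:

```r
generate_synthetic(synth_config(rng_seed = 1), dir = "demo")
run_pipeline("demo/E.tsv", "demo/R.tsv", "demo/annotations.tsv",
             list.files("demo/targets", full.names = TRUE),
             "demo/go_bp.gmt", "demo/disease_genes.txt",
             out_dir = "demo/out", pipeline_config(seed = 1))
```

A thin command-line wrapper with `simulate`, `ppa`, `disease-go` and
`run` subcommands is installed at
`system.file("cli", "mirmodule", package = "mirmodule")`.

## Documentation

The methods vignette (`vignettes/mirna-mrna-modules.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, the synthetic generator's design and what it does and does not
emulate, numerical edge cases, and known limitations.
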