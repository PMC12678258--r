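# resilmine

Literature-based mining of community-resilience indicators for public
health emergencies.

Assessment frameworks for community resilience — the indicators a city or
district would score itself on before the next epidemic — are usually
drafted by committees. `resilmine` implements the data-driven route for
researchers in public-health informatics and disaster science: start from
a corpus of research articles, extract the phrase-level indicators the
literature itself keeps using, and organise them into a validated,
hierarchical indicator system.

The pipeline:

1. **Contrastive text representations.** Documents are encoded and trained
   with the InfoNCE objective over in-batch negatives,

   `L = -log [ exp(sim(f(d), f(d+))/τ) / Σ_j exp(sim(f(d), f(d_j))/τ) ]`,

   with cosine similarity `sim`, temperature `τ = 0.07`, and augmented
   positives `d+` (15% random masking, sentence reordering, synonym
   replacement). A deterministic desk-scale encoder is the default; a
   trainable token-embedding encoder implements the same contract.
2. **A four-phase screening funnel.** All 1–6-grams are scored
   (exact frequencies, normalized TF-IDF, relevance to the corpus
   centroid, a specificity index) and filtered: frequency ≥ 5 →
   frequency ≥ 7 and spread over ≥ 10 articles → relevance ≥ 0.65 →
   quality filters (length, genericity, nested-phrase absorption,
   near-duplicate merging, optional reviewer consensus), with a
   threshold sensitivity analysis.
3. **Poincaré-ball embedding.** Indicators are embedded in the open unit
   ball, `d(x,y) = acosh(1 + 2‖x−y‖² / ((1−‖x‖²)(1−‖y‖²)))`, and hierarchy
   preservation is scored by the Hierarchical Fidelity Score — the
   fraction of parent→child edges whose parent lies closer to the origin —
   against a Euclidean baseline fitted with the same stress objective.
4. **Relation matrix under a DAG constraint.** Multi-head self-attention
   (8 heads, `softmax(QKᵀ/√d_k)V`) over the indicator embeddings yields a
   relation matrix `C`, constrained acyclic through the trace-exponential
   penalty `h(C) = tr(e^{C∘C}) − n` and symmetrized as `S = (C + Cᵀ)/2`.
5. **Tangent-space clustering.** The origin log map carries ball points to
   Euclidean space; seeded k-means with farthest-point initialization is
   scanned over k = 3..7 and the winner elected by silhouette,
   Davies–Bouldin, and NPMI topic coherence.
6. **Validation statistics and framework comparison.** Cohen's kappa
   (pairwise and panel mean), the 5-point Likert retention rule
   (≥ 4 approvals and mean ≥ 4), consensus gating at 2/3, flagging of
   indicators whose group means diverge > 20% across NPI-stringency
   strata, and overlap/novelty counts against the packaged
   indicator–framework membership table.

A seeded synthetic-corpus generator (planted phrases with exact
frequencies, a planted topic hierarchy, Zipf noise, simulated rater
panels) makes the whole pipeline testable end to end without any external
corpus.

## Worked example

```r
library(resilmine)

report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> <pipeline_report> corpus N = 230
#>   funnel: pool=28981 phase1=664 phase2=439 phase3=435 phase4=43
#>   HFS hyperbolic 0.395 vs euclidean 0.342; distortion 0.284 vs 0.287
#>   best k = 3
#>   panel kappa 0.663, mean expert score 4.12
```

Reading the numbers: from a 230-document synthetic corpus, 28,981 raw
n-gram candidates shrink to 664 by pool frequency, 439 by frequency and
source breadth, 435 by semantic relevance, and 43 final indicators after
the quality filters — including all 39 planted indicators, with 4
noise survivors. The ball embedding preserves the planted hierarchy better
than the Euclidean baseline fitted from the same inputs (HFS 0.395 vs
0.342) at slightly lower distortion, the cluster scan elects its k by
three-metric vote, and the simulated 3-expert panel agrees at kappa 0.66
with a mean 15-expert importance score of 4.12/5.

Framework comparison is literal column counting over the packaged
membership table:

```r
overlap_stats(load_membership())$frameworks
#>   framework count  fraction
#> 1       cri    21 0.5384615
#> 2   peoples    21 0.5384615
#> 3    sendai    17 0.4358974
```

Individual stages are plain functions — for example:

```r
d  <- poincare_distance(c(0, 0), c(0.5, 0))   # 2*atanh(0.5) = ln 3
p  <- dag_penalty(matrix(c(0, 1, 1, 0), 2))   # 2*cosh(1) - 2: a 2-cycle
C2 <- enforce_dag(matrix(c(0, 1, 1, 0), 2))   # penalty driven below 1e-8
```

A command-line wrapper with verbs `generate`, `extract`, `embed`,
`relate`, `cluster`, `validate`, `compare`, `run` ships under
`inst/cli/resilmine.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "resilmine.R", package = "resilmine"))')" \
  run --seed 1 --out out/
```

## Design notes

The methods vignette (`vignettes/mining-indicators.Rmd`) documents the
model and every open design choice: the specificity-index definition, the
anisotropic default encoder, the stress objective with Riemannian
preconditioning and MDS initialization, the printed (non-standard) origin
log map, the DAG-enforcement tie-breaks, the NPMI coherence definition,
and what passing tests on synthetic corpora do and do not establish about
real literature.
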