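---
title: "Mining community-resilience indicators from literature: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining community-resilience indicators: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilmine)
```

## The problem

Assessment frameworks for community resilience in public health emergencies
are usually assembled by expert committees. `resilmine` implements the
alternative: mine the indicators from the research literature itself. A
corpus of articles is screened into a compact set of phrase-level
indicators ("telemedicine infrastructure", "mutual aid networks", ...),
the indicators are embedded in hyperbolic space so that their hierarchy is
legible, pairwise relations are estimated under an acyclicity constraint,
and the set is organised into dimensions by clustering — with expert-panel
statistics and comparisons against established frameworks closing the
loop.

The pipeline has seven computational stages, each usable on its own:

1. corpus ingestion and preprocessing (`read_corpus()`, `preprocess()`);
2. contrastive text representations (`augment()`, `info_nce_loss()`,
   `train_contrastive()`);
3. candidate-phrase extraction and the four-phase screening funnel
   (`extract_ngrams()`, `screen()`, `sensitivity_analysis()`);
4. Poincaré-ball embedding with a Euclidean baseline (`embed_ball()`,
   `hfs()`, `compare_spaces()`);
5. a multi-head self-attention relation matrix under a
   trace-exponential acyclicity constraint (`mhsa_relation_matrix()`,
   `dag_penalty()`, `enforce_dag()`);
6. tangent-space clustering with three-metric model selection
   (`tangent_project()`, `select_k()`);
7. validation statistics and framework-overlap accounting
   (`cohen_kappa()`, `likert_retention()`, `overlap_stats()`).

Because no reference corpus ships with the package, a seeded synthetic
generator (`generate_corpus()`, `generate_raters()`) produces corpora with
exactly known phrase statistics, a planted topic hierarchy, and simulated
rater panels. Every stage is tested against that ground truth.

## Contrastive representations

Documents are represented by an encoder `f` and trained with the InfoNCE
objective: for anchor `d` with augmented positive `d+` and in-batch
negatives `n_j`,

    L = -log  exp(sim(f(d), f(d+)) / tau)
              ------------------------------------------
              exp(sim(f(d), f(d+)) / tau) + sum_j exp(sim(f(d), f(n_j)) / tau)

with cosine similarity `sim` and temperature `tau = 0.07`. Positives are
built by random masking (exactly `round(0.15 n)` tokens replaced by
`[mask]`, sampled without replacement), sentence reordering, and synonym
replacement from a packaged lexicon (one attempt per eligible token at
probability 0.1 — the replacement rate is not pinned down elsewhere, so it
is a package choice). The training loop follows the standard fine-tuning
schedule: batch 16 with 2-step gradient accumulation, peak learning rate
2e-5 with linear warmup over 10% of steps then linear decay to zero,
gradient-norm clipping at 1.0, 3 epochs, a 15% validation split
(round-half-up) checked every 50 steps, early stopping after 5 checks
without improvement in mean reciprocal rank (MRR), and the best-MRR
checkpoint returned.

Two encoders implement one contract (`encode()`):

* `hash_encoder()` — the desk-scale default. Every token type gets a fixed
  direction keyed by a stable string hash and the encoder seed; a text is
  the mean of its token directions. No training, fully deterministic
  across sessions.
* `embedding_encoder()` — a trainable token-embedding model (text = mean
  of learned token vectors) optimised by `train_contrastive()` with exact
  analytic gradients of the InfoNCE objective through the cosine.

A full transformer fine-tune is deliberately out of scope; the masked
language-modelling term sometimes combined with contrastive objectives is
likewise omitted (no weighting between the two is available to adopt, and
the contrastive term alone serves the pipeline).

**Anisotropy.** Transformer embedding spaces are strongly anisotropic:
cosines between arbitrary in-domain texts sit well above zero. Absolute
cosine thresholds — such as the 0.65 relevance floor below — are only
meaningful in such a geometry. The hash encoder therefore mixes a shared
component into every token direction (`anisotropy = 0.3` of the variance),
reproducing that regime. Without it, random-direction bag-of-token
cosines hover near zero and an absolute threshold of 0.65 on the rescaled
cosine would reject everything.

**Ranking metrics.** Validation ranks each document's augmented positive
against all other positives. Ties break pessimistically (a tied candidate
counts as ranked above the positive), so reported accuracy and MRR are
conservative. Embedding coherence is the mean cosine over supplied
same-topic pairs and is reported as `NA` when no pairs exist; in synthetic
runs the generator's topics supply the pairs.

## The screening funnel

Candidates are all contiguous 1–6-grams (within sentences) with exact
total and document frequencies. Scores:

* normalized TF-IDF: `total_freq * ln(N / doc_freq)`, scaled by the pool
  maximum into [0, 1];
* relevance: `(cos(phrase, centroid) + 1) / 2` against the mean document
  embedding ("semantic coherence" and "semantic relevance" share this one
  implementation — the two names describe the same cosine-based quantity);
* specificity: mean token IDF over the phrase's tokens divided by the
  corpus's 95th-percentile token IDF (type-7 quantile), clipped to [0, 1];
  unseen tokens count at the maximal IDF `ln N`. No formula for the
  "specificity index" is available to adopt, so this normalized-IDF
  reading — generic terms score near 0, rare technical terms near 1 — is
  the package's definition. Note it is corpus-size dependent: the same
  document spread sits lower on the IDF scale in a smaller corpus, so
  scaled-down corpora warrant a proportionally scaled floor.

The funnel (`screen()`):

1. **Phase 1** — pool admission at total frequency >= 5 (optionally the
   upper quartile Q3 of the pool frequency distribution, when that is
   stricter; both rules ship because both appear in practice, and
   precedence is configurable);
2. **Phase 2** — total frequency >= 7 *and* document spread >= 10;
3. **Phase 3** — relevance >= 0.65;
4. **Phase 4** — quality filters: drop phrases longer than 6 words and
   generic single words; apply the 0.45 TF-IDF and 0.50 specificity
   floors (individually toggleable); drop blocklisted (ambiguous)
   phrases — ambiguity detection is a curated list, not a model; absorb
   nested phrases (a candidate contained in a longer candidate is dropped
   when its frequency outside that phrase falls below the pool floor —
   the C-value-style rule that keeps "triage surge" and discards the
   "triage" and "surge" fragments it explains); merge near-duplicates at
   embedding cosine >= 0.9 keeping the higher-relevance member; and gate
   on reviewer consensus (>= 2/3 approval) when a ratings table is
   supplied — otherwise that manual stage is skipped.

Phase counts are non-increasing, each phase's survivors are a subset of
the previous phase's, and the whole funnel is invariant to pool row order
(merging walks a canonical order: descending relevance, then
alphabetical). `sensitivity_analysis()` re-runs Phases 3–4 across a
threshold grid (default 0.55–0.75) and reports retained counts and the
overlap with a reference set; at the configured default threshold it
reproduces the main funnel exactly.

One boundary case is worth stating plainly: the consensus gate passes a
fraction exactly equal to 2/3 and anything above it — including 0.67,
which is numerically greater than 2/3.

## Hyperbolic embedding

Points live in the open unit ball with

    d(x, y) = acosh(1 + 2 ||x - y||^2 / ((1 - ||x||^2)(1 - ||y||^2))),

curvature fixed at -1. Hierarchy preservation is scored by the
Hierarchical Fidelity Score: the fraction of parent -> child edges whose
parent is strictly closer to the origin than its child (Euclidean norm
plays that role for the baseline).

**Fitting.** No fitting objective is pinned down by the method
description, so the package minimises weighted metric stress
`sum w_ij (d(x_i, x_j) - delta_ij)^2` by projected gradient descent:
backtracking line search (stress never increases over accepted steps),
re-clipping into the ball at margin 1e-5 after every step, and — when a
hierarchy is supplied — a hinge margin term pushing each parent to smaller
radius than its children (weight 1, on by default; `compare_spaces()`
turns it off in both spaces so that geometry alone drives the
hyperbolic-vs-Euclidean comparison).

Two numerical choices matter and were settled by experiment:

* **Riemannian preconditioning.** The Euclidean stress gradient explodes
  near the boundary; scaling it by the inverse Poincaré metric
  `(1 - ||x||^2)^2 / 4` keeps step sizes comparable between centre and
  boundary. Without it the optimizer stalls for targets that need
  near-boundary placements.
* **Classical-MDS initialization.** Tiny random initializations leave the
  ball fit in poor local minima (on a 3-level tree: stress 5591 against
  728, and distortion *worse* than the Euclidean baseline — the opposite
  of what hyperbolic geometry should deliver). The packaged initializer
  takes the classical MDS configuration, maps radii by `r -> tanh(r/2)`
  (the Euclidean norm of a ball point at hyperbolic distance `r` from the
  origin), adds seeded Gaussian jitter (sd 0.01), and falls back to a
  small random ball when MDS degenerates. With it, ball embeddings of
  tree metrics dominate the Euclidean baseline on both fidelity and
  distortion, as they should.

The dissimilarity fed to the embedding is `1 - cosine` of encoder phrase
embeddings (floored at 1e-6 off-diagonal so relative distortion is
defined). `distortion_rate()` is scale-aligned mean relative distortion:
embedded distances are first scaled by the least-squares scalar
`sum(d_emb d_ref) / sum(d_emb^2)`, then `mean |s d_emb - d_ref| / d_ref`
is reported — the printed distortion numbers elsewhere come with no
formula, so this scale-invariant definition is the package's.

**The origin log map is implemented exactly as printed**:
`log_o(x) = 2 x / (1 - ||x||^2)`. The standard Poincaré log map carries an
additional `atanh(||x||)/||x||` factor; the package follows the printed
radial-scaling form deliberately and notes the discrepancy here rather
than silently "correcting" it. The map is radial and strictly monotone in
`||x||`, so cluster geometry near the origin is unaffected in practice.

## Relation matrix and the acyclicity constraint

Indicator embeddings (tangent-projected) feed a standard multi-head
self-attention: per head, `Q = H W_Q`, `K = H W_K`, `V = H W_V`, weights
`softmax(QK'/sqrt(d_k))` row-wise, outputs concatenated over 8 heads
(`d_k = 64`) and linearly projected to an `n x n` relation matrix `C`. No
training objective for the projections is available to adopt; they are
seeded orthogonal matrices by default, making the relation matrix a
deterministic function of the embeddings — the output-projection reading
of "concatenated and linearly transformed" is one consistent
interpretation and is recorded as such.

Acyclicity is enforced through `h(C) = tr(e^{C o C}) - n` (Hadamard
square; zero exactly when the weighted graph is acyclic). The matrix
exponential is a scaling-and-squaring [6/6] Padé implementation, accurate
to ~1e-10 on entries in [-2, 2] and cross-checked against an independent
implementation in the tests. `enforce_dag()` minimises
`||X - C||_F^2 + lambda h(X)` by gradient descent
(`grad h = (e^{X o X})' o 2X`) with `lambda` doubling whenever the inner
iteration converges above tolerance (1e-8). Three deterministic
refinements handle the degenerate cases:

* exact two-cycles (`X_ij = X_ji`) are saddle points of the symmetric
  dynamics, so an infinitesimal tie-break (lower triangle scaled by
  `1 - 1e-6`) is applied first;
* entries driven below 1e-3 — optimisation residue of broken cycles — are
  snapped to exact zero;
* any cycle remaining in the `|x| > 1e-6` thresholded graph is broken by
  zeroing its smallest-magnitude edge.

Both cleanups shrink `C o C` entry-wise, so they can only decrease the
trace-exponential penalty; after them the thresholded graph always passes
a topological-sort check. An already-acyclic matrix returns unchanged.

## Clustering and model selection

Ball embeddings are projected to the origin tangent space (k-means assumes
Euclidean geometry) and clustered by seeded Lloyd iterations with
farthest-point initialization, 10 restarts (best within-cluster sum of
squares wins), and a documented empty-cluster rule: an emptied centroid is
re-seeded at the point farthest from its assigned centroid. `k` is scanned
over 3–7 and elected by majority vote across three metrics — silhouette
(max), Davies–Bouldin (min), and NPMI topic coherence (max) — with ties
broken toward the smaller `k`. The vote rule matters only when the metrics
disagree; on clean planted structure all three point at the same `k`.

Coherence is the package's definition (the score is named elsewhere but
not defined): add-one-smoothed normalized pointwise mutual information of
document co-occurrence over within-cluster phrase pairs,
`p(.) = (df + 1)/(N + 1)`, averaged over clusters that contain at least
one pair. Phrases that always co-occur score exactly 1; phrases that
never co-occur score negative. Whether such a score should be computed on
the analysis corpus or an external one is genuinely open; the package
uses the analysis corpus, which is what the synthetic ground truth can
verify. Degenerate conventions: singleton silhouette contributions are 0,
as is the all-points-identical case; Davies–Bouldin raises an error on
coincident centroids rather than dividing by zero.

## Validation statistics

* `cohen_kappa()` — `(p_o - p_e) / (1 - p_e)` with chance agreement from
  marginal frequencies; two constant, identical raters yield 1 by
  convention (logged). Multi-rater panels are summarised as the mean of
  all pairwise kappas — the named statistic is Cohen's, so the package
  does not substitute a multi-rater generalization.
* `likert_retention()` — retained iff >= 4 raters score >= 4 *and* the
  item mean is >= 4.0; the two sub-rules are individually toggleable and
  the conjunction is the default reading.
* `npi_variance_flag()` — "variance greater than 20% between groups" is
  operationalized as the relative range of group means,
  `(max - min) / overall mean > 0.20`, toggleable to coefficient of
  variation; flags never remove an item from the retained set.

## The synthetic generator: what it does and does not show

`generate_corpus()` plants each phrase as a contiguous token run with
*exactly* its target total frequency and document spread, assigns every
document a topic (round-robin) so documents are topically coherent, and
fills the rest with Zipf(s = 1.1) noise over a made-up vocabulary. The
Zipf head is truncated (rank offset 50) because the generator emulates an
*already preprocessed* corpus: the ultra-frequent head of raw text is
stop words, which `preprocess()` removes from real input. One global seed
fans out to all streams, so fixtures are byte-reproducible.
`generate_raters()` draws latent 1–5 scores skewed toward 4–5 (mean 4.35,
emulating panels scoring pre-vetted indicators); each rater copies the
latent score with the agreement probability or draws uniformly.

The default study-scale conditions (`pipeline_config()`): 230 documents,
39 planted two-word indicators in 4 topics (10/10/10/9) with total
frequencies 20–29 and document spreads 10–11 — clearing the funnel's
frequency, breadth, and score thresholds the way real indicators would —
plus 25 low-frequency decoys the funnel must reject, a phrase-level
hierarchy (topic heads parent their topic members), 2-dimensional
embeddings, and panels of 3, 5, and 15 raters at agreement 0.85 with a
strict/moderate/voluntary NPI stratification.

Passing tests on this generator demonstrate that the *mechanics* are
right: counts are exact, filters match brute-force recomputation,
geometry identities hold, planted structure is recovered. They do not
show that the thresholds transfer to real literature: synthetic noise has
no off-domain documents (everything is "relevant"), no morphology or
synonymy beyond the packaged lexicon, no realistic prose, and its
frequency scale is far below a real corpus. On real input the relevance
gate carries discrimination that the synthetic world cannot express, and
the TF-IDF/specificity floors would need recalibration against the
corpus at hand.

Test problem sizes are chosen for depth per second: corpora of 40–230
documents, embeddings of up to 40 points, 400–2000 optimizer iterations,
exhaustive enumeration only where the space is small (all binary
matrices up to 4x4 for the acyclicity check), and 10-seed replication for
the directional hyperbolic-vs-Euclidean claim.

## Known limitations

* The default encoder is a deterministic stand-in with an explicit
  anisotropy knob; it captures frequency and co-occurrence structure, not
  meaning. Plug in a stronger encoder via the `encode()` contract for
  real corpora.
* The relation matrix is only as good as the embeddings and the seeded
  projections; with the default untrained projections it is a structured
  readout, not a fitted model.
* `enforce_dag()` returns *a* nearby acyclic matrix, not the projection
  onto the acyclic set; the cycle-breaking tie-break (upper triangle
  wins) is a convention.
* Framework-overlap statistics are literal column counts over the packaged
  membership table; where prose claims and that table disagree, the table
  wins and the disagreement is left visible rather than reconciled.
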