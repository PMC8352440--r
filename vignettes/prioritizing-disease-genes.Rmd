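---
title: "Prioritizing disease genes with shortest-path features and a least-squares SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes with shortest-path features and a least-squares SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsvm)
```

## The problem and the model

Most computational disease-gene discovery rests on one hypothesis: similar
diseases are related to similar genes. Given a target disease, `pathsvm`
collects the known genes of every disease similar to the target as the
candidate pool, describes each candidate by where it sits in a functional
gene network relative to each similar disease's gene set, and trains a
classifier to separate the target's known genes from the rest of the pool.
High-scoring unlabeled candidates are nominated as putative novel genes of
the target disease.

Three inputs drive the pipeline, all plain TSV:

* a sparse disease–disease similarity table (an absent pair means
  "unknown", treated as similarity 0);
* a disease–gene association table in the style of a DisGeNET export;
* a weighted undirected gene network in the style of a HumanNet edge list,
  where the weight of an edge is an interaction strength.

The feature vector of a candidate gene has one dimension per similar
disease: the length of the shortest weighted path (Dijkstra) from the gene
to the nearest of that disease's genes, or a fixed membership value when
the gene itself belongs to the disease. Columns are z-scored
(`(F - mean(F)) / sd(F)`, sample standard deviation) before classification.

The classifier is a least-squares SVM with Gaussian RBF kernel
$K(x, y) = \exp(-\lVert x-y\rVert^2 / 2\sigma^2)$. The structural risk
$\gamma \sum_i \varepsilon_i^2 + \tfrac12 \lVert w \rVert^2$ is minimized
via Lagrange multipliers; the stationarity conditions eliminate the primal
weights and reduce training to a single symmetric linear system

$$\textstyle\sum_i a_i = 0, \qquad \Omega a + \frac{a}{2\gamma} + b\,\mathbf 1 = y,$$

with $\Omega_{ij} = K(x_i, x_j)$, dual coefficients $a$, bias $b$ and
labels $y_i \in \{\pm 1\}$. The conditions also give
$a_i = 2\gamma\,\varepsilon_i$, tying every coefficient to its training
residual; `summary()` on a fit reports the residuals of both identities,
and the test suite checks the fit against two independent references (an
eigendecomposition/Schur solve of the same conditions, and a direct BFGS
minimization of the objective in the kernel span). The decision value
$f(x) = \sum_j a_j K(x_j, x) + b$ is a ranking score, not a calibrated
probability.

Evaluation is k-fold cross-validation with held-out decision scores pooled
into a single ROC and PR curve. The final model is trained on all known
positives plus an equal-sized random sample of unlabeled candidates
("negatives" in the positive-unlabeled sense), and every remaining
candidate is ranked by its decision score.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_similarity` | 0 | similarity threshold for "similar" diseases; any recorded positive similarity qualifies |
| `transform` | `"reciprocal"` | edge length = 1/strength (see below) |
| `membership_value` | 0 | feature value when a gene belongs to the disease (see below) |
| `gamma` | 1 | weight on the squared training error; larger fits tighter |
| `sigma` | median heuristic | RBF width; median pairwise distance of the training rows |
| `k` | 10 | cross-validation folds |
| `threshold` | 0 | nomination cut on the decision score (the class boundary) |

Neither `gamma` nor `sigma` has a published reference value for this
method, so the package uses the conventional neutral defaults above; both
are plain arguments everywhere they appear.

### Edge lengths: why the default inverts the weight

A shortest-path algorithm sums edge *lengths*, but functional-network
weights are interaction *strengths*: higher means closer. Using the stated
weight directly as a length (the `identity` transform, which is the literal
reading of the source convention) makes strongly interacting genes *far*
apart, inverting the guilt-by-association signal. The package therefore
defaults to `reciprocal` (length = 1/strength) and keeps `identity`,
`neg_log` and `one_minus` available. On the synthetic benchmark this
choice is measurable: the planted module structure is recovered markedly
better under `reciprocal` than under `identity` (the acceptance script
reports the cross-validated AUC at the defaults).

### Membership value: why the default is 0

When a candidate gene is itself one of a disease's known genes, its
distance to that disease's gene set is literally zero — the set contains
the gene, and the shortest-path source label is $d = 0$. An alternative
convention reads a member's feature as a full-strength interaction value
of 1. The two conflict: under either length transform, 1 is *larger* than
many genuine path lengths, so members would look farther than
non-members. The package defaults to `membership_value = 0` for internal
consistency and offers the value-1 convention as an argument.

### The target's own dimension is excluded

A feature column for the target disease itself would equal the membership
value exactly for every positive — the label written into the features.
`build_feature_matrix()` therefore drops the target from the dimension
list.

## The synthetic benchmark: what it emulates, what it does not

`generate_benchmark()` plants a fully known ground truth so the whole
pipeline can be tested without external databases:

* a planted-partition network — 4 modules of 50 genes by default, edge
  probability 0.3 within and 0.02 between modules, weights uniform on
  (0.1, 1), a typical confidence-score range;
* 8 diseases of 25 genes, each anchored to a module and drawing 90% of its
  genes from it (10% "leak" elsewhere), so same-module diseases overlap —
  the statistical signature of "similar diseases share genes";
* disease similarity = Jaccard overlap of the full gene sets, a monotone
  stand-in for any external similarity score. It is computed *before* the
  holdout below: similarity emulates an external knowledge source, and
  computing it after hiding target genes would erode exactly the disease
  links that make hidden genes discoverable;
* 20% of the target's genes are hidden from the emitted associations and
  recorded as ground truth, emulating not-yet-discovered disease genes.
  Hidden genes are drawn preferentially from target genes that some
  similar disease also carries, because a "novel" gene in this method is
  by definition one reachable through a similar disease — hiding an
  unreachable gene would measure candidate coverage, not ranking quality.

A rejected draw (largest component under 90% of genes; with
`p_between = 0`, per module) is retried with the seed incremented, at most
ten times, rather than patched by adding edges.

The generator does **not** emulate heavy-tailed degree distributions,
evidence-weighted associations, disease subtypes or identifier noise. A
pipeline that recovers the planted structure is demonstrably correct *as
machinery*; real-data performance still depends on the quality of the
similarity scores and the network, which are inputs here.

### What the benchmark can and cannot attain

Two contamination channels are built into the default conditions and cap
every classifier, including an oracle that knows the planted modules: ~8%
of the target's genes lie outside its module (leak), and the balanced
"negative" sample drawn from the candidate pool contains hidden
module-mates of the positives (the positive-unlabeled setting). The
acceptance script reports the pooled cross-validated AUC alongside a
label-shuffled null and the held-out recovery so these ceilings are
visible rather than hidden; at desk scale (40 labeled genes) the shuffled
null also shows the well-known downward bias of pooled cross-validation
scores under per-fold class imbalance. Recovery is measured among held-out
genes that appear in the ranking: a held-out gene that happens to be drawn
into the negative sample is labeled, hence unrankable, by construction.

## Numerical choices

* **Dijkstra ties** among equally distant frontier genes settle in
  lexicographic (C-collation) id order, making distances and predecessor
  trees bit-identical across runs and platforms.
* **Unreachable entries** impute per column as 1.5 times the largest
  finite value in that column — "farther than anything observed" — before
  z-scoring; a column with no finite value imputes 0. Infinities would
  destroy the z-scores, and a global constant would reorder columns with
  different scales.
* **Zero-variance columns** normalize to all zeros rather than NaN.
* **The KKT system** is solved densely with LAPACK; a singular system is
  an error (with a hint), never silently jittered.
* **AUC** uses the Mann–Whitney rank formula with tie-aware ROC vertices;
  **AUPR** uses step-wise average precision, not trapezoids, which
  overestimate PR area.
* **Folds, negative draws and the generator** derive from explicit integer
  seeds via an RNG-state-preserving wrapper, so library calls never
  disturb the caller's random stream and identical seeds give
  byte-identical output files.
* Problem sizes throughout the tests and the acceptance script — a
  200-gene network, 8 diseases, 40 labeled genes, five replicate seeds —
  are chosen so the planted effects are comfortably detectable while a
  full run stays in the seconds range.

## A worked run

```{r example}
bench <- generate_benchmark(benchmark_config(seed = 7))
bench
res <- suppressWarnings(
  run_pipeline(bench$network, bench$associations, bench$similarities,
               bench$target_disease, seed = 7))
res$cv
head(res$ranking$entries)
# how many hidden target genes surface in the top fifth of the ranking?
unl <- res$ranking$entries
inside <- intersect(bench$heldout_targets, unl$gene)
mean(unl$rank[match(inside, unl$gene)] <= ceiling(0.2 * nrow(unl)))
```

## Limitations

* Similarity computation is out of scope: the package consumes similarity
  scores, it does not produce them, and no identifier mapping is
  attempted.
* The decision score is uncalibrated; the default nomination threshold 0
  is the class boundary, not a controlled error rate. The
  `nomination_frequency()` helper quantifies stability under negative
  re-sampling instead.
* "Negatives" are unlabeled candidates; hidden positives among them bias
  both training and the apparent error rates — inherent to the
  positive-unlabeled setting, not fixable by the classifier.
* The dense KKT solve is cubic in the number of labeled genes; it is meant
  for the thousands, not millions.
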