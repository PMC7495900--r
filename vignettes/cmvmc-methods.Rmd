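---
title: "Consensus multi-view gene selection: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus multi-view gene selection: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Expression matrices carry thousands of genes, most of them irrelevant or
redundant for telling tissue samples apart. Unsupervised gene selection
replaces the full matrix with a small panel of representative genes before
any sample-level analysis. cmvmc does this by clustering *genes* under two
complementary notions of similarity and keeping one medoid gene per
consensus cluster:

* **View 1 — co-expression.** `S1[i, j] = 1 - d(g_i, g_j) / d_max`, the
  complement of the Euclidean distance between the two genes' expression
  profiles, scaled by the largest pairwise distance so the entries land in
  [0, 1]. (The unscaled form `1 - d` is available via `normalize = "none"`;
  it is the literal textbook definition but is unbounded below, so the
  scaled form is the default — the similarity-view contract requires
  [0, 1].)
* **View 2 — function.** The mean of a Gene Ontology term-set similarity
  and a protein-interaction-network similarity,
  `S2[i, j] = (GO(i, j) + PPI(i, j)) / 2`. Both measures are pluggable
  callables with a [0, 1] contract; the shipped defaults are
  best-match-average Jaccard similarity over self-inclusive ancestor term
  sets (`go_jaccard_bma()`) and edge confidence for interacting pairs with
  neighborhood Jaccard otherwise (`ppi_confidence_jaccard()`). Users with a
  preferred semantic-similarity implementation pass their own callables.

A gene panel supported by both views is more trustworthy than one supported
by either alone; genes that agree only in one view (pure co-expression
artifacts, or annotated modules with no expression coherence) should not
survive selection.

## Candidate solutions and objectives

A candidate ("parent") solution encodes three medoid strings over the
aligned gene index:

* string 1 — K medoid genes for view 1,
* string 2 — K medoid genes for view 2 (same K, independently chosen genes),
* string 3 — the consensus, recomputed from the other two at every
  evaluation and never perturbed directly.

K is bounded by `[2, floor(sqrt(n))]`, the usual heuristic ceiling for an
unknown cluster count. Every non-medoid gene joins its most similar medoid
(ties to the earliest string position), giving one partition per view.

Three objectives are optimized simultaneously:

* `XB1`, `XB2` — the Xie–Beni validity index of each view's partition,
  adapted to crisp medoid clustering with dissimilarity `1 - S`:
  `XB = sum_k sum_{x in C_k} d(x, m_k)^2 / (n * min_{k != l} d(m_k, m_l)^2)`,
  minimized. Coincident medoids return an `Inf` sentinel so degenerate
  strings lose every comparison they can lose.
* `AI` — the agreement index between the two view partitions, maximized.
  Both partitions are expanded into binary co-membership matrices (unit
  diagonal); with `AG` the number of positions (of n²) where the matrices
  agree, `AI = (AG + 1) / (n² - AG + 1)`. The +1 terms avoid division by
  zero; the index spans `[1/(n²+1), n²+1]` and is maximal exactly when the
  two partitions induce the same co-membership relation.

## The annealer

The optimizer is archived multi-objective simulated annealing: a single
solution chain plus a bounded archive of mutually non-dominated solutions.
Moves that dominate or are non-dominated against the current solution are
taken; moves dominated by the current solution and/or archive members are
taken with probability `1 / (1 + exp(dom_avg / T))`, where `dom_avg` is the
mean "amount of domination" — the product over differing objectives of the
normalized absolute difference, with ranges tracked as running min/max over
the run. The temperature follows a geometric schedule.

Defaults (`amosa_config()`): `tmax = 100`, `tmin = 1e-4`, `alpha = 0.9`
(132 temperature levels), 50 moves per level, soft/hard archive limits
40/20, 10 random initial solutions. These magnitudes follow common archived
simulated-annealing practice; every one of them is exposed in the
configuration. When the archive exceeds its soft limit — and once more at
the end of the run — it is clustered down to the hard limit by
single-linkage agglomeration of objective vectors, keeping the member
nearest each cluster centroid (ties by insertion order). A newcomer whose
objective vector exactly equals a member's is not inserted: the archive
keeps one representative per point of the front, which matters downstream
because the ensemble counts votes per archive member.

Three perturbation operators are drawn uniformly: replace one medoid in one
randomly chosen string; add a random gene as a new medoid to both strings;
delete a random medoid from both strings. Add/delete move the solution's K
in lock-step across the two strings, keeping the per-view partitions
comparable; replacement acts on a single string so that one view's
clustering can be refined without disturbing the other — with both strings
forced to move at once the annealer provably cannot approach compromise
solutions, because every improving move in one view is coupled to a random
change in the other. Operators that would push K out of bounds are
re-drawn.

## Consensus and ensemble

String 3 is built by overlap matching: the K×K contingency table of the two
view partitions is matched greedily by descending overlap (ties to the
lower index pair, each cluster used at most once, stopping at zero
overlap). The genes common to a matched pair form a consensus core whose
medoid is the most central common gene under the combined similarity
`(S1 + S2)/2`; all other genes join the core with the highest mean combined
similarity. Cores are held fixed during this placement step — scores
against a growing cluster would depend on placement order. If fewer than
two pairs match, the partition of the string with the better Xie–Beni index
is copied, so every solution stays evaluable.

After annealing, the consensus partitions of all archive members are
ensembled by pairwise majority voting: the co-clustering vote fraction of
every gene pair is accumulated, and genes agglomerate by average linkage
while the mean vote between groups strictly exceeds the threshold (default
0.5, a strict majority). Groups of two or more genes become final cores;
leftover genes are placed by maximum mean combined similarity; degenerate
votes (fewer than two cores) fall back to the single archived partition
with the best mean Xie–Beni across views. Average-linkage merging rather
than transitive closure of the pairwise-majority graph is deliberate: with
many correlated archive members a single borderline pair (say a 0.55 vote)
would otherwise chain two groups together even when their genes disagree
in nearly every solution. Average linkage honors each individual majority
where it is consistent and resolves conflicting majorities conservatively,
which is the standard evidence-accumulation treatment of consensus
clustering.

One medoid per final cluster — the member with the highest mean combined
similarity to its cluster mates — becomes the selected gene set, and the
expression matrix is reduced to those rows.

## Downstream scoring

`cluster_samples()` clusters the samples of a (reduced) matrix with the
same annealer on Euclidean dissimilarity, optimizing (Xie–Beni minimized,
Silhouette maximized) over sample-medoid strings with
`K in [2, floor(sqrt(d))]`, and returns the archive member with the best
Silhouette — Silhouette is also the index the method's evaluation tables
rank by. Internal validity is reported with the Silhouette index (singleton
points contribute 0; a point with zero dissimilarity everywhere contributes
0) and the Davies–Bouldin index (coordinate-mean centers in vector mode,
medoids in dissimilarity mode; coincident centers give the `Inf` sentinel).
External validity uses classification accuracy — each cluster mapped to its
modal true class, ties to the class occurring earliest in the cluster — and
the adjusted Rand index.

## The synthetic study data

`generate_synthetic()` plants the structure every pipeline stage is tested
against:

* `k` signal clusters of genes, split evenly. Prototypes follow a
  tissue-module design: each cluster is up-regulated (amplitude 1, sign and
  magnitude varied per round when clusters outnumber classes) in exactly
  one of `n_classes` sample classes, so all prototype profiles are
  equally separated — the co-expression structure of multi-tissue panels,
  where a random-levels design would instead make some cluster pairs
  arbitrarily hard to tell apart by the luck of the draw. Member genes add
  `Normal(0, sigma)` noise.
* a `noise_frac` fraction of pure-noise genes, uniform over the prototype
  range widened by one amplitude unit per side. They are clear outliers
  with no co-expression structure and form a designated noise cluster
  (label `k + 1`) in the truth partition.
* view 2 as a block similarity matrix over the truth partition — within a
  planted cluster, including the noise cluster, `U(0.7, 0.9)`; between
  clusters `U(0.1, 0.3)` — then a `1 - rho` fraction of genes get their
  rows resampled to `U(0.1, 0.9)`. At `rho = 1` the view-2 co-membership
  equals the truth partition's exactly; the noise cluster is thus a
  functionally coherent module with *no* expression support, the
  single-view artifact the consensus is meant to discount.

What the generator does not emulate: heteroscedastic microarray noise,
correlated noise genes, unbalanced cluster sizes, dropout. Passing the
recovery tests shows the pipeline separates block-structured signal from
uniform outliers at the stated noise levels; it does not certify
performance on real arrays.

At the default study conditions (n = 120 genes, d = 20 samples, K* = 4,
sigma = 0.1, rho = 0.9, 30% noise genes, default annealer), the ensemble
partition restricted to the signal genes matches the planted clusters
essentially perfectly (adjusted Rand 1.0 across seeds in our runs), and in
the noiseless limit (sigma = 0, rho = 1, no noise genes) the full pipeline
returns exactly the planted partition and one medoid per planted cluster.
The ensemble K, however, typically lands at 5–7, not K*: the crisp
Xie–Beni index rewards extra medoids that absorb outlier noise genes (the
numerator shrinks while the minimum medoid separation, pinned by signal
medoid pairs, is unchanged), so archived strings drift above K* and stable
noise micro-clusters survive the vote as small extra clusters. A fraction
of the selected genes are therefore noise-cluster members under these
conditions; the signal panel itself is recovered cleanly. We report both
facets honestly rather than suppressing small clusters post hoc.

## Numerical and degenerate-input conventions

* Similarity matrices must be symmetric to 1e-8 (then symmetrized as
  `(M + M')/2`), within [0, 1] to 1e-12, unit diagonal (forced).
* An all-constant expression matrix yields all-ones view-1 similarity with
  a warning.
* Expression rows with any missing value are dropped at load time with a
  count in the warning.
* `Inf` objectives participate in domination normally; in the amount of
  domination a differing pair involving `Inf` contributes the maximal
  factor 1.
* All internal indices and labels are 1-based; on-disk cluster labels are
  0-based integers.
* Every stochastic entry point takes a `seed`; fixed seed means
  reproducible output, byte-identical for the CLI.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at
n = 120 genes × 20 samples (five seeded replicates plus a noiseless run),
property checks on instances of n ≤ 50, and the downstream sample
clustering at d = 20. These sizes keep a complete run in the low minutes on
one core while leaving the planted-recovery problem non-trivial (the
annealer evaluates ~6,600 solutions per run).

## Known limitations

* Exactly two views are wired into the optimizer, as in the underlying
  method; the containers generalize but `run_cmvmc()` does not.
* The functional-view defaults are documented stand-ins with the right
  contract, not a reimplementation of any published fused similarity
  measure; supply your own callables for exact reproduction.
* The Xie–Beni index on heavy-outlier data inflates the recovered cluster
  count (see above); interpret `K` and small clusters accordingly, and
  inspect `recovery_noise_genes_selected`-style diagnostics when ground
  truth is available.
* GO-enrichment validation of clusters and supervised classifiers are out
  of scope; the package stops at the reduced matrix and internal/external
  cluster validity.
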