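# cmvmc — consensus multi-view gene selection

`cmvmc` selects a small, non-redundant panel of genes from an expression
matrix by clustering the *genes* under two complementary similarity views —
co-expression (Euclidean distance between expression profiles) and function
(Gene Ontology + protein-interaction-network similarity) — and keeping one
medoid gene per consensus cluster. The reduced matrix that results is meant
for downstream sample classification: fewer, more trustworthy features.

The clustering core is an archived multi-objective simulated annealer
(AMOSA). Each candidate solution encodes one medoid string per view plus
their consensus, and three objectives are optimized at once:

* `XB1`, `XB2` — the Xie–Beni cluster validity index of each view's
  partition (`XB = Σ_k Σ_{x∈C_k} d(x, m_k)² / (n · min_{k≠l} d(m_k, m_l)²)`,
  with `d = 1 − S`), minimized;
* `AI` — the agreement index between the two partitions
  (`AI = (AG + 1)/(DG + 1)`, where `AG` counts positions on which the two
  co-membership matrices agree and `DG = n² − AG`), maximized.

The archive of mutually non-dominated solutions is ensembled by pairwise
majority voting over the consensus partitions; final cluster medoids are
the selected genes. The package also ships the format readers the pipeline
touches (expression and similarity TSV/CSV, OBO, GAF 2.x, edge-list and
PSI-MITAB networks), internal/external validity measures (Silhouette,
Davies–Bouldin, classification accuracy, adjusted Rand), an AMOSA-based
sample-clustering step for scoring a selection, a planted-structure
synthetic data generator, and a command-line interface.

## Worked example

Generate two-view data with four planted gene clusters, 30% pure-noise
genes and a partially concordant functional view, run the pipeline, and
score the reduced matrix:

```r
library(cmvmc)

sim <- generate_synthetic(n = 120, d = 20, k = 4, sigma = 0.1, rho = 0.9,
                          noise_frac = 0.3, seed = 1)
v1  <- build_view1(sim$em)                     # co-expression view
res <- run_cmvmc(v1, sim$view2, cfg = amosa_config(), seed = 1)
res
#> cmvmc_result: 20 non-dominated solution(s), consensus K in [2, 10] over 120 genes

sel <- select_genes(sim$em, res, v1, sim$view2)
sel$genes
#> [1] "g007" "g032" "g046" "g076" "g095"
sel$reduced
#> ExpressionMatrix: 5 genes x 20 samples (4 sample classes)

sig <- sim$truth$signal
adjusted_rand(sel$partition$labels[sig],
              sim$truth$gene_partition$labels[sig])
#> [1] 1

cs <- cluster_samples(sel$reduced, seed = 2)
cs$K; round(cs$silhouette, 3)
#> [1] 4
#> [1] 0.472
classification_accuracy(cs$partition, sim$em$sample_labels)
#> [1] 100
```

The run reduced 120 genes to a 5-gene panel whose clustering matches the
four planted signal clusters exactly (adjusted Rand 1; the fifth gene
represents the planted functional-only noise module), and clustering the
20 samples on the reduced matrix recovers the four tissue classes with
100% classification accuracy — on the full noisy matrix the same
clustering reaches a Silhouette of only ≈ 0.24 against 0.47 here.

## Command line

The same pipeline is scriptable through the installed `cmvmc` executable
(or `Rscript -e 'cmvmc::cmvmc_main()' --args ...`):

```sh
cmvmc simulate --n 120 --d 20 --k 4 --sigma 0.1 --rho 0.9 \
      --noise-frac 0.3 --seed 7 --out-dir sim/
cmvmc pipeline --expression sim/expression.tsv --view2 sim/view2.tsv \
      --labels sim/labels.tsv --seed 7 --out-dir results/
```

`pipeline` writes `genes.txt`, `X_reduced.tsv`, `gene_clusters.tsv`,
`report.json` (Silhouette, Davies–Bouldin, classification accuracy, K) and
a run manifest. `views`, `run`, `select` and `evaluate` expose the
individual stages; one YAML config mirrors every flag, and a fixed
`--seed` makes outputs byte-identical across runs.

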