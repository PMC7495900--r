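# Steps 5-6: ensemble the archived consensus partitions by majority voting
# over gene pairs, extract one medoid per final cluster as the selected
# genes, and emit the reduced expression matrix.

#' Majority-vote ensemble of partitions
#'
#' Evidence accumulation over gene pairs: the co-clustering vote fraction
#' of every pair is computed over the input partitions, and genes are
#' agglomerated by average linkage as long as the mean vote between groups
#' strictly exceeds `threshold` (so a pair is kept together only when the
#' majority of solutions co-cluster it, and no chain of isolated pairwise
#' majorities can bridge two groups that mostly disagree). The resulting
#' groups of size >= 2 become core clusters and every remaining gene joins
#' the core with maximal mean combined similarity (S1 + S2)/2. When fewer
#' than 2 cores emerge the vote is degenerate and the single input
#' partition with the best (lowest) mean Xie-Beni index across the two
#' views is returned instead.
#'
#' @param partitions non-empty list of `Partition`s over the same n genes.
#' @param view1,view2 aligned `SimilarityView`s (used for the
#'   maximum-average-similarity placement and the fallback ranking).
#' @param threshold vote fraction required to keep a pair together
#'   (strict majority, default 0.5).
#' @return a `Partition` over the n genes.
#' @export
majority_vote <- function(partitions, view1, view2, threshold = 0.5) {
  stopifnot(length(partitions) >= 1L)
  partitions <- lapply(partitions, as_partition_keep)
  n <- length(partitions[[1L]]$labels)
  sizes <- vapply(partitions, function(p) length(p$labels), integer(1))
  if (any(sizes != n))
    stop("partitions cover different numbers of genes: ",
         paste(unique(sizes), collapse = ", "))
  m <- length(partitions)
  votes <- Reduce(`+`, lapply(partitions, comembership))
  hc <- stats::hclust(stats::as.dist(1 - votes / m), method = "average")
  grp <- stats::cutree(hc, h = 1 - threshold - 1e-9)
  core_ids <- which(tabulate(grp) >= 2L)
  if (length(core_ids) < 2L) {
    meanxb <- vapply(partitions, function(p) {
      med <- extract_medoids(p, view1, view2)
      if (p$K < 2L) return(Inf)
      mean(c(xb_index(p, med, view1), xb_index(p, med, view2)))
    }, numeric(1))
    return(partitions[[which.min(meanxb)]])
  }
  cores <- lapply(core_ids, function(k) which(grp == k))
  lab <- integer(n)
  for (k in seq_along(cores)) lab[cores[[k]]] <- k
  rest <- which(lab == 0L)
  if (length(rest)) {
    sc <- (view1$matrix + view2$matrix) / 2
    score <- vapply(cores, function(core)
      rowMeans(sc[rest, core, drop = FALSE]), numeric(length(rest)))
    score <- matrix(score, nrow = length(rest))
    lab[rest] <- max.col(score, ties.method = "first")
  }
  structure(list(labels = lab, K = length(cores)), class = "Partition")
}

#' Extract one medoid gene per cluster
#'
#' For every cluster the member with maximal mean combined similarity
#' (S1 + S2)/2 to the other members is the medoid; a singleton cluster is
#' its own medoid. Ties break to the lowest gene index. The result has
#' exactly K genes, one per cluster.
#'
#' @param p a `Partition` over the genes of the views.
#' @param view1,view2 aligned `SimilarityView`s.
#' @return integer vector of gene indices, ordered by cluster label.
#' @export
extract_medoids <- function(p, view1, view2) {
  p <- as_partition_keep(p)
  sc <- (view1$matrix + view2$matrix) / 2
  vapply(seq_len(p$K), function(k) {
    members <- which(p$labels == k)
    if (length(members) == 1L) return(members)
    sub <- sc[members, members, drop = FALSE]
    avg <- (rowSums(sub) - 1) / (length(members) - 1L)
    members[which.max(avg)]
  }, integer(1))
}

#' Select genes from an optimizer result and reduce the expression matrix
#'
#' Runs the full step-5/step-6 pipeline: all archived consensus partitions
#' are ensembled by [majority_vote()], the final medoids are extracted as
#' the candidate gene set, and the expression matrix is reduced to those
#' rows (original sample order preserved).
#'
#' @param em the `ExpressionMatrix` the views were built from.
#' @param result a `cmvmc_result` from [run_cmvmc()].
#' @param view1,view2 the aligned views used in the run.
#' @param threshold majority threshold, see [majority_vote()].
#' @return list with `genes` (character, the candidate set `Cand`),
#'   `partition` (final ensemble `Partition`), `reduced` (reduced
#'   `ExpressionMatrix` with `length(genes)` rows).
#' @export
select_genes <- function(em, result, view1, view2, threshold = 0.5) {
  stopifnot(inherits(em, "ExpressionMatrix"),
            inherits(result, "cmvmc_result"))
  parts <- lapply(result$solutions, `[[`, "partition3")
  final <- majority_vote(parts, view1, view2, threshold = threshold)
  med <- extract_medoids(final, view1, view2)
  genes <- view1$gene_ids[med]
  idx <- match(genes, em$gene_ids)
  if (anyNA(idx))
    stop("selected gene(s) missing from the expression matrix: ",
         paste(genes[is.na(idx)], collapse = ", "))
  reduced <- expression_matrix(em$values[idx, , drop = FALSE],
                               gene_ids = genes,
                               sample_ids = em$sample_ids,
                               sample_labels = em$sample_labels)
  list(genes = genes, partition = final, reduced = reduced)
}
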