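# Internal and external cluster validity, plus the downstream AMOSA-based
# sample clustering used to score a gene selection.

#' Silhouette index
#'
#' Mean over all points of `(b - a) / max(a, b)` where `a` is the mean
#' dissimilarity to the point's own cluster and `b` the smallest mean
#' dissimilarity to any other cluster. A singleton point contributes 0, as
#' does a point with `a = b = 0`. Higher is better; range \[-1, 1\].
#'
#' @param p a `Partition` (K >= 2).
#' @param d n x n dissimilarity matrix.
#' @return real in \[-1, 1\].
#' @export
silhouette_index <- function(p, d) {
  p <- as_partition_keep(p)
  if (p$K < 2L) stop("silhouette needs at least 2 clusters")
  d <- as.matrix(d)
  n <- length(p$labels)
  stopifnot(nrow(d) == n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(p$labels == p$labels[i])
    if (length(own) == 1L) next                       # singleton -> 0
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(seq_len(p$K), p$labels[i]), function(k)
      mean(d[i, p$labels == k]), numeric(1)))
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' `DB = (1/K) * sum_k max_{l != k} (sigma_k + sigma_l) / d(c_k, c_l)`.
#' In vector mode the cluster centers are coordinate means and `sigma` the
#' mean Euclidean distance to the center; in dissimilarity mode the centers
#' are medoids (members minimizing total within-cluster dissimilarity) and
#' `sigma` the mean dissimilarity to the medoid. Lower is better; coincident
#' centers return the `+Inf` sentinel.
#'
#' @param p a `Partition` (K >= 2).
#' @param points numeric matrix (one row per element) for vector mode.
#' @param d n x n dissimilarity matrix for dissimilarity mode. Exactly one
#'   of `points` / `d` must be given.
#' @return non-negative real (possibly `Inf`).
#' @export
davies_bouldin <- function(p, points = NULL, d = NULL) {
  p <- as_partition_keep(p)
  if (p$K < 2L) stop("Davies-Bouldin needs at least 2 clusters")
  if (is.null(points) == is.null(d))
    stop("give exactly one of `points` or `d`")
  K <- p$K
  if (!is.null(points)) {
    points <- as.matrix(points)
    centers <- do.call(rbind, lapply(seq_len(K), function(k)
      colMeans(points[p$labels == k, , drop = FALSE])))
    sigma <- vapply(seq_len(K), function(k) {
      rows <- points[p$labels == k, , drop = FALSE]
      mean(sqrt(rowSums(sweep(rows, 2L, centers[k, ])^2)))
    }, numeric(1))
    sep <- as.matrix(stats::dist(centers))
  } else {
    d <- as.matrix(d)
    med <- vapply(seq_len(K), function(k) {
      members <- which(p$labels == k)
      members[which.min(rowSums(d[members, members, drop = FALSE]))]
    }, integer(1))
    sigma <- vapply(seq_len(K), function(k)
      mean(d[med[k], p$labels == k]), numeric(1))
    sep <- d[med, med, drop = FALSE]
  }
  r <- vapply(seq_len(K), function(k) {
    others <- setdiff(seq_len(K), k)
    vals <- (sigma[k] + sigma[others]) / sep[k, others]
    vals[sep[k, others] == 0] <- Inf
    max(vals)
  }, numeric(1))
  mean(r)
}

#' Classification accuracy of a partition against known classes
#'
#' Every cluster is mapped to its modal true class (ties resolved to the
#' class of the tied member occurring earliest in the cluster), and CA is
#' the percentage of elements whose cluster maps to their own class.
#' Invariant to cluster relabeling.
#'
#' @param p a `Partition`.
#' @param labels true class label per element.
#' @return percentage in \[0, 100\].
#' @export
classification_accuracy <- function(p, labels) {
  p <- as_partition_keep(p)
  n <- length(p$labels)
  if (length(labels) != n)
    stop("labels length (", length(labels), ") != partition size (", n, ")")
  labels <- as.character(labels)
  correct <- 0L
  for (k in seq_len(p$K)) {
    cls <- labels[p$labels == k]
    if (!length(cls)) next
    counts <- table(cls)
    top <- names(counts)[counts == max(counts)]
    modal <- if (length(top) == 1L) top else
      cls[min(match(top, cls))]   # tie: class occurring earliest in cluster
    correct <- correct + sum(cls == modal)
  }
  100 * correct / n
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected partition agreement computed from the contingency table;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param p1,p2 `Partition`s (or raw label vectors) over the same elements.
#' @return real <= 1.
#' @export
adjusted_rand <- function(p1, p2) {
  l1 <- if (inherits(p1, "Partition")) p1$labels else as.integer(factor(p1))
  l2 <- if (inherits(p2, "Partition")) p2$labels else as.integer(factor(p2))
  if (length(l1) != length(l2)) stop("partitions differ in length")
  mclust::adjustedRandIndex(l1, l2)
}

#' Multi-objective medoid clustering of samples
#'
#' The downstream scoring step: samples are clustered on the Euclidean
#' dissimilarity of their (reduced) gene profiles by the same annealer,
#' optimizing (Xie-Beni minimized, Silhouette maximized) over medoid strings
#' with K in \[2, floor(sqrt(d))\]; the archive member with the best
#' Silhouette is returned.
#'
#' @param em an `ExpressionMatrix` (typically the reduced matrix).
#' @param cfg an [amosa_config()].
#' @param seed optional integer seed.
#' @return list with `partition` (over samples), `K`, `silhouette`, `xb`,
#'   `medoids` (sample indices).
#' @export
cluster_samples <- function(em, cfg = amosa_config(), seed = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  d_n <- length(em$sample_ids)
  if (d_n < 4L) stop("need at least 4 samples so that floor(sqrt(d)) >= 2")
  if (!is.null(seed)) set.seed(seed)
  dis <- as.matrix(stats::dist(t(em$values)))
  dmax <- max(dis)
  if (dmax == 0) stop("all samples identical; nothing to cluster")
  sv <- similarity_view(1 - dis / dmax, gene_ids = em$sample_ids)
  km <- max_k(d_n)
  problem <- list(
    initial = function() sample.int(d_n, sample_k(km)),
    perturb = function(ms) {
      repeat {
        op <- sample.int(3L, 1L)
        if (op == 1L) break
        if (op == 2L && length(ms) + 1L <= km) break
        if (op == 3L && length(ms) - 1L >= 2L) break
      }
      if (op == 1L) {
        ms[sample.int(length(ms), 1L)] <- sample(setdiff(seq_len(d_n), ms), 1L)
      } else if (op == 2L) {
        ms <- c(ms, sample(setdiff(seq_len(d_n), ms), 1L))
      } else ms <- ms[-sample.int(length(ms), 1L)]
      ms
    },
    evaluate = function(ms) {
      pp <- assign_genes(ms, sv)
      c(xb_index(pp, ms, sv), silhouette_index(pp, dis))
    })
  archive <- anneal(problem, cfg, directions = c("min", "max"))
  obj <- archive_objectives(archive)
  best <- which.max(obj[, 2L])
  ms <- archive$members[[best]]$solution
  pp <- assign_genes(ms, sv)
  list(partition = pp, K = length(ms),
       silhouette = obj[best, 2L], xb = obj[best, 1L], medoids = ms)
}
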