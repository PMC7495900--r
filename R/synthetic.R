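# Planted-structure generator. Emulates the shape of the study inputs - a
# genes x samples expression matrix plus a second, functional similarity
# view concordant with the same planted gene partition - so every pipeline
# stage is testable without external downloads.

#' Generate two-view gene data with planted structure
#'
#' Signal genes are split evenly into `k` planted clusters. Prototypes
#' follow the tissue-module design of multi-tissue expression data: each
#' planted cluster is up-regulated in exactly one sample class (amplitude
#' alternating in sign and growing when clusters outnumber classes, so all
#' prototype profiles are distinct and equally separated when
#' `n_classes = k`), and member genes are the prototype plus
#' `Normal(0, sigma)` noise. A fraction `noise_frac` of genes are
#' pure-noise features drawn uniformly over the prototype range widened by
#' one amplitude unit on each side, making them clear outliers with no
#' co-expression structure; in the truth they form a designated noise
#' cluster (label `k + 1`). The second view is a block
#' similarity matrix over the clusters of the truth partition - within a
#' planted cluster, including the noise cluster, `Uniform(0.7, 0.9)`;
#' between clusters `Uniform(0.1, 0.3)` - so the view-2 co-membership at
#' `rho = 1` equals the truth partition's exactly. The noise cluster thus
#' models a functionally coherent gene module with no expression support:
#' only genes backed by both views should survive as selected medoids. A
#' fraction `1 - rho` of genes have their view-2 rows/columns resampled
#' to random levels `Uniform(0.1, 0.9)`.
#'
#' @param n number of genes.
#' @param d number of samples.
#' @param k number of planted gene clusters (`k <= floor(sqrt(n))`, or the
#'   clustering core could not even represent the truth).
#' @param sigma within-cluster expression noise (sd).
#' @param rho view-2 concordance in \[0, 1\].
#' @param noise_frac fraction of pure-noise genes.
#' @param n_classes number of planted sample classes; defaults to `k`, one
#'   class per planted cluster.
#' @param seed optional integer seed.
#' @return list with `em` (an `ExpressionMatrix` with `sample_labels`),
#'   `view2` (a `SimilarityView`), `truth` (class `SyntheticTruth`: list
#'   with `gene_partition` including the noise cluster, `signal` logical
#'   mask, `sample_partition`, `params`).
#' @export
generate_synthetic <- function(n = 120L, d = 20L, k = 4L, sigma = 0.1,
                               rho = 0.9, noise_frac = 0.3, n_classes = k,
                               seed = NULL) {
  stopifnot(n >= 8L, d >= 4L, k >= 2L, sigma >= 0, rho >= 0, rho <= 1,
            noise_frac >= 0, noise_frac < 1, n_classes >= 1L)
  if (k > max_k(n))
    stop("k = ", k, " planted clusters exceed floor(sqrt(n)) = ", max_k(n),
         "; the clustering core could not represent the truth")
  if (!is.null(seed)) set.seed(seed)
  n_noise <- round(noise_frac * n)
  n_signal <- n - n_noise
  stopifnot(n_signal >= 2L * k)
  gene_lab <- c(sort(rep_len(seq_len(k), n_signal)),
                rep(k + 1L, n_noise))
  signal <- gene_lab <= k
  sample_lab <- sort(rep_len(seq_len(n_classes), d))

  # tissue-module prototypes: cluster k is up-regulated in one class, with
  # amplitude alternating in sign per round when clusters outnumber classes
  pref <- ((seq_len(k) - 1L) %% n_classes) + 1L
  round_k <- ceiling(seq_len(k) / n_classes)
  amp <- (1 + 0.5 * (round_k - 1)) * (-1)^(round_k - 1)
  proto_levels <- matrix(0, k, n_classes)
  proto_levels[cbind(seq_len(k), pref)] <- amp
  proto <- proto_levels[, sample_lab, drop = FALSE]
  values <- matrix(0, n, d)
  for (i in which(signal))
    values[i, ] <- proto[gene_lab[i], ] + stats::rnorm(d, 0, sigma)
  if (n_noise > 0) {
    lo <- min(proto_levels) - 1; hi <- max(proto_levels) + 1
    for (i in which(!signal)) values[i, ] <- stats::runif(d, lo, hi)
  }
  gene_ids <- sprintf("g%03d", seq_len(n))
  em <- expression_matrix(values, gene_ids = gene_ids,
                          sample_ids = sprintf("s%02d", seq_len(d)),
                          sample_labels = paste0("class", sample_lab))

  s2 <- matrix(0, n, n)
  ut <- upper.tri(s2)
  s2[ut] <- stats::runif(sum(ut), 0.1, 0.3)
  for (cl in seq_len(max(gene_lab))) {
    members <- which(gene_lab == cl)
    if (length(members) < 2L) next
    blk <- matrix(stats::runif(length(members)^2, 0.7, 0.9),
                  length(members))
    s2[members, members][upper.tri(blk)] <- blk[upper.tri(blk)]
  }
  discordant <- sample.int(n, round((1 - rho) * n))
  for (g in discordant) {
    s2[g, ] <- stats::runif(n, 0.1, 0.9)
    s2[, g] <- s2[g, ]
  }
  s2[lower.tri(s2)] <- t(s2)[lower.tri(s2)]
  diag(s2) <- 1
  view2 <- similarity_view(s2, gene_ids = gene_ids)

  truth <- structure(list(
    gene_partition = partition(gene_lab),
    signal = signal,
    sample_partition = partition(sample_lab),
    params = list(n = n, d = d, k = k, sigma = sigma, rho = rho,
                  noise_frac = noise_frac, n_classes = n_classes,
                  seed = seed)),
    class = "SyntheticTruth")
  list(em = em, view2 = view2, truth = truth)
}

#' Randomly reassign a fraction of partition labels
#'
#' `ceiling(f * n)` randomly chosen elements are moved to a uniformly random
#' different cluster; the draw is repeated if it would empty a cluster, so K
#' is preserved. Used to probe how the agreement index decays as two
#' partitions drift apart.
#'
#' @param p a `Partition` with K >= 2.
#' @param f fraction of elements to move, in \[0, 1\].
#' @param max_tries redraw attempts before giving up.
#' @return a `Partition` with the same K.
#' @export
perturb_partition <- function(p, f, max_tries = 1000L) {
  p <- as_partition_keep(p)
  stopifnot(f >= 0, f <= 1, p$K >= 2L)
  n <- length(p$labels)
  m <- ceiling(f * n)
  if (m == 0L) return(p)
  for (try in seq_len(max_tries)) {
    lab <- p$labels
    victims <- sample.int(n, m)
    for (v in victims)
      lab[v] <- sample(setdiff(seq_len(p$K), lab[v]), 1L)
    if (all(seq_len(p$K) %in% lab))
      return(structure(list(labels = lab, K = p$K), class = "Partition"))
  }
  stop("could not move ", m, " elements without emptying a cluster")
}
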