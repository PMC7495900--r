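# The consensus multi-view clustering core. A candidate ("parent") solution
# encodes three medoid strings: one per view plus their consensus. Strings 1
# and 2 are optimized directly by the annealer; string 3 is recomputed from
# the other two at every evaluation. Objectives are the Xie-Beni index of
# each view's partition (minimized) and the agreement index between the two
# partitions (maximized). Dissimilarity is 1 - similarity throughout.

max_k <- function(n) floor(sqrt(n))

# uniform K in [2, km]; sample() would misread the scalar 2:2 case
sample_k <- function(km) if (km <= 2L) 2L else sample(2:km, 1L)

#' Draw a random parent solution
#'
#' One cluster count K is drawn uniformly on \[2, floor(sqrt(n))\] and
#' shared by both strings (each parent solution encodes K clusters per
#' view, as the add/delete perturbations move both strings' K in
#' lock-step); the K medoids of each string are sampled independently
#' without replacement. The consensus string starts empty; partitions are
#' unassigned until [evaluate_solution()].
#'
#' @param n number of genes (>= 4, so that floor(sqrt(n)) >= 2).
#' @return list of class `ParentSolution` with `string1`, `string2` (integer
#'   medoid vectors), empty `string3`, NULL partitions and objectives.
#' @export
init_solution <- function(n) {
  if (n < 4L) stop("need at least 4 genes so that floor(sqrt(n)) >= 2")
  km <- max_k(n)
  k <- sample_k(km)
  structure(list(string1 = sample.int(n, k), string2 = sample.int(n, k),
                 string3 = integer(0),
                 partition1 = NULL, partition2 = NULL, partition3 = NULL,
                 objectives = NULL),
            class = "ParentSolution")
}

#' Assign genes to their most similar medoid
#'
#' Every non-medoid gene joins the cluster of the medoid it is most similar
#' to under the view; each medoid anchors its own cluster. Ties are broken
#' by the lowest medoid position in the string. Cluster label k corresponds
#' to the k-th medoid.
#'
#' @param medoids integer vector of distinct gene indices.
#' @param view a `SimilarityView`.
#' @return a `Partition` with `K = length(medoids)`.
#' @export
assign_genes <- function(medoids, view) {
  stopifnot(inherits(view, "SimilarityView"))
  n <- length(view$gene_ids)
  if (anyDuplicated(medoids) || any(medoids < 1L) || any(medoids > n))
    stop("medoids must be distinct gene indices in 1..n")
  lab <- max.col(view$matrix[, medoids, drop = FALSE], ties.method = "first")
  lab[medoids] <- seq_along(medoids)
  structure(list(labels = lab, K = length(medoids)), class = "Partition")
}

#' Xie-Beni index for crisp medoid clustering
#'
#' `XB = sum_k sum_{x in C_k} d(x, m_k)^2 / (n * min_{k != l} d(m_k, m_l)^2)`
#' with dissimilarity `d = 1 - similarity`. Lower is better; coincident
#' medoids (zero separation) return the `+Inf` sentinel.
#'
#' @param p the `Partition` induced by `medoids` (cluster k = k-th medoid).
#' @param medoids integer medoid vector.
#' @param view a `SimilarityView`.
#' @return non-negative real (possibly `Inf`).
#' @export
xb_index <- function(p, medoids, view) {
  p <- as_partition_keep(p)
  K <- length(medoids)
  if (K < 2L) stop("Xie-Beni index needs at least 2 clusters")
  n <- length(p$labels)
  d_to_own <- 1 - view$matrix[cbind(seq_len(n), medoids[p$labels])]
  sep <- 1 - view$matrix[medoids, medoids, drop = FALSE]
  min_sep <- min(sep[upper.tri(sep)])
  if (min_sep <= 0) return(Inf)
  sum(d_to_own^2) / (n * min_sep^2)
}

as_partition_keep <- function(p) {
  if (inherits(p, "Partition")) p else
    structure(list(labels = as.integer(p), K = max(as.integer(p))),
              class = "Partition")
}

#' Agreement index between two partitions
#'
#' Both partitions are turned into binary co-membership (agreement) matrices
#' with unit diagonal; `AG` counts the positions (out of n^2) where the two
#' matrices agree and `DG = n^2 - AG` the disagreements. The index is
#' `AI = (AG + 1) / (DG + 1)` (the +1 avoids division by zero), so identical
#' co-membership gives the maximum `n^2 + 1` and higher is better.
#'
#' @param p1,p2 `Partition`s over the same n elements.
#' @return positive rational.
#' @export
agreement_index <- function(p1, p2) {
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  n <- length(p1$labels)
  if (n != length(p2$labels))
    stop("partitions differ in length: ", n, " vs ", length(p2$labels))
  a1 <- outer(p1$labels, p1$labels, "==")
  a2 <- outer(p2$labels, p2$labels, "==")
  ag <- sum(a1 == a2)
  (ag + 1) / (n^2 - ag + 1)
}

#' Build the consensus of the two view partitions
#'
#' Implements the overlap-matching consensus: (a) the K1 x K2 contingency
#' table of the two partitions is computed; (b) cluster pairs are greedily
#' matched by descending overlap (ties by the lower index pair), each
#' cluster used at most once, stopping at zero overlap; (c) within each
#' matched pair the genes common to both clusters form the consensus core,
#' whose medoid is the most centrally located common gene - the one with
#' maximal average combined similarity (S1 + S2)/2 to the other common
#' genes; (d) every remaining gene joins the core with maximal mean combined
#' similarity; (e) if fewer than 2 pairs match, the partition of the string
#' with the better (lower) Xie-Beni index is copied as the consensus.
#'
#' @param p1,p2 `Partition`s induced by `med1`, `med2` under `view1`,
#'   `view2`.
#' @param med1,med2 the two medoid strings.
#' @param view1,view2 aligned `SimilarityView`s.
#' @return list with `medoids` (consensus medoid string), `partition`
#'   (consensus `Partition`) and `fallback` (logical).
#' @export
build_consensus <- function(p1, p2, med1, med2, view1, view2) {
  p1 <- as_partition_keep(p1); p2 <- as_partition_keep(p2)
  n <- length(p1$labels)
  ct <- table(factor(p1$labels, levels = seq_len(p1$K)),
              factor(p2$labels, levels = seq_len(p2$K)))
  used1 <- logical(p1$K); used2 <- logical(p2$K)
  pairs <- list()
  repeat {
    ct_av <- ct
    ct_av[used1, ] <- -1L
    ct_av[, used2] <- -1L
    best <- max(ct_av)
    if (best <= 0L) break
    hits <- which(ct_av == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    pairs[[length(pairs) + 1L]] <- c(i, j)
    used1[i] <- TRUE; used2[j] <- TRUE
  }
  if (length(pairs) < 2L) {
    xb1 <- xb_index(p1, med1, view1)
    xb2 <- xb_index(p2, med2, view2)
    if (xb1 <= xb2)
      return(list(medoids = med1, partition = p1, fallback = TRUE))
    return(list(medoids = med2, partition = p2, fallback = TRUE))
  }
  sc <- (view1$matrix + view2$matrix) / 2
  cores <- lapply(pairs, function(pr)
    which(p1$labels == pr[1L] & p2$labels == pr[2L]))
  med3 <- vapply(cores, function(core) {
    if (length(core) == 1L) return(core)
    sub <- sc[core, core, drop = FALSE]
    avg <- (rowSums(sub) - 1) / (length(core) - 1L)
    core[which.max(avg)]          # which.max ties -> lowest gene index
  }, integer(1))
  lab <- integer(n)
  for (k in seq_along(cores)) lab[cores[[k]]] <- k
  rest <- which(lab == 0L)
  if (length(rest)) {
    score <- vapply(cores, function(core)
      rowMeans(sc[rest, core, drop = FALSE]), numeric(length(rest)))
    score <- matrix(score, nrow = length(rest))
    lab[rest] <- max.col(score, ties.method = "first")
  }
  list(medoids = med3,
       partition = structure(list(labels = lab, K = length(cores)),
                             class = "Partition"),
       fallback = FALSE)
}

#' Evaluate a parent solution under both views
#'
#' Induces the two view partitions from the medoid strings, computes the
#' objective vector (XB1, XB2, AI) and rebuilds the consensus string and
#' partition, returning a fully populated `ParentSolution`.
#'
#' @param sol a `ParentSolution` (only `string1`/`string2` are read).
#' @param view1,view2 aligned `SimilarityView`s.
#' @return the populated `ParentSolution`; `objectives` is `c(xb1, xb2, ai)`
#'   with XB minimized and AI maximized.
#' @export
evaluate_solution <- function(sol, view1, view2) {
  p1 <- assign_genes(sol$string1, view1)
  p2 <- assign_genes(sol$string2, view2)
  xb1 <- xb_index(p1, sol$string1, view1)
  xb2 <- xb_index(p2, sol$string2, view2)
  ai <- agreement_index(p1, p2)
  cons <- build_consensus(p1, p2, sol$string1, sol$string2, view1, view2)
  sol$partition1 <- p1; sol$partition2 <- p2
  sol$string3 <- cons$medoids; sol$partition3 <- cons$partition
  sol$objectives <- c(xb1 = xb1, xb2 = xb2, ai = ai)
  sol
}

#' Perturb a parent solution
#'
#' One of three operators is drawn uniformly: (1) replace one existing
#' medoid - at a random position of one randomly chosen string - with a
#' random non-medoid gene, leaving the other string intact so that each
#' view's clustering can be refined independently; (2) add a random
#' non-medoid gene as a new medoid to both strings (independent draws per
#' string), increasing the encoded cluster count of the solution by one;
#' (3) delete the medoid at a random position of each string, decreasing
#' it by one. Operators 2 and 3 re-draw when they would push K outside
#' \[2, floor(sqrt(n))\], so K never leaves its bounds. The consensus
#' string is never perturbed directly.
#'
#' @param sol a `ParentSolution`.
#' @param n number of genes.
#' @return a new `ParentSolution` with perturbed strings and cleared
#'   partitions/objectives.
#' @export
perturb_solution <- function(sol, n) {
  km <- max_k(n)
  k <- length(sol$string1)
  repeat {
    op <- sample.int(3L, 1L)
    if (op == 1L) break
    if (op == 2L && k + 1L <= km) break
    if (op == 3L && k - 1L >= 2L) break
  }
  s1 <- sol$string1; s2 <- sol$string2
  if (op == 1L) {
    if (sample.int(2L, 1L) == 1L) {
      s1[sample.int(length(s1), 1L)] <- sample(setdiff(seq_len(n), s1), 1L)
    } else {
      s2[sample.int(length(s2), 1L)] <- sample(setdiff(seq_len(n), s2), 1L)
    }
  } else if (op == 2L) {
    s1 <- c(s1, sample(setdiff(seq_len(n), s1), 1L))
    s2 <- c(s2, sample(setdiff(seq_len(n), s2), 1L))
  } else {
    s1 <- s1[-sample.int(length(s1), 1L)]
    s2 <- s2[-sample.int(length(s2), 1L)]
  }
  structure(list(string1 = s1, string2 = s2, string3 = integer(0),
                 partition1 = NULL, partition2 = NULL, partition3 = NULL,
                 objectives = NULL),
            class = "ParentSolution")
}

#' Run the consensus multi-view clustering optimizer
#'
#' Wires {[init_solution()], [perturb_solution()], [evaluate_solution()]}
#' into the AMOSA engine with objectives (XB1 min, XB2 min, AI max) and
#' returns the final archive of mutually non-dominated parent solutions,
#' each with a fully materialized consensus partition.
#'
#' @param view1,view2 aligned `SimilarityView`s over the same gene index.
#' @param cfg an [amosa_config()].
#' @param seed optional integer seed for the whole run.
#' @return object of class `cmvmc_result`: list with `solutions` (list of
#'   populated `ParentSolution`s), `objectives` (matrix, one row per
#'   solution: xb1, xb2, ai), `gene_ids`, `cfg`, `seed`.
#' @export
run_cmvmc <- function(view1, view2, cfg = amosa_config(), seed = NULL) {
  stopifnot(inherits(view1, "SimilarityView"),
            inherits(view2, "SimilarityView"))
  if (!identical(view1$gene_ids, view2$gene_ids))
    stop("views are not aligned; run align_views() first")
  n <- length(view1$gene_ids)
  if (!is.null(seed)) set.seed(seed)
  problem <- list(
    initial = function() init_solution(n),
    perturb = function(s) perturb_solution(s, n),
    evaluate = function(s) evaluate_solution(s, view1, view2)$objectives)
  archive <- anneal(problem, cfg, directions = c("min", "min", "max"))
  solutions <- lapply(archive$members, function(mem)
    evaluate_solution(mem$solution, view1, view2))
  structure(list(solutions = solutions,
                 objectives = do.call(rbind, lapply(solutions,
                                                    `[[`, "objectives")),
                 archive = archive,
                 gene_ids = view1$gene_ids, cfg = cfg, seed = seed),
            class = "cmvmc_result")
}

#' @export
print.cmvmc_result <- function(x, ...) {
  ks <- vapply(x$solutions, function(s) s$partition3$K, integer(1))
  cat("cmvmc_result:", length(x$solutions), "non-dominated solution(s), ",
      "consensus K in [", min(ks), ",", max(ks), "] over",
      length(x$gene_ids), "genes\n")
  invisible(x)
}
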