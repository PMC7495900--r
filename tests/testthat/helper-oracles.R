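# Independent oracles and fixture builders shared across the suite.

# literal double-loop agreement index over all n^2 ordered pairs
ai_brute <- function(l1, l2) {
  n <- length(l1)
  ag <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a1 <- as.integer(l1[i] == l1[j])
    a2 <- as.integer(l2[i] == l2[j])
    if (a1 == a2) ag <- ag + 1L
  }
  (ag + 1) / (n^2 - ag + 1)
}

# pair-counting adjusted Rand, independent of mclust
ari_brute <- function(l1, l2) {
  n <- length(l1)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- l1[i] == l1[j]; b <- l2[i] == l2[j]
    if (a && b) s11 <- s11 + 1
    else if (!a && !b) s00 <- s00 + 1
    else if (a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / tot
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(0)
  (s11 - expected) / (maxi - expected)
}

# naive Davies-Bouldin in vector mode, written independently
db_brute <- function(labels, points) {
  K <- max(labels)
  cen <- lapply(1:K, function(k) colMeans(points[labels == k, , drop = FALSE]))
  sig <- sapply(1:K, function(k) {
    rows <- points[labels == k, , drop = FALSE]
    mean(sqrt(rowSums((rows - matrix(cen[[k]], nrow(rows), ncol(rows),
                                     byrow = TRUE))^2)))
  })
  mean(sapply(1:K, function(k) {
    max(sapply(setdiff(1:K, k), function(l)
      (sig[k] + sig[l]) / sqrt(sum((cen[[k]] - cen[[l]])^2))))
  }))
}

rand_partition <- function(n, K) {
  repeat {
    lab <- sample.int(K, n, replace = TRUE)
    if (length(unique(lab)) == K) return(partition(lab))
  }
}

# similarity view from an explicit symmetric matrix
make_view <- function(m, ids = NULL) {
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(m)))
  similarity_view(m, gene_ids = ids)
}

# random valid similarity view
random_view <- function(n) {
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  make_view(m)
}

# short annealing schedule for small-instance optimizer tests
short_cfg <- function(...) {
  amosa_config(tmax = 10, tmin = 0.01, alpha = 0.9, iters_per_temp = 10L,
               sl = 20L, hl = 10L, n_init = 5L, ...)
}
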