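test_that("initial solutions respect the K bounds and share one K", {
  set.seed(1)
  for (rep in 1:50) {
    sol <- init_solution(100)
    k <- length(sol$string1)
    expect_true(k >= 2 && k <= 10)
    expect_equal(length(sol$string2), k)
    expect_false(anyDuplicated(sol$string1) > 0)
    expect_false(anyDuplicated(sol$string2) > 0)
    expect_length(sol$string3, 0L)
  }
  # n = 4 collapses the bound to K = 2
  set.seed(2)
  expect_equal(length(init_solution(4)$string1), 2L)
  expect_error(init_solution(3), "at least 4")
  # fixed seed reproduces the draw exactly
  set.seed(7); a <- init_solution(50)
  set.seed(7); b <- init_solution(50)
  expect_identical(a, b)
})

test_that("genes join their most similar medoid with first-position ties", {
  m <- diag(1, 3)
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.1
  v <- make_view(m)
  p <- assign_genes(c(1L, 2L), v)
  expect_equal(p$labels, c(1L, 2L, 1L))

  # exact tie goes to the medoid listed first in the string
  mt <- diag(1, 3)
  mt[1, 3] <- mt[3, 1] <- 0.5
  mt[2, 3] <- mt[3, 2] <- 0.5
  expect_equal(assign_genes(c(1L, 2L), make_view(mt))$labels[3], 1L)
  expect_equal(assign_genes(c(2L, 1L), make_view(mt))$labels[3], 1L)

  # six genes, medoids {1, 4}, block-structured similarity
  m6 <- matrix(0.1, 6, 6)
  m6[1:3, 1:3] <- 0.8
  m6[4:6, 4:6] <- 0.8
  diag(m6) <- 1
  p6 <- assign_genes(c(1L, 4L), make_view(m6))
  expect_equal(p6$labels, c(1L, 1L, 1L, 2L, 2L, 2L))
  # every medoid anchors its own cluster and all genes are covered
  expect_equal(p6$labels[c(1, 4)], 1:2)
  expect_length(p6$labels, 6L)

  expect_error(assign_genes(c(1L, 1L), make_view(m6)), "distinct")
})

test_that("Xie-Beni matches hand arithmetic and flags degeneracies", {
  # 4 genes, within-cluster dissimilarities {0, .1, 0, .1}, separation 1
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.9     # d = 0.1
  m[3, 4] <- m[4, 3] <- 0.9
  diag(m) <- 1
  v <- make_view(m)
  p <- assign_genes(c(1L, 3L), v)
  expect_equal(xb_index(p, c(1L, 3L), v), (0.01 + 0.01) / (4 * 1))

  # zero numerator when every gene coincides with its medoid
  mz <- matrix(0, 4, 4)
  mz[1, 2] <- mz[2, 1] <- 1
  mz[3, 4] <- mz[4, 3] <- 1
  diag(mz) <- 1
  vz <- make_view(mz)
  pz <- assign_genes(c(1L, 3L), vz)
  expect_equal(xb_index(pz, c(1L, 3L), vz), 0)

  # coincident medoids (similarity 1) hit the +Inf sentinel
  expect_equal(xb_index(pz, c(1L, 2L), vz), Inf)
  expect_error(xb_index(partition(rep(1, 4)), c(1L), v), "2 clusters")
})

test_that("Xie-Beni is invariant to uniform scaling of dissimilarities", {
  set.seed(3)
  n <- 10
  base <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  base <- base / max(base)
  for (c_scale in c(0.25, 0.5)) {
    v1 <- make_view(1 - base)
    v2 <- make_view(1 - base * c_scale)
    med <- c(1L, 5L, 9L)
    p <- assign_genes(med, v1)
    expect_equal(assign_genes(med, v2)$labels, p$labels)
    expect_equal(xb_index(p, med, v2), xb_index(p, med, v1),
                 tolerance = 1e-12)
  }
})

test_that("agreement index reproduces its closed forms", {
  expect_equal(agreement_index(partition(c(1, 1, 2)), partition(c(2, 2, 1))),
               10)                                   # identical co-membership
  expect_equal(agreement_index(partition(c(1, 1, 2, 2)),
                               partition(c(1, 2, 1, 2))), 1.0)
  expect_equal(agreement_index(partition(1:3), partition(c(1, 1, 1))), 4 / 7)
  expect_error(agreement_index(partition(1:3), partition(1:4)), "length")
})

test_that("agreement index equals brute-force enumeration on random pairs", {
  set.seed(4)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    p1 <- rand_partition(n, sample(2:min(4, n), 1))
    p2 <- rand_partition(n, sample(2:min(4, n), 1))
    expect_identical(agreement_index(p1, p2), ai_brute(p1$labels, p2$labels))
  }
})

test_that("agreement is maximal exactly for identical co-membership", {
  set.seed(5)
  n <- 9
  p <- rand_partition(n, 3)
  relabeled <- partition(match(p$labels, unique(rev(p$labels))))
  expect_equal(agreement_index(p, relabeled), n^2 + 1)
  moved <- perturb_partition(p, 0.3)
  expect_lt(agreement_index(p, moved), n^2 + 1)
})

test_that("consensus of identical partitions preserves the co-membership", {
  m <- matrix(0.1, 6, 6); m[1:3, 1:3] <- 0.8; m[4:6, 4:6] <- 0.8; diag(m) <- 1
  v1 <- make_view(m); v2 <- make_view(m)
  med <- c(1L, 4L)
  p <- assign_genes(med, v1)
  cons <- build_consensus(p, p, med, med, v1, v2)
  expect_false(cons$fallback)
  expect_identical(comembership(cons$partition), comembership(p))
})

test_that("consensus matches overlapping clusters and reassigns the rest", {
  # P1 = {1,2,3}{4,5,6}, P2 = {1,2,4}{3,5,6}: cores {1,2} and {5,6};
  # similarities steer gene 3 to the first core and gene 4 to the second
  m1 <- matrix(0.1, 6, 6); m1[1:3, 1:3] <- 0.8; m1[4:6, 4:6] <- 0.8
  diag(m1) <- 1
  m2 <- m1
  p1 <- partition(c(1, 1, 1, 2, 2, 2))
  p2 <- partition(c(1, 1, 2, 1, 2, 2))
  cons <- build_consensus(p1, p2, c(1L, 5L), c(2L, 6L),
                          make_view(m1), make_view(m2))
  expect_false(cons$fallback)
  expect_equal(cons$partition$K, 2L)
  lab <- cons$partition$labels
  expect_equal(lab[1], lab[2])          # core 1 stays together
  expect_equal(lab[5], lab[6])          # core 2 stays together
  expect_equal(lab[3], lab[1])          # block similarity pulls 3 to core 1
  expect_equal(lab[4], lab[5])          # and 4 to core 2
  # consensus medoids are members of their own clusters
  expect_equal(lab[cons$medoids], seq_len(cons$partition$K))
})

test_that("consensus falls back to the stronger string when matching degenerates", {
  # contingency [[0,1],[1,2]]: after matching (2,2) the rest has overlap 0
  m <- matrix(0.2, 4, 4); diag(m) <- 1
  m[2, 3] <- m[3, 2] <- 0.9; m[2, 4] <- m[4, 2] <- 0.9
  v1 <- make_view(m); v2 <- make_view(m)
  p1 <- partition(c(1, 2, 2, 2))
  p2 <- partition(c(2, 1, 2, 2))
  cons <- build_consensus(p1, p2, c(1L, 2L), c(1L, 2L), v1, v2)
  expect_true(cons$fallback)
  expect_true(identical(cons$partition$labels, p1$labels) ||
                identical(cons$partition$labels, p2$labels))
})

test_that("evaluation wires the objective vector from its components", {
  set.seed(6)
  v1 <- random_view(12)
  v2 <- random_view(12)
  set.seed(10)
  sol <- init_solution(12)
  ev <- evaluate_solution(sol, v1, v2)
  expect_equal(unname(ev$objectives[1]),
               xb_index(ev$partition1, ev$string1, v1))
  expect_equal(unname(ev$objectives[2]),
               xb_index(ev$partition2, ev$string2, v2))
  expect_equal(unname(ev$objectives[3]),
               agreement_index(ev$partition1, ev$partition2))
  expect_gt(ev$partition3$K, 0L)
  expect_length(ev$string3, ev$partition3$K)

  # identical views and strings give coinciding XB components
  sol2 <- sol; sol2$string2 <- sol2$string1
  ev2 <- evaluate_solution(sol2, v1, v1)
  expect_equal(ev2$objectives[["xb1"]], ev2$objectives[["xb2"]])
  expect_equal(unname(ev2$objectives[3]), 12^2 + 1)
})

test_that("perturbations never leave the K bounds over thousands of draws", {
  set.seed(8)
  n <- 50
  km <- floor(sqrt(n))
  sol <- init_solution(n)
  violations <- 0L
  for (i in 1:10000) {
    sol <- perturb_solution(sol, n)
    k <- length(sol$string1)
    if (k < 2 || k > km || length(sol$string2) != k ||
        anyDuplicated(sol$string1) || anyDuplicated(sol$string2) ||
        !all(c(sol$string1, sol$string2) %in% seq_len(n)))
      violations <- violations + 1L
  }
  expect_equal(violations, 0L)
})

test_that("the optimizer is deterministic and returns a sound archive", {
  set.seed(12)
  sim <- generate_synthetic(n = 40, d = 8, k = 3, sigma = 0.1, rho = 1,
                            noise_frac = 0, n_classes = 3, seed = 33)
  v1 <- build_view1(sim$em)
  r1 <- run_cmvmc(v1, sim$view2, cfg = short_cfg(), seed = 5)
  r2 <- run_cmvmc(v1, sim$view2, cfg = short_cfg(), seed = 5)
  expect_identical(r1$objectives, r2$objectives)
  expect_identical(lapply(r1$solutions, `[[`, "string3"),
                   lapply(r2$solutions, `[[`, "string3"))
  # mutually non-dominated members, AI maximized
  obj <- r1$objectives
  for (i in seq_len(nrow(obj))) for (j in seq_len(nrow(obj)))
    if (i != j)
      expect_false(dominates(obj[i, ], obj[j, ],
                             directions = c("min", "min", "max")))
  expect_error(run_cmvmc(v1, make_view(diag(5)), cfg = short_cfg()),
               "aligned")
})
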