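test_that("Pareto domination is strict and direction-aware", {
  expect_true(dominates(c(1, 1, 1), c(2, 2, 2)))
  expect_false(dominates(c(2, 2, 2), c(1, 1, 1)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(1, 2)))          # equality never dominates
  expect_true(dominates(c(1, 5), c(2, 3), directions = c("min", "max")))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("domination amount multiplies normalized differences of differing objectives", {
  expect_equal(domination_amount(c(1, 2), c(1, 2)), 0)
  expect_equal(domination_amount(c(0, 0), c(1, 1), ranges = c(1, 1)), 1)
  # equal components stay out of the product
  expect_equal(domination_amount(c(0, 0.5), c(1, 0.5), ranges = c(1, 1)), 1)
  expect_equal(domination_amount(c(0, 0), c(2, 3), ranges = c(2, 3)), 1)
  expect_equal(domination_amount(c(0, 0), c(1, 3), ranges = c(2, 3)), 0.5)
  # the Inf sentinel contributes the maximal factor instead of NaN
  expect_equal(domination_amount(c(0, 0), c(Inf, 3), ranges = c(2, 3)), 1)
  expect_equal(domination_amount(c(Inf, 0), c(Inf, 3), ranges = c(2, 3)), 1)
})

test_that("archive insertion enforces mutual non-domination and the size limits", {
  arch <- cmvmc:::new_archive(sl = 10L, hl = 5L)
  arch <- archive_insert(arch, "a", c(2, 2))
  arch <- archive_insert(arch, "b", c(1, 3))
  expect_length(arch$members, 2L)

  # a dominating newcomer sweeps the archive
  arch2 <- archive_insert(arch, "c", c(0.5, 0.5))
  expect_length(arch2$members, 1L)
  expect_equal(arch2$members[[1]]$solution, "c")

  # a dominated newcomer is rejected
  arch3 <- archive_insert(arch2, "d", c(1, 1))
  expect_length(arch3$members, 1L)

  # an exact duplicate of an existing objective vector is rejected
  arch4 <- archive_insert(arch2, "e", c(0.5, 0.5))
  expect_length(arch4$members, 1L)

  # exceeding SL triggers clustering down to HL
  arch5 <- cmvmc:::new_archive(sl = 3L, hl = 2L)
  pts <- list(c(0, 10), c(3, 6), c(6, 3), c(10, 0))
  for (i in seq_along(pts))
    arch5 <- archive_insert(arch5, paste0("s", i), pts[[i]])
  expect_length(arch5$members, 2L)
})

test_that("annealing solves a single-objective convex toy problem", {
  problem <- list(
    initial = function() runif(1, -10, 10),
    perturb = function(x) x + rnorm(1, 0, 0.5),
    evaluate = function(x) (x - 3)^2)
  set.seed(1)
  arch <- anneal(problem, amosa_config(tmax = 10, tmin = 1e-3,
                                       iters_per_temp = 25L))
  best <- arch$members[[which.min(archive_objectives(arch)[, 1])]]$solution
  expect_lt(abs(best - 3), 0.1)
})

test_that("annealing recovers the analytic Pareto set of a biobjective toy", {
  problem <- list(
    initial = function() runif(1, -2, 3),
    perturb = function(x) x + rnorm(1, 0, 0.2),
    evaluate = function(x) c(x^2, (1 - x)^2))
  set.seed(2)
  arch <- anneal(problem, amosa_config(tmax = 10, tmin = 1e-3,
                                       iters_per_temp = 25L))
  xs <- unlist(lapply(arch$members, `[[`, "solution"))
  expect_true(all(xs >= -0.05 & xs <= 1.05))
  expect_gt(length(xs), 1L)
})

test_that("the archive is pairwise non-dominated after every seeded run", {
  problem <- list(
    initial = function() runif(2, -1, 2),
    perturb = function(x) x + rnorm(2, 0, 0.3),
    evaluate = function(x) c(sum(x^2), sum((x - 1)^2)))
  for (s in 1:20) {
    set.seed(s)
    arch <- anneal(problem, amosa_config(tmax = 5, tmin = 0.05,
                                         iters_per_temp = 10L))
    obj <- archive_objectives(arch)
    for (i in seq_len(nrow(obj))) for (j in seq_len(nrow(obj))) {
      if (i != j) expect_false(dominates(obj[i, ], obj[j, ]))
    }
  }
})

test_that("annealing is reproducible under a fixed seed", {
  problem <- list(
    initial = function() runif(1, -5, 5),
    perturb = function(x) x + rnorm(1),
    evaluate = function(x) c(x^2, (x - 2)^2))
  a1 <- anneal(problem, short_cfg(), seed = 99)
  a2 <- anneal(problem, short_cfg(), seed = 99)
  expect_identical(archive_objectives(a1), archive_objectives(a2))
})

test_that("tmax = tmin runs exactly one temperature level", {
  evals <- 0L
  problem <- list(
    initial = function() 0,
    perturb = function(x) x + rnorm(1),
    evaluate = function(x) { evals <<- evals + 1L; x^2 })
  set.seed(3)
  cfg <- amosa_config(tmax = 1, tmin = 1, iters_per_temp = 7L, n_init = 2L)
  anneal(problem, cfg)
  expect_equal(evals, 2L + 7L)
})

test_that("a failing evaluation discards the move and annealing continues", {
  problem <- list(
    initial = function() 1,
    perturb = function(x) x + rnorm(1),
    evaluate = function(x) {
      if (x < 0) stop("infeasible region")
      x^2
    })
  set.seed(4)
  expect_no_error(suppressMessages(
    arch <- anneal(problem, short_cfg())))
  expect_gt(length(arch$members), 0L)
})

test_that("maximized objectives are negated internally and restored on output", {
  problem <- list(
    initial = function() runif(1, 0, 1),
    perturb = function(x) min(max(x + rnorm(1, 0, 0.2), 0), 1),
    evaluate = function(x) c(x, x))     # min first, max second: conflict-free
  set.seed(5)
  arch <- anneal(problem, short_cfg(), directions = c("min", "max"))
  obj <- archive_objectives(arch)
  expect_true(all(obj[, 2] >= 0))       # raw scale restored, not negated
})
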