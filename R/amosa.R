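# Archived Multi-Objective Simulated Annealing. The engine is generic: a
# problem supplies initial(), perturb(solution) and evaluate(solution) (the
# latter returning a numeric objective vector), and the engine owns Pareto
# domination, the temperature schedule, the probabilistic acceptance of
# dominated moves and a bounded non-dominated archive. All objectives are
# handled internally as minimization; maximized components are negated on
# the way in via `directions`.

#' AMOSA configuration
#'
#' Defaults follow the usual magnitudes for archived simulated annealing:
#' geometric cooling from `tmax` to `tmin` with factor `alpha`,
#' `iters_per_temp` moves per temperature level, a soft archive limit `sl`
#' pruned down to the hard limit `hl` by single-linkage clustering of
#' objective vectors, and `n_init` evaluated random solutions seeding the
#' archive.
#'
#' @param tmax,tmin initial and final temperature, `tmax >= tmin > 0`.
#' @param alpha geometric cooling factor in (0, 1).
#' @param iters_per_temp moves per temperature level (>= 1).
#' @param sl,hl soft and hard archive limits, `sl >= hl >= 2`.
#' @param n_init size of the random initial population.
#' @return list of class `amosa_config`.
#' @export
amosa_config <- function(tmax = 100, tmin = 1e-4, alpha = 0.9,
                         iters_per_temp = 50L, sl = 40L, hl = 20L,
                         n_init = 10L) {
  stopifnot(tmax >= tmin, tmin > 0, alpha > 0, alpha < 1,
            iters_per_temp >= 1, sl >= hl, hl >= 2, n_init >= 1)
  structure(list(tmax = tmax, tmin = tmin, alpha = alpha,
                 iters_per_temp = as.integer(iters_per_temp),
                 sl = as.integer(sl), hl = as.integer(hl),
                 n_init = as.integer(n_init)),
            class = "amosa_config")
}

to_min <- function(values, directions) {
  if (is.null(directions)) return(values)
  if (length(directions) != length(values))
    stop("directions length must match the objective vector length")
  ifelse(directions == "max", -values, values)
}

#' Pareto domination between objective vectors
#'
#' `a` dominates `b` iff, after converting maximized components to
#' minimization, `a` is no worse in every objective and strictly better in
#' at least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @param directions optional per-component `"min"`/`"max"`; all-min when
#'   omitted.
#' @return logical.
#' @export
dominates <- function(a, b, directions = NULL) {
  if (length(a) != length(b))
    stop("objective vectors differ in length: ", length(a), " vs ", length(b))
  a <- to_min(a, directions); b <- to_min(b, directions)
  all(a <= b) && any(a < b)
}

#' Amount of domination between two objective vectors
#'
#' Product over the objectives in which `a` and `b` differ of the normalized
#' absolute difference `|a_i - b_i| / range_i`; 0 when the vectors are equal
#' in every objective. A differing pair involving a non-finite value (the
#' Xie-Beni degeneracy sentinel) contributes the maximal factor 1.
#'
#' @param a,b numeric objective vectors (minimization form).
#' @param ranges per-objective normalization ranges (observed spread).
#' @return non-negative real.
#' @export
domination_amount <- function(a, b, ranges = rep(1, length(a))) {
  if (length(a) != length(b))
    stop("objective vectors differ in length")
  diffs <- abs(a - b)
  differ <- (a != b)
  differ[is.na(differ)] <- TRUE   # Inf vs Inf compares NA after subtraction
  differ <- differ & !(is.infinite(a) & is.infinite(b) & sign(a) == sign(b))
  if (!any(differ)) return(0)
  f <- diffs[differ] / pmax(ranges[differ], 1e-12)
  f[!is.finite(f)] <- 1
  prod(f)
}

new_archive <- function(sl, hl) {
  structure(list(members = list(), sl = sl, hl = hl, next_id = 1L),
            class = "amosa_archive")
}

#' @export
print.amosa_archive <- function(x, ...) {
  cat("AMOSA archive:", length(x$members), "non-dominated solution(s)\n")
  invisible(x)
}

#' Objective vectors of an archive
#'
#' @param archive an `amosa_archive`.
#' @return matrix, one row per member, raw (direction-preserving) objectives.
#' @export
archive_objectives <- function(archive) {
  do.call(rbind, lapply(archive$members, `[[`, "objectives"))
}

prune_archive <- function(archive, ranges, limit = archive$sl) {
  m <- length(archive$members)
  if (m <= limit) return(archive)
  obj <- do.call(rbind, lapply(archive$members, `[[`, "obj_min"))
  scl <- sweep(obj, 2L, pmax(ranges, 1e-12), "/")
  scl[!is.finite(scl)] <- 0
  cl <- stats::cutree(stats::hclust(stats::dist(scl), method = "single"),
                      k = archive$hl)
  keep <- integer(0)
  for (k in sort(unique(cl))) {
    idx <- which(cl == k)
    cen <- colMeans(scl[idx, , drop = FALSE])
    d2 <- rowSums((scl[idx, , drop = FALSE] -
                     matrix(cen, length(idx), ncol(scl), byrow = TRUE))^2)
    ins <- vapply(archive$members[idx], `[[`, integer(1), "id")
    keep <- c(keep, idx[order(d2, ins)[1L]])   # ties by insertion order
  }
  archive$members <- archive$members[sort(keep)]
  archive
}

#' Insert a solution into an AMOSA archive
#'
#' Members dominated by the newcomer are removed; a newcomer dominated by
#' any member is rejected, as is one whose objective vector exactly equals
#' an existing member's (the archive keeps one representative per point of
#' the front); when the archive then exceeds its soft limit it is pruned to
#' the hard limit by single-linkage clustering of objective vectors,
#' keeping the member closest to each cluster centroid (ties by insertion
#' order).
#'
#' @param archive an `amosa_archive` (see [anneal()]).
#' @param solution arbitrary solution object.
#' @param obj_min its objective vector in minimization form.
#' @param objectives raw (direction-preserving) objectives to store;
#'   defaults to `obj_min`.
#' @param ranges per-objective normalization for the pruning step.
#' @return the updated archive.
#' @export
archive_insert <- function(archive, solution, obj_min,
                           objectives = obj_min,
                           ranges = rep(1, length(obj_min))) {
  stopifnot(inherits(archive, "amosa_archive"))
  for (mem in archive$members)
    if (identical(mem$obj_min, obj_min) || dominates(mem$obj_min, obj_min))
      return(archive)
  dominated <- vapply(archive$members, function(mem)
    dominates(obj_min, mem$obj_min), logical(1))
  if (length(dominated)) archive$members <- archive$members[!dominated]
  archive$members[[length(archive$members) + 1L]] <-
    list(solution = solution, objectives = objectives, obj_min = obj_min,
         id = archive$next_id)
  archive$next_id <- archive$next_id + 1L
  prune_archive(archive, ranges)
}

#' Run archived multi-objective simulated annealing
#'
#' Implements the AMOSA case analysis. At each move a perturbed solution is
#' compared with the current solution and the archive: moves to dominated
#' solutions are accepted with probability `1 / (1 + exp(dom_avg / T))`
#' where `dom_avg` is the mean amount of domination by the current solution
#' and any dominating archive members, so worse moves are taken freely at
#' high temperature and almost never near the end of the schedule.
#' Non-dominated or dominating solutions always become current and enter the
#' archive (evicting members they dominate). When a move dominates the
#' current solution but is itself dominated in the archive, the engine jumps
#' either to the move or to its least-dominating archive member. Objective
#' ranges used for normalization are tracked as running min/max over all
#' evaluations.
#'
#' Solutions raising an error in `evaluate` are discarded (with a message)
#' and annealing continues.
#'
#' @param problem list with callables `initial()`, `perturb(solution)` and
#'   `evaluate(solution)`; `evaluate` returns a numeric objective vector of
#'   fixed length.
#' @param cfg an [amosa_config()].
#' @param directions per-objective `"min"`/`"max"`; all-min when omitted.
#' @param seed optional integer seed (applied via `set.seed`).
#' @return the final `amosa_archive`; member `objectives` are raw
#'   (direction-preserving) vectors.
#' @export
anneal <- function(problem, cfg = amosa_config(), directions = NULL,
                   seed = NULL) {
  stopifnot(is.function(problem$initial), is.function(problem$perturb),
            is.function(problem$evaluate), inherits(cfg, "amosa_config"))
  if (!is.null(seed)) set.seed(seed)
  run_min <- NULL; run_max <- NULL
  track <- function(v) {
    fin <- is.finite(v)
    if (is.null(run_min)) {
      run_min <<- ifelse(fin, v, Inf); run_max <<- ifelse(fin, v, -Inf)
    } else {
      run_min <<- ifelse(fin & v < run_min, v, run_min)
      run_max <<- ifelse(fin & v > run_max, v, run_max)
    }
  }
  ranges <- function() {
    r <- run_max - run_min
    r[!is.finite(r) | r <= 0] <- 1
    r
  }
  eval_min <- function(s) to_min(problem$evaluate(s), directions)

  archive <- new_archive(cfg$sl, cfg$hl)
  for (i in seq_len(cfg$n_init)) {
    s <- problem$initial()
    o <- eval_min(s)
    track(o)
    archive <- archive_insert(archive, s, o, ranges = ranges())
  }
  if (!length(archive$members)) stop("no evaluable initial solution")
  cur <- archive$members[[sample.int(length(archive$members), 1L)]]
  current <- cur$solution; cur_obj <- cur$obj_min

  temp <- cfg$tmax
  while (temp >= cfg$tmin) {
    for (it in seq_len(cfg$iters_per_temp)) {
      new_sol <- problem$perturb(current)
      new_obj <- tryCatch(eval_min(new_sol), error = function(e) {
        message("discarding failed perturbation: ", conditionMessage(e))
        NULL
      })
      if (is.null(new_obj)) next
      track(new_obj)
      rg <- ranges()
      dom_by <- which(vapply(archive$members, function(mem)
        dominates(mem$obj_min, new_obj), logical(1)))
      if (dominates(cur_obj, new_obj)) {
        # case 1: move is dominated by current (and possibly the archive)
        amounts <- c(domination_amount(cur_obj, new_obj, rg),
                     vapply(dom_by, function(i)
                       domination_amount(archive$members[[i]]$obj_min,
                                         new_obj, rg), numeric(1)))
        if (stats::runif(1) < 1 / (1 + exp(mean(amounts) / temp))) {
          current <- new_sol; cur_obj <- new_obj
        }
      } else if (dominates(new_obj, cur_obj)) {
        # case 3: move dominates current
        if (length(dom_by)) {
          amounts <- vapply(dom_by, function(i)
            domination_amount(archive$members[[i]]$obj_min, new_obj, rg),
            numeric(1))
          best <- dom_by[which.min(amounts)]
          if (stats::runif(1) < 1 / (1 + exp(-min(amounts)))) {
            current <- archive$members[[best]]$solution
            cur_obj <- archive$members[[best]]$obj_min
          } else {
            current <- new_sol; cur_obj <- new_obj
          }
        } else {
          archive <- archive_insert(archive, new_sol, new_obj, ranges = rg)
          current <- new_sol; cur_obj <- new_obj
        }
      } else {
        # case 2: current and move are mutually non-dominating
        if (length(dom_by)) {
          amounts <- vapply(dom_by, function(i)
            domination_amount(archive$members[[i]]$obj_min, new_obj, rg),
            numeric(1))
          if (stats::runif(1) < 1 / (1 + exp(mean(amounts) / temp))) {
            current <- new_sol; cur_obj <- new_obj
          }
        } else {
          archive <- archive_insert(archive, new_sol, new_obj, ranges = rg)
          current <- new_sol; cur_obj <- new_obj
        }
      }
    }
    temp <- temp * cfg$alpha
  }
  # the delivered solution set is at most HL, as in archived simulated
  # annealing: cluster the final archive down when it ends oversized
  archive <- prune_archive(archive, ranges(), limit = cfg$hl)
  if (!is.null(directions))
    archive$members <- lapply(archive$members, function(mem) {
      mem$objectives <- ifelse(directions == "max", -mem$obj_min, mem$obj_min)
      mem
    })
  archive
}
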