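# Screening criteria: predicates on an evaluate_design() result.

# All listed aggregate |relative errors| within their thresholds.
# `thresholds` is a named vector, e.g. c(NON = 0.10, ADV = 0.10, CRC = 0.05).
crit_aggregate <- function(thresholds) {
  force(thresholds)
  function(ev) {
    re <- ev$agg_rel_err[names(thresholds)]
    all(!is.na(re)) && all(abs(re) <= thresholds)
  }
}

# Every usable per-age-group |relative error| (all states x groups) within
# one threshold.
crit_per_group <- function(threshold) {
  force(threshold)
  function(ev) {
    re <- ev$group_rel_err
    any(!is.na(re)) && max(abs(re), na.rm = TRUE) <= threshold
  }
}

#' Latin hypercube sample of parameter designs
#'
#' Draws `n` designs from a [design_space()] by Latin hypercube sampling
#' in natural coordinates: each parameter's range is cut into `n`
#' equal-width strata and each stratum is hit exactly once, with
#' independent stratum permutations across parameters.
#'
#' @param space a [design_space()].
#' @param n number of designs.
#' @param seed integer seed (draws are reproducible; the caller's RNG
#'   state is untouched).
#' @return An `n x p` numeric matrix, columns named after the parameters.
#' @examples
#' sp <- design_space(baseline_design("cycle", "male"))
#' dim(lhs_sample(sp, 10, seed = 1))
#' @export
lhs_sample <- function(space, n, seed = 1L) {
  stopifnot(inherits(space, "design_space"), n >= 1)
  if (any(space$lower >= space$upper)) {
    stop("degenerate search range in design space", call. = FALSE)
  }
  preserve_rng()
  set.seed(check_seed(seed))
  u <- lhs::randomLHS(n, nrow(space))
  out <- sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower,
               `+`)
  colnames(out) <- space$name
  out
}

#' Screen designs in sampling order, returning the first acceptable one
#'
#' Evaluates the rows of `designs` in order and returns the first design
#' whose three aggregate relative errors are all within `threshold` (10%
#' by default).  If no design passes, the minimum-loss design among all
#' evaluated is returned with the `fallback` flag set.  This is the
#' phase-1 procedure for the cycle engine: LHS 100 designs over the +/-20%
#' space, take the first that fits.
#'
#' @param space the [design_space()] the rows of `designs` live in.
#' @param designs matrix of candidate designs (rows), e.g. from
#'   [lhs_sample()].
#' @param evaluator a [make_evaluator()] closure.
#' @param threshold aggregate relative-error bound.
#' @param states aggregate states the criterion applies to.
#' @return A `phase1_result`: list with `design` (typed), `loss`,
#'   `evaluations`, `passed`, `fallback`, `max_agg_rel_err` and the
#'   evaluation `log`.
#' @export
screen_first_passing <- function(space, designs, evaluator,
                                 threshold = 0.10,
                                 states = c("NON", "ADV", "CRC")) {
  crit <- crit_aggregate(stats::setNames(rep(threshold, length(states)),
                                         states))
  losses <- numeric(0)
  evs <- list()
  hit <- NA_integer_
  for (j in seq_len(nrow(designs))) {
    d <- space_design(space, designs[j, ])
    ev <- evaluator(d)
    losses[j] <- ev$loss
    evs[[j]] <- ev
    if (crit(ev)) { hit <- j; break }
  }
  fallback <- is.na(hit)
  pick <- if (fallback) which.min(losses) else hit
  structure(list(design = space_design(space, designs[pick, ]),
                 loss = losses[pick],
                 evaluations = length(losses),
                 passed = !fallback,
                 fallback = fallback,
                 max_agg_rel_err = max(abs(evs[[pick]]$agg_rel_err[states])),
                 log = data.frame(index = seq_along(losses),
                                  loss = losses)),
            class = "phase1_result")
}

# Evaluate a set of pair values (matrix cols = the 2 pair parameters) with
# the other coordinates frozen at `incumbent`; common helper for the grid
# and orthogonal stages.
eval_pair_candidates <- function(space, pair, values, incumbent, evaluator) {
  lapply(seq_len(nrow(values)), function(j) {
    x <- as.numeric(incumbent)
    names(x) <- space$name
    x[pair] <- values[j, ]
    ev <- evaluator(space_design(space, x))
    list(values = values[j, ], design = x, ev = ev)
  })
}

pair_bounds <- function(space, pair) {
  i <- match(pair, space$name)
  if (any(is.na(i))) stop("unknown pair parameters: ",
                          paste(pair, collapse = ", "), call. = FALSE)
  list(lower = space$lower[i], upper = space$upper[i])
}

#' Centered grid search over one parameter pair
#'
#' Evaluates an `n_grid x n_grid` grid (default 5x5, 25 evaluations) over
#' the bounds of the two named parameters, all other parameters frozen at
#' `incumbent`.  With an odd `n_grid` and the default symmetric ranges the
#' centre node is the incumbent itself.  A candidate is accepted when
#' every per-age-group relative error (all states and groups, 15 cells for
#' three states and five groups) is within `threshold`.
#'
#' @param space a [design_space()].
#' @param pair character vector of the two parameter names (e.g.
#'   `c("delta0", "gamma0")`).
#' @param evaluator a [make_evaluator()] closure.
#' @param incumbent design values to freeze the other parameters at
#'   (default the baseline).
#' @param n_grid nodes per dimension.
#' @param threshold per-age-group relative-error bound.
#' @return A list with `accepted` (data.frame of passing pair values and
#'   losses), `best` (the carried-forward pair values: min-loss accepted,
#'   or min-loss overall with `fallback = TRUE` if none pass), `design`
#'   (full design vector with `best` substituted), `loss`, `evaluations`,
#'   `fallback`.
#' @export
grid_search_pair <- function(space, pair, evaluator,
                             incumbent = space$baseline, n_grid = 5,
                             threshold = 0.15) {
  b <- pair_bounds(space, pair)
  g1 <- seq(b$lower[1], b$upper[1], length.out = n_grid)
  g2 <- seq(b$lower[2], b$upper[2], length.out = n_grid)
  values <- as.matrix(expand.grid(g1, g2, KEEP.OUT.ATTRS = FALSE))
  colnames(values) <- pair
  select_pair_stage(space, pair, values, incumbent, evaluator,
                    crit_per_group(threshold))
}

#' Orthogonally stratified sample over one parameter pair
#'
#' Draws `n` points over the two named parameters' bounds such that each
#' of the `n` even intervals of each dimension is covered exactly once
#' (Latin-hypercube-style orthogonal stratification).
#'
#' @inheritParams grid_search_pair
#' @param n points (and intervals per dimension).
#' @param seed integer seed.
#' @return An `n x 2` matrix of pair values.
#' @export
orthogonal_sample_pair <- function(space, pair, n = 10, seed = 1L) {
  b <- pair_bounds(space, pair)
  if (any(b$lower >= b$upper)) stop("degenerate pair bounds", call. = FALSE)
  preserve_rng()
  set.seed(check_seed(seed))
  u <- lhs::randomLHS(n, 2)
  values <- cbind(b$lower[1] + u[, 1] * (b$upper[1] - b$lower[1]),
                  b$lower[2] + u[, 2] * (b$upper[2] - b$lower[2]))
  colnames(values) <- pair
  values
}

# Evaluate candidates for one stage and pick the carried-forward design:
# the min-loss criterion-passing candidate, the incumbent if it is better
# (and was already evaluated as `incumbent_ev`), or the min-loss candidate
# overall with the fallback flag when nothing passes.
select_pair_stage <- function(space, pair, values, incumbent, evaluator,
                              crit, incumbent_ev = NULL) {
  cands <- eval_pair_candidates(space, pair, values, incumbent, evaluator)
  if (!is.null(incumbent_ev)) {
    x <- as.numeric(incumbent)
    names(x) <- space$name
    cands <- c(cands, list(list(values = x[pair], design = x,
                                ev = incumbent_ev, is_incumbent = TRUE)))
  }
  losses <- vapply(cands, function(c) c$ev$loss, numeric(1))
  pass <- vapply(cands, function(c) crit(c$ev), logical(1))
  fallback <- !any(pass)
  pool <- if (fallback) seq_along(cands) else which(pass)
  pick <- pool[which.min(losses[pool])]
  accepted <- if (any(pass)) {
    data.frame(do.call(rbind, lapply(cands[pass], `[[`, "values")),
               loss = losses[pass])
  } else {
    data.frame()
  }
  n_eval <- nrow(values)   # the incumbent, if supplied, was not re-evaluated
  list(accepted = accepted,
       best = cands[[pick]]$values,
       design = cands[[pick]]$design,
       ev = cands[[pick]]$ev,
       loss = losses[pick],
       evaluations = n_eval,
       fallback = fallback)
}

#' Progressive (stage-wise) phase-1 search for the event engine
#'
#' The preliminary global search over the 8 Johnson SB shape parameters,
#' following the adenoma-carcinoma sequence: first a 5x5 centred grid on
#' the risk pair `(delta0, gamma0)` with every per-age-group relative
#' error within 15%; then 10-point orthogonal samples over
#' `(delta1, gamma1)` and `(delta2, gamma2)` (in that order — far more
#' `P_NON` than `NP_NON` adenomas transition to `ADV`), accepting
#' aggregate `NON` and `ADV` errors within 10%; finally a 10-point
#' orthogonal sample over `(delta3, gamma3)` accepting aggregate `NON`
#' and `ADV` within 10% and `CRC` within 5%.  Each stage freezes the
#' previously selected values, perturbs only its pair, and carries the
#' minimum-loss acceptable design forward (keeping the inherited design
#' when it is strictly better, so the incumbent loss never increases
#' between stages); a stage in which nothing passes falls back to its
#' minimum-loss candidate and sets the `fallback` flag.  The default plan
#' costs 25 + 10 + 10 + 10 = 55 evaluations.
#'
#' @param space a [design_space()] for the event engine.
#' @param evaluator a [make_evaluator()] closure.
#' @param seed integer seed for the orthogonal sampling stages.
#' @param n_grid grid nodes per dimension in stage 1.
#' @param n_orth points per orthogonal stage.
#' @return A `phase1_result`: `design`, `loss`, `evaluations`, `fallback`
#'   (any stage fell back), `stages` (per-stage summaries), and the final
#'   stage's evaluation details `ev`.
#' @export
progressive_search <- function(space, evaluator, seed = 1L, n_grid = 5,
                               n_orth = 10) {
  stopifnot(inherits(space, "design_space"),
            attr(space, "engine") == "event")
  plan <- list(
    list(pair = c("delta0", "gamma0"), method = "grid",
         crit = crit_per_group(0.15)),
    list(pair = c("delta1", "gamma1"), method = "orth",
         crit = crit_aggregate(c(NON = 0.10, ADV = 0.10))),
    list(pair = c("delta2", "gamma2"), method = "orth",
         crit = crit_aggregate(c(NON = 0.10, ADV = 0.10))),
    list(pair = c("delta3", "gamma3"), method = "orth",
         crit = crit_aggregate(c(NON = 0.10, ADV = 0.10, CRC = 0.05))))
  incumbent <- space$baseline
  incumbent_ev <- NULL
  stages <- list()
  total_eval <- 0L
  fallback <- FALSE
  for (k in seq_along(plan)) {
    st <- plan[[k]]
    values <- if (st$method == "grid") {
      b <- pair_bounds(space, st$pair)
      v <- as.matrix(expand.grid(seq(b$lower[1], b$upper[1],
                                     length.out = n_grid),
                                 seq(b$lower[2], b$upper[2],
                                     length.out = n_grid),
                                 KEEP.OUT.ATTRS = FALSE))
      colnames(v) <- st$pair
      v
    } else {
      orthogonal_sample_pair(space, st$pair, n = n_orth,
                             seed = hash_seed(seed, 3L, k))
    }
    res <- select_pair_stage(space, st$pair, values, incumbent, evaluator,
                             st$crit, incumbent_ev = incumbent_ev)
    incumbent <- res$design
    incumbent_ev <- res$ev
    total_eval <- total_eval + res$evaluations
    fallback <- fallback || res$fallback
    stages[[k]] <- list(pair = st$pair, accepted = res$accepted,
                        loss = res$loss, evaluations = res$evaluations,
                        fallback = res$fallback)
  }
  structure(list(design = space_design(space, incumbent),
                 loss = incumbent_ev$loss,
                 ev = incumbent_ev,
                 evaluations = total_eval,
                 passed = !fallback,
                 fallback = fallback,
                 stages = stages),
            class = "phase1_result")
}

#' @export
print.phase1_result <- function(x, ...) {
  cat(sprintf("<phase1_result> loss %.5g after %d evaluations (%s)\n",
              x$loss, x$evaluations,
              if (x$fallback) "fallback: criterion not met"
              else "criterion met"))
  invisible(x)
}
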