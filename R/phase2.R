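#' Block plan for the sequential local-search strategy
#'
#' Splits a design vector into an ordered list of parameter blocks with a
#' per-block evaluation budget.  The default order follows the declared
#' blocks of the design space, which encode the sensitivity ordering used
#' throughout: event engine `risk`, `p_non`, `np_non`, `adv`; cycle
#' engine `initiation`, `early`, `advanced`.  The total budget is split
#' equally, any remainder going to the first (most sensitive) block.
#'
#' @param space a [design_space()].
#' @param budget total evaluation budget across blocks.
#' @param blocks optional character vector reordering / subsetting the
#'   block labels.
#' @return A list with class `"block_plan"`: per block, the parameter
#'   indices and its budget.
#' @export
block_plan <- function(space, budget, blocks = unique(space$block)) {
  stopifnot(inherits(space, "design_space"), budget >= length(blocks))
  if (!setequal(blocks, unique(space$block))) {
    stop("blocks must be a permutation of the design-space blocks",
         call. = FALSE)
  }
  per <- budget %/% length(blocks)
  budgets <- rep(per, length(blocks))
  budgets[1] <- budgets[1] + budget - sum(budgets)
  structure(list(blocks = lapply(blocks, function(b)
                   which(space$block == b)),
                 labels = blocks, budgets = budgets, budget = budget),
            class = "block_plan")
}

#' Full-space local-search strategy
#'
#' One Nelder-Mead run over all parameters of the objective, from `x0`,
#' under a total evaluation budget.
#'
#' @param objective function of the full design vector returning a scalar
#'   loss.
#' @param x0 numeric start vector.
#' @param budget maximum objective evaluations.
#' @param opts an [nm_options()]; its `max_evaluations` is overridden by
#'   `budget`.
#' @return A `calibration_result` (see [nelder_mead()]).
#' @export
full_space_strategy <- function(objective, x0, budget,
                                opts = nm_options()) {
  opts$max_evaluations <- budget
  nelder_mead(objective, x0, opts)
}

#' Sequential (block-wise) local-search strategy
#'
#' Runs Nelder-Mead over one parameter block at a time, in the plan's
#' order, with all other coordinates frozen at the current incumbent;
#' each block run starts from the incumbent and its best vertex becomes
#' the next incumbent, so the chained loss never increases.  The returned
#' trajectory is the concatenation of the block trajectories (best-so-far
#' across the whole chain).
#'
#' @param objective function of the full design vector.
#' @param x0 numeric start vector.
#' @param plan a [block_plan()].
#' @param opts an [nm_options()].
#' @return A `calibration_result` with an extra `blocks` element giving
#'   per-block evaluations and losses.
#' @export
sequential_strategy <- function(objective, x0, plan, opts = nm_options()) {
  stopifnot(inherits(plan, "block_plan"))
  incumbent <- x0
  best_f <- Inf
  traj <- numeric(0)
  blocks_out <- list()
  for (k in seq_along(plan$blocks)) {
    idx <- plan$blocks[[k]]
    frozen <- incumbent
    sub_obj <- function(xb) {
      x <- frozen
      x[idx] <- xb
      objective(x)
    }
    o <- opts
    o$max_evaluations <- plan$budgets[k]
    res <- nelder_mead(sub_obj, incumbent[idx], o)
    incumbent[idx] <- res$par
    best_f <- min(best_f, res$value)
    traj <- c(traj, res$trajectory)
    blocks_out[[k]] <- list(label = plan$labels[k],
                            evaluations = res$evaluations,
                            value = res$value)
  }
  structure(list(par = incumbent, value = best_f,
                 evaluations = as.integer(
                   sum(vapply(blocks_out, `[[`, numeric(1),
                              "evaluations"))),
                 trajectory = cummin(traj),
                 converged = NA, blocks = blocks_out),
            class = "calibration_result")
}
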