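#' Calibrate an engine against targets under an evaluation budget
#'
#' The end-to-end recalibration driver.  Three strategies are available:
#'
#' * `"direct"` — straightforward full-space Nelder-Mead from the
#'   baseline design, spending the whole effort on the local search.
#' * `"two-phase-full"` — phase 1 (global sampling: LHS screening for the
#'   19-parameter cycle engine, the progressive grid + orthogonal plan
#'   for the 8-parameter event engine) to find a promising start, then
#'   full-space Nelder-Mead on the remaining budget.
#' * `"two-phase-seq"` — phase 1, then Nelder-Mead sequentially over the
#'   ordered parameter blocks (the sensitivity order of the design
#'   space), each block search freezing the other coordinates.
#'
#' One design evaluation (however many replications it averages) costs
#' one unit of effort, and phase-1 evaluations count against the same
#' budget.  The local search runs in unconstrained coordinates (log for
#' positive parameters, logit for per-cycle probabilities), so no
#' proposed design is ever invalid.
#'
#' @param baseline the starting `event_design` or `cycle_design` (the
#'   prior point estimate).
#' @param cohort a [cohort_spec()].
#' @param targets a `target_table`.
#' @param strategy one of `"direct"`, `"two-phase-full"`,
#'   `"two-phase-seq"`.
#' @param effort total evaluation budget.
#' @param seed integer seed: fixes the CRN streams of every evaluation
#'   and the phase-1 sampling.
#' @param R simulation replications per evaluation.
#' @param spec a [loss_spec()].
#' @param life life table.
#' @param space a [design_space()] around `baseline`.
#' @param n_lhs LHS designs for cycle-engine phase 1.
#' @param opts an [nm_options()] for phase 2.
#' @return A `calibration_run`: list with `strategy`, `design` (best
#'   found), `loss`, `evaluations` (named: phase1, phase2, total),
#'   `excluded` (phase 1 consumed the whole effort), `phase1`, `phase2`,
#'   and `trajectory` (data.frame: evaluation, loss, incumbent_loss,
#'   phase).
#' @examples
#' base <- baseline_design("event", "male")
#' tg <- generate_synthetic_targets(base, cohort_spec(n = 100), seed = 3)
#' r <- calibrate(base, cohort_spec(n = 100), tg, "direct", effort = 15,
#'                seed = 3)
#' r$loss
#' @export
calibrate <- function(baseline, cohort, targets,
                      strategy = c("direct", "two-phase-full",
                                   "two-phase-seq"),
                      effort = 100, seed = 1L, R = 1, spec = loss_spec(),
                      life = synthetic_life_table(cohort$birth_year),
                      space = design_space(baseline), n_lhs = 100,
                      opts = nm_options()) {
  strategy <- match.arg(strategy)
  stopifnot(effort >= 1)
  engine <- attr(space, "engine")
  evaluator <- make_evaluator(cohort, targets, spec = spec, R = R,
                              seed = seed, life = life)

  phase1 <- NULL
  incumbent <- space$baseline
  incumbent_loss <- NA_real_
  if (strategy != "direct") {
    phase1 <- if (engine == "cycle") {
      designs <- lhs_sample(space, min(n_lhs, effort), seed = seed)
      screen_first_passing(space, designs, evaluator)
    } else {
      progressive_search(space, evaluator, seed = seed)
    }
    incumbent <- as.numeric(phase1$design)
    incumbent_loss <- phase1$loss
  }
  p1_evals <- evaluator_count(evaluator)
  remaining <- effort - p1_evals
  excluded <- strategy != "direct" && remaining <= 0

  phase2 <- NULL
  if (!excluded) {
    objective <- function(xu) {
      evaluator(space_design(space, from_unconstrained(space, xu)))$loss
    }
    x0u <- to_unconstrained(space, incumbent)
    phase2 <- if (strategy == "two-phase-seq") {
      sequential_strategy(objective, x0u,
                          block_plan(space, remaining), opts)
    } else {
      full_space_strategy(objective, x0u, remaining, opts)
    }
  }

  log <- evaluator_log(evaluator)
  total <- evaluator_count(evaluator)
  trajectory <- data.frame(evaluation = seq_len(total),
                           loss = log$loss,
                           incumbent_loss = cummin(log$loss),
                           phase = rep(c("phase1", "phase2"),
                                       c(p1_evals, total - p1_evals)))
  # the reported solution is the best design ever evaluated in the run,
  # so the final loss equals the minimum of the trajectory
  best <- evaluator_best(evaluator)
  structure(list(strategy = strategy, design = best$design,
                 loss = best$loss,
                 evaluations = c(phase1 = p1_evals,
                                 phase2 = total - p1_evals,
                                 total = total),
                 excluded = excluded, phase1 = phase1, phase2 = phase2,
                 trajectory = trajectory),
            class = "calibration_run")
}

#' @export
print.calibration_run <- function(x, ...) {
  cat(sprintf("<calibration_run> %s: loss %.6g (%d evaluations: %d phase1 + %d phase2)%s\n",
              x$strategy, x$loss, x$evaluations[["total"]],
              x$evaluations[["phase1"]], x$evaluations[["phase2"]],
              if (x$excluded) " [excluded: phase 1 used the whole effort]"
              else ""))
  invisible(x)
}

#' Write a calibration trajectory as CSV
#'
#' Columns `evaluation_index`, `loss`, `incumbent_loss`, `phase` — the
#' input for convergence-profile plots.
#'
#' @param run a `calibration_run`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(run, path) {
  tr <- run$trajectory
  utils::write.csv(data.frame(evaluation_index = tr$evaluation,
                              loss = tr$loss,
                              incumbent_loss = tr$incumbent_loss,
                              phase = tr$phase),
                   path, row.names = FALSE)
  invisible(path)
}
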