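# Replication seed for replication k of a calibration run with CRN base
# `seed`.  Shared by design evaluation and synthetic-target generation, so
# running both with the same base seed uses identical random streams
# (common random numbers).
replication_seed <- function(seed, k) hash_seed(seed, 7L, k)

simulate_engine <- function(design, cohort, life, seed) {
  if (inherits(design, "event_design")) {
    simulate_event_cohort(design, cohort, life = life, seed = seed)
  } else {
    simulate_cycle_cohort(design, cohort, life = life, seed = seed)
  }
}

# Simulate R replications and return averaged per-group and aggregate
# prevalence (proportion scale).
simulate_prevalence <- function(design, cohort, life, R, seed,
                                groups = default_age_groups(),
                                weighted = TRUE) {
  tabs <- lapply(seq_len(R), function(k) {
    tr <- simulate_engine(design, cohort, life, replication_seed(seed, k))
    compute_prevalence(tr, groups)
  })
  agg <- rowMeans(vapply(tabs, aggregate_prevalence, numeric(3),
                         weighted = weighted))
  tab <- tabs[[1]]
  for (s in c("alive", "NON", "ADV", "CRC")) {
    tab[[s]] <- rowMeans(vapply(tabs, function(t) t[[s]],
                                numeric(nrow(tab))))
  }
  list(table = tab, aggregate = agg)
}

#' Evaluate a parameter design against calibration targets
#'
#' The single objective evaluation of the calibration problem: simulate
#' `R` replications of the cohort under `design` (with common random
#' numbers — the replication streams depend only on `seed` and the
#' replication index, not on the design), average the prevalences across
#' replications, and score the averaged aggregate prevalences against the
#' targets with the weighted sum-squared relative-error loss.  However
#' many replications are used, this counts as *one* function evaluation in
#' all budget accounting.
#'
#' @param design an `event_design` or `cycle_design`; the engine is
#'   inferred from the class.
#' @param cohort a [cohort_spec()].
#' @param targets a `target_table` (from [load_target_table()] or
#'   [generate_synthetic_targets()]).
#' @param spec a [loss_spec()]; its states are intersected with the states
#'   the targets carry.
#' @param R number of simulation replications averaged per evaluation.
#' @param seed CRN base seed.
#' @param life life table.
#' @return A list with elements `loss` (scalar), `aggregate` (predicted
#'   aggregate prevalences, percent), `agg_rel_err` (named signed relative
#'   errors on the aggregates), and `group_rel_err` (groups x states
#'   matrix of per-age-group relative errors; `NA` where the target cell
#'   is unusable).
#' @examples
#' base <- baseline_design("event", "male")
#' tg <- generate_synthetic_targets(base, cohort_spec(n = 200), R = 1,
#'                                  seed = 7)
#' evaluate_design(base, cohort_spec(n = 200), tg, R = 1, seed = 7)$loss
#' @export
evaluate_design <- function(design, cohort, targets, spec = loss_spec(),
                            R = 1, seed = 1L,
                            life = synthetic_life_table(cohort$birth_year)) {
  stopifnot(inherits(targets, "target_table"), R >= 1)
  states <- intersect(spec$states, targets$states)
  if (length(states) == 0L) stop("targets carry none of the loss states",
                                 call. = FALSE)
  spec_used <- loss_spec(w_non = spec$weights[["NON"]],
                         w_adv = spec$weights[["ADV"]],
                         w_crc = spec$weights[["CRC"]], states = states)
  sim <- simulate_prevalence(design, cohort, life, R, seed)
  pred_agg <- 100 * sim$aggregate               # percent, like the targets
  agg_re <- stats::setNames(
    relative_error(pred_agg[states], targets$aggregate[states]), states)
  grp <- vapply(states, function(s) {
    tgt <- targets$table[[s]]
    pred <- 100 * sim$table[[s]][match(targets$table$age_group,
                                       sim$table$age_group)]
    ifelse(tgt > 0, (pred - tgt) / tgt, NA_real_)
  }, numeric(nrow(targets$table)))
  grp <- matrix(grp, nrow = nrow(targets$table),
                dimnames = list(targets$table$age_group, states))
  list(loss = weighted_loss(pred_agg, targets$aggregate, spec_used),
       aggregate = pred_agg,
       agg_rel_err = agg_re,
       group_rel_err = grp)
}

#' Build a counting evaluator for the search procedures
#'
#' Wraps [evaluate_design()] into the closure interface the phase-1 and
#' phase-2 procedures consume: `f(design)` returns the evaluation list and
#' increments a shared evaluation counter, so budget accounting is exact
#' across phases.  The CRN base seed is fixed at construction: every
#' design is scored on identical random streams.
#'
#' @inheritParams evaluate_design
#' @return A function `f(design)`; `evaluator_count(f)` reads the number
#'   of evaluations performed and `evaluator_log(f)` the per-evaluation
#'   log (loss and aggregate relative errors).
#' @export
make_evaluator <- function(cohort, targets, spec = loss_spec(), R = 1,
                           seed = 1L,
                           life = synthetic_life_table(cohort$birth_year)) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  env$log <- list()
  env$best_loss <- Inf
  env$best_design <- NULL
  f <- function(design) {
    out <- evaluate_design(design, cohort, targets, spec = spec, R = R,
                           seed = seed, life = life)
    env$count <- env$count + 1L
    env$log[[env$count]] <- c(evaluation = env$count, loss = out$loss,
                              out$agg_rel_err)
    if (out$loss < env$best_loss) {
      env$best_loss <- out$loss
      env$best_design <- design
    }
    out
  }
  attr(f, "env") <- env
  f
}

#' @rdname make_evaluator
#' @param f an evaluator created by `make_evaluator`.
#' @export
evaluator_count <- function(f) attr(f, "env")$count

#' @rdname make_evaluator
#' @export
evaluator_best <- function(f) {
  env <- attr(f, "env")
  list(design = env$best_design, loss = env$best_loss)
}

#' @rdname make_evaluator
#' @export
evaluator_log <- function(f) {
  env <- attr(f, "env")
  if (env$count == 0L) return(NULL)
  as.data.frame(do.call(rbind, env$log))
}
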