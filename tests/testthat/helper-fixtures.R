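# Shared fixtures: everything is generated in code at test time.

tiny_cohort <- function(n = 60, sex = "male") cohort_spec(n = n, sex = sex)

# Hand-build a trace_statement from explicit death ages and adenoma records.
make_trace <- function(death_age, adenomas = NULL, sex = "male",
                       engine = "event") {
  if (is.null(adenomas)) {
    adenomas <- data.frame(id = integer(0), adenoma_index = integer(0),
                           class = character(0),
                           occurrence_age = numeric(0),
                           age_to_adv = numeric(0),
                           age_to_crc = numeric(0))
  }
  neocalib:::new_trace(engine = engine, seed = 0L,
                       cohort = cohort_spec(n = length(death_age), sex = sex),
                       death_age = death_age, adenomas = adenomas,
                       cycle_length = if (engine == "cycle") 0.25 else NULL)
}

# An evaluator stand-in that replays a script of aggregate relative-error
# vectors, ignoring the design it is handed.
scripted_evaluator <- function(script) {
  i <- 0L
  function(design) {
    i <<- i + 1L
    re <- script[[min(i, length(script))]]
    list(loss = sum(re^2), aggregate = NULL, agg_rel_err = re,
         group_rel_err = matrix(re, nrow = 1,
                                dimnames = list("55-59", names(re))))
  }
}

# A deterministic evaluator computed from the design itself: relative
# errors are (value - baseline)/baseline per parameter in `params`.
analytic_evaluator <- function(space, params,
                               states = c("NON", "ADV", "CRC")) {
  base <- stats::setNames(space$baseline, space$name)
  function(design) {
    v <- as.numeric(design)[match(params, names(design))]
    re <- (v - base[params]) / base[params]
    re <- stats::setNames(rep_len(re, length(states)), states)
    list(loss = sum(re^2), aggregate = NULL, agg_rel_err = re,
         group_rel_err = matrix(rep(re, each = 2), nrow = 2,
                                dimnames = list(c("55-59", "60-64"),
                                                states)))
  }
}

brenner_path <- function() {
  system.file("extdata", "brenner_targets.csv", package = "neocalib")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
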