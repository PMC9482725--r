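#' Build an individual's state-transition chart
#'
#' Converts one individual's adenoma records into a piecewise-constant map
#' from age to preclinical state on `[0, death_age)`.  The chart jumps
#' exactly at event ages, its value at any age equals
#' [classify_state()] at that age, and — because the state definitions are
#' cumulative ("has had") — it is non-decreasing in the precedence order
#' `HEALTHY < NON < ADV < CRC`.
#'
#' @param adenomas data.frame of one individual's adenoma records
#'   (`occurrence_age`, `age_to_adv`, `age_to_crc`; `NA` = censored), with
#'   events age-ordered within each adenoma.
#' @param death_age death age in years.
#' @return A data.frame with class `"state_chart"` and columns `from`,
#'   `to`, `state`: half-open intervals `[from, to)` covering
#'   `[0, death_age)`.
#' @examples
#' h <- data.frame(occurrence_age = 50, age_to_adv = 58, age_to_crc = 66)
#' build_state_chart(h, death_age = 80)
#' @export
build_state_chart <- function(adenomas, death_age) {
  stopifnot(is.numeric(death_age), death_age > 0)
  if (!is.null(adenomas) && nrow(adenomas) > 0L) {
    bad <- (!is.na(adenomas$age_to_adv) &
              adenomas$age_to_adv < adenomas$occurrence_age) |
      (!is.na(adenomas$age_to_crc) & !is.na(adenomas$age_to_adv) &
         adenomas$age_to_crc < adenomas$age_to_adv) |
      (!is.na(adenomas$age_to_crc) &
         adenomas$age_to_crc < adenomas$occurrence_age)
    if (any(bad)) stop("malformed trace: adenoma events out of order",
                       call. = FALSE)
  }
  t_non <- suppressWarnings(min(adenomas$occurrence_age, na.rm = TRUE))
  t_adv <- suppressWarnings(min(adenomas$age_to_adv, na.rm = TRUE))
  t_crc <- suppressWarnings(min(adenomas$age_to_crc, na.rm = TRUE))
  if (is.null(adenomas) || nrow(adenomas) == 0L) {
    t_non <- t_adv <- t_crc <- Inf
  }
  breaks <- c(0, t_non, min(t_adv, t_crc), t_crc, death_age)
  states <- c("HEALTHY", "NON", "ADV", "CRC")
  keep <- breaks[-5] < death_age & breaks[-5] < breaks[-1]
  # drop zero-length segments (e.g. ADV skipped by an immediate cancer)
  out <- data.frame(from = pmin(breaks[-5], death_age)[keep],
                    to = pmin(breaks[-1], death_age)[keep],
                    state = states[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("state_chart", "data.frame")
  out
}

default_age_groups <- function() {
  data.frame(label = c("55-59", "60-64", "65-69", "70-74", "75-79"),
             lower = c(55, 60, 65, 70, 75),
             upper = c(60, 65, 70, 75, 80),
             midpoint = c(57.5, 62.5, 67.5, 72.5, 77.5),
             stringsAsFactors = FALSE)
}

#' Compute age-group prevalence from a trace statement
#'
#' For each 5-year age group, evaluates every individual's state chart at
#' the group's midpoint age (57.5, 62.5, ... for the default groups) among
#' the individuals alive at that age, and reports the proportions in each
#' of the cumulative preclinical states `NON`, `ADV` and `CRC` together
#' with the alive count.  Because the cohort shares a single birth year,
#' the five age groups are five snapshots of the same cohort at increasing
#' ages.
#'
#' @param trace a `trace_statement` from either engine.
#' @param groups a data.frame of age groups with columns `label`, `lower`,
#'   `upper`, `midpoint`; default the five groups 55-59 ... 75-79.
#' @return A data.frame with class `"prevalence_table"`: columns
#'   `age_group`, `alive`, `NON`, `ADV`, `CRC` (proportions in `[0, 1]`),
#'   with one row per group.
#' @examples
#' tr <- simulate_event_cohort(baseline_design("event", "male"),
#'                             cohort_spec(n = 200), seed = 1)
#' compute_prevalence(tr)
#' @export
compute_prevalence <- function(trace, groups = default_age_groups()) {
  stopifnot(inherits(trace, "trace_statement"))
  fe <- first_entry_ages(trace)
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    a <- groups$midpoint[g]
    alive <- fe$death_age > a
    n_alive <- sum(alive)
    if (n_alive == 0L) {
      stop("degenerate cohort: no individual alive at age ", a,
           " (group ", groups$label[g], ")", call. = FALSE)
    }
    crc <- fe$t_crc[alive] <= a
    adv <- !crc & fe$t_adv[alive] <= a
    non <- !crc & !adv & fe$t_non[alive] <= a
    data.frame(age_group = groups$label[g], alive = n_alive,
               NON = mean(non), ADV = mean(adv), CRC = mean(crc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Aggregate prevalence over age groups
#'
#' Collapses a prevalence table to one value per state.  By default the
#' aggregate is the alive-count-weighted mean of the group values (so it
#' equals the prevalence in the pooled alive population); `weighted =
#' FALSE` gives the simple mean.
#'
#' @param table a `prevalence_table` (or target table with the same
#'   columns).
#' @param weighted weight groups by alive counts (default) or equally.
#' @return A named numeric vector `c(NON =, ADV =, CRC =)`.
#' @examples
#' tr <- simulate_event_cohort(baseline_design("event", "male"),
#'                             cohort_spec(n = 200), seed = 1)
#' aggregate_prevalence(compute_prevalence(tr))
#' @export
aggregate_prevalence <- function(table, weighted = TRUE) {
  stopifnot(all(c("NON", "ADV", "CRC") %in% names(table)))
  w <- if (weighted && !is.null(table$alive)) table$alive else
    rep(1, nrow(table))
  if (sum(w) <= 0) stop("cannot aggregate: zero total alive count",
                        call. = FALSE)
  vapply(c("NON", "ADV", "CRC"),
         function(s) sum(w * table[[s]]) / sum(w), numeric(1))
}

#' Read / write prevalence (or target) tables as CSV
#'
#' The shared on-disk dialect for predicted and target prevalence: columns
#' `sex`, `age_group`, `state`, `prevalence_percent` (percent scale), with
#' `age_group = "AGG"` rows holding the aggregates.
#'
#' @param table a `prevalence_table`.
#' @param sex value for the `sex` column.
#' @param path file path.
#' @param weighted passed to [aggregate_prevalence()] for the `AGG` rows.
#' @return `write_prevalence` returns `path` invisibly.
#' @export
write_prevalence <- function(table, sex, path, weighted = TRUE) {
  agg <- aggregate_prevalence(table, weighted = weighted)
  long <- rbind(
    do.call(rbind, lapply(c("NON", "ADV", "CRC"), function(s) {
      data.frame(sex = sex, age_group = table$age_group, state = s,
                 prevalence_percent = round(100 * table[[s]], 2))
    })),
    data.frame(sex = sex, age_group = "AGG", state = c("NON", "ADV", "CRC"),
               prevalence_percent = round(100 * agg, 2)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
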