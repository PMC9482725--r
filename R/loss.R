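#' Relative error between a prediction and a target
#'
#' `(pred - target) / target`, with both values on the same scale (percent
#' or proportion — the ratio is scale-free as long as the two agree).
#'
#' @param pred predicted value(s).
#' @param target target value(s); must be nonzero.
#' @return The signed relative error(s).
#' @examples
#' relative_error(6.25, 6.6)   # -0.05303
#' @export
relative_error <- function(pred, target) {
  if (any(target == 0)) {
    stop("relative error undefined for a zero target", call. = FALSE)
  }
  (pred - target) / target
}

#' Loss specification: weights on the three aggregate responses
#'
#' The calibration loss is the weighted sum of squared relative errors on
#' the aggregate `NON`, `ADV` and `CRC` prevalences.  The cancer weight
#' must exceed both others, so a mis-fit of the (rare but consequential)
#' cancerous state dominates; the default `(1, 1, 4)` realises that
#' ordering without drowning the other two states.
#'
#' @param w_non,w_adv,w_crc nonnegative weights; `w_crc` must be strictly
#'   larger than each of the other two.
#' @param states which states enter the loss; targets transcribed from the
#'   published registry table carry only `ADV` and `CRC`, in which case the
#'   loss runs in two-state mode.
#' @return A list with class `"loss_spec"`.
#' @examples
#' loss_spec()
#' @export
loss_spec <- function(w_non = 1, w_adv = 1, w_crc = 4,
                      states = c("NON", "ADV", "CRC")) {
  w <- c(NON = w_non, ADV = w_adv, CRC = w_crc)
  if (any(w < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  if (!(w_crc > w_adv && w_crc > w_non)) {
    stop("the CRC weight must exceed the NON and ADV weights",
         call. = FALSE)
  }
  states <- match.arg(states, several.ok = TRUE)
  structure(list(weights = w, states = states), class = "loss_spec")
}

#' Weighted sum-squared relative-error loss
#'
#' \eqn{L = \sum_s w_s \, ((p_s - t_s)/t_s)^2} over the states named in
#' `spec$states`.  Zero iff every used prediction equals its target (for
#' strictly positive weights), and invariant to a common rescaling of
#' predictions and targets (percent vs proportion).
#'
#' @param preds,targets named vectors holding (at least) the states used
#'   by `spec`; same scale.
#' @param spec a [loss_spec()].
#' @return A single nonnegative number.
#' @examples
#' weighted_loss(c(NON = 22, ADV = 9.0, CRC = 1.5),
#'               c(NON = 20, ADV = 8.9, CRC = 1.5))
#' @export
weighted_loss <- function(preds, targets, spec = loss_spec()) {
  stopifnot(inherits(spec, "loss_spec"))
  st <- spec$states
  if (!all(st %in% names(preds)) || !all(st %in% names(targets))) {
    stop("preds/targets must carry named values for states: ",
         paste(st, collapse = ", "), call. = FALSE)
  }
  re <- relative_error(as.numeric(preds[st]), as.numeric(targets[st]))
  sum(spec$weights[st] * re^2)
}

#' Load a calibration-target table
#'
#' Reads the shared CSV dialect (`sex`, `age_group`, `state`,
#' `prevalence_percent`) and returns, for one sex, a validated target
#' table in the same wide shape as a [compute_prevalence()] result, plus
#' the aggregate row.  The packaged fixture
#' `system.file("extdata", "brenner_targets.csv", package = "neocalib")`
#' transcribes the published German screening-colonoscopy registry
#' benchmarks (advanced adenoma and cancerous neoplasia, both sexes, ages
#' 55-79); it carries no `NON` column, so losses against it run in
#' two-state mode.
#'
#' @param path CSV path.
#' @param sex which sex's rows to load.
#' @return A list with class `"target_table"`: elements `table` (wide
#'   data.frame: `age_group` + one column per state, percent scale),
#'   `aggregate` (named vector, percent), `states`, `sex`, `provenance`.
#' @examples
#' path <- system.file("extdata", "brenner_targets.csv", package = "neocalib")
#' load_target_table(path, "male")$table
#' @export
load_target_table <- function(path, sex = c("male", "female")) {
  sex <- match.arg(sex)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_group", "state", "prevalence_percent")
  if (!all(need %in% names(raw))) {
    stop("target CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[raw$sex == sex, ]
  if (nrow(raw) == 0L) stop("no rows for sex '", sex, "'", call. = FALSE)
  if (any(!is.finite(raw$prevalence_percent))) {
    stop("non-numeric or missing target values", call. = FALSE)
  }
  if (any(raw$prevalence_percent <= 0)) {
    stop("targets must be strictly positive (relative errors divide by ",
         "them)", call. = FALSE)
  }
  states <- intersect(c("NON", "ADV", "CRC"), unique(raw$state))
  groups <- setdiff(unique(raw$age_group), "AGG")
  wide <- data.frame(age_group = groups, stringsAsFactors = FALSE)
  for (s in states) {
    sub <- raw[raw$state == s & raw$age_group != "AGG", ]
    v <- sub$prevalence_percent[match(groups, sub$age_group)]
    if (any(is.na(v))) stop("missing ", s, " cells in target table",
                            call. = FALSE)
    wide[[s]] <- v
  }
  agg_rows <- raw[raw$age_group == "AGG", ]
  agg <- if (nrow(agg_rows) > 0L) {
    stats::setNames(agg_rows$prevalence_percent, agg_rows$state)[states]
  } else {
    vapply(states, function(s) mean(wide[[s]]), numeric(1))
  }
  structure(list(table = wide, aggregate = agg, states = states, sex = sex,
                 provenance = attr(raw, "provenance")),
            class = "target_table")
}

#' @export
print.target_table <- function(x, ...) {
  cat(sprintf("<target_table> %s, states %s, %d age groups + aggregate\n",
              x$sex, paste(x$states, collapse = "/"), nrow(x$table)))
  print(x$table)
  invisible(x)
}
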