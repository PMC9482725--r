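# Trace statements: the common output of both engines.

new_trace <- function(engine, seed, cohort, death_age, adenomas,
                      cycle_length = NULL) {
  individuals <- data.frame(id = seq_len(cohort$n),
                            sex = cohort$sex,
                            birth_year = cohort$birth_year,
                            death_age = death_age,
                            stringsAsFactors = FALSE)
  structure(list(engine = engine, seed = seed, cohort = cohort,
                 cycle_length = cycle_length,
                 individuals = individuals, adenomas = adenomas),
            class = "trace_statement")
}

#' @export
print.trace_statement <- function(x, ...) {
  cat(sprintf(paste0("<trace_statement> %s engine, seed %d: %d %s ",
                     "individuals born %d, %d adenomas\n"),
              x$engine, x$seed, nrow(x$individuals), x$cohort$sex,
              x$cohort$birth_year, nrow(x$adenomas)))
  invisible(x)
}

#' Classify an individual's preclinical state at a given age
#'
#' Applies the cumulative ("has had") state definitions with precedence
#' `CRC > ADV > NON > HEALTHY` to one individual's adenoma records: `CRC`
#' if any adenoma has become cancerous by `age` (or the individual
#' developed CRC), `ADV` if any adenoma has advanced but none has become
#' cancerous, `NON` if any adenoma has occurred, else `HEALTHY`.  Only
#' events with event age `<= age` count, and states never revert.
#'
#' @param adenomas a data.frame of one individual's adenoma records with
#'   columns `occurrence_age`, `age_to_adv`, `age_to_crc` (`NA` =
#'   censored).
#' @param age query age in years.
#' @param death_age the individual's death age; querying beyond it is an
#'   error.
#' @return One of `"HEALTHY"`, `"NON"`, `"ADV"`, `"CRC"`.
#' @examples
#' h <- data.frame(occurrence_age = 50, age_to_adv = 58, age_to_crc = 66)
#' classify_state(h, 60, death_age = 80)
#' @export
classify_state <- function(adenomas, age, death_age = Inf) {
  stopifnot(is.numeric(age), length(age) == 1L)
  if (age > death_age) {
    stop("cannot classify at age ", age, ": individual died at ", death_age,
         call. = FALSE)
  }
  if (is.null(adenomas) || nrow(adenomas) == 0L) return("HEALTHY")
  if (any(!is.na(adenomas$age_to_crc) & adenomas$age_to_crc <= age)) {
    return("CRC")
  }
  if (any(!is.na(adenomas$age_to_adv) & adenomas$age_to_adv <= age)) {
    return("ADV")
  }
  if (any(adenomas$occurrence_age <= age)) return("NON")
  "HEALTHY"
}

#' Export / import a trace statement as TSV
#'
#' One row per event, columns `individual_id`, `sex`, `birth_year`,
#' `event`, `age_years` (4 decimals), `adenoma_index`.  Events are `BIRTH`,
#' `ADENOMA_P_NON` / `ADENOMA_NP_NON` / `ADENOMA_IMM`, `TO_ADV`, `TO_CRC`
#' and `DEATH`; `adenoma_index` is `NA` for `BIRTH` and `DEATH`.  The cycle
#' engine exports the same dialect: first-entry cycle times are converted
#' to ages on simulation.
#'
#' @param trace a `trace_statement`.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns
#'   the event data.frame (it does not reconstitute a full
#'   `trace_statement`).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_statement"))
  ind <- trace$individuals
  ad <- trace$adenomas
  occ_label <- c(P_NON = "ADENOMA_P_NON", NP_NON = "ADENOMA_NP_NON",
                 IMMEDIATE_CRC = "ADENOMA_IMM")[ad$class]
  adv <- !is.na(ad$age_to_adv)
  crc <- !is.na(ad$age_to_crc)
  rows <- rbind(
    data.frame(individual_id = ind$id, event = rep("BIRTH", nrow(ind)),
               age_years = 0, adenoma_index = NA_integer_),
    data.frame(individual_id = ad$id, event = unname(occ_label),
               age_years = ad$occurrence_age,
               adenoma_index = ad$adenoma_index),
    data.frame(individual_id = ad$id[adv],
               event = rep("TO_ADV", sum(adv)),
               age_years = ad$age_to_adv[adv],
               adenoma_index = ad$adenoma_index[adv]),
    data.frame(individual_id = ad$id[crc],
               event = rep("TO_CRC", sum(crc)),
               age_years = ad$age_to_crc[crc],
               adenoma_index = ad$adenoma_index[crc]),
    data.frame(individual_id = ind$id, event = rep("DEATH", nrow(ind)),
               age_years = ind$death_age, adenoma_index = NA_integer_))
  rows <- rows[order(rows$individual_id, rows$age_years,
                     match(rows$event, c("BIRTH", "ADENOMA_P_NON",
                                         "ADENOMA_NP_NON", "ADENOMA_IMM",
                                         "TO_ADV", "TO_CRC", "DEATH"))), ]
  out <- data.frame(individual_id = rows$individual_id,
                    sex = ind$sex[rows$individual_id],
                    birth_year = ind$birth_year[rows$individual_id],
                    event = rows$event,
                    age_years = sprintf("%.4f", rows$age_years),
                    adenoma_index = rows$adenoma_index)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "sex", "birth_year", "event", "age_years",
            "adenoma_index")
  if (!all(need %in% names(ev))) {
    stop("malformed trace file: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ev$age_years <- as.numeric(ev$age_years)
  ev
}

# Per-individual first-entry ages into NON / ADV / CRC (Inf if never).
# The vectorised backbone of prevalence extraction.
first_entry_ages <- function(trace) {
  n <- nrow(trace$individuals)
  ad <- trace$adenomas
  t_non <- rep(Inf, n); t_adv <- rep(Inf, n); t_crc <- rep(Inf, n)
  if (nrow(ad) > 0L) {
    agg <- function(val, id) {
      ok <- !is.na(val)
      if (!any(ok)) return(rep(Inf, n))
      m <- tapply(val[ok], factor(id[ok], levels = seq_len(n)), min)
      m[is.na(m)] <- Inf
      as.numeric(m)
    }
    t_non <- agg(ad$occurrence_age, ad$id)
    t_adv <- agg(ad$age_to_adv, ad$id)
    t_crc <- agg(ad$age_to_crc, ad$id)
  }
  data.frame(id = seq_len(n), death_age = trace$individuals$death_age,
             t_non = t_non, t_adv = t_adv, t_crc = t_crc)
}
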