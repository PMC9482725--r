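#' Read a calibration configuration file
#'
#' A YAML file with optional sections `engine` (`"event"` or `"cycle"`),
#' `sex`, `cohort` (`n_individuals`, `birth_year`, `end_age`), `space` (`rel`,
#' `rel_delta`), `loss` (`w_non`, `w_adv`, `w_crc`), `phase1` (`n_lhs`,
#' `n_grid`, `n_orth`), `phase2` (`strategy`, `effort`, `R`), `benchmark`
#' (`efforts`, `n_runs`, `R_targets`, `R_search`, `R_report`, `crn`),
#' `seed`, and optional paths `targets` (CSV) and `life_table` (CSV).
#' Missing entries take the package defaults.  Every run driven by the
#' command-line interface writes the fully resolved configuration next to
#' its outputs.
#'
#' @param path YAML file path; `NULL` gives the pure defaults.
#' @return A nested list of settings with class `"neocalib_config"`.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    engine = "event", sex = "male",
    cohort = list(n_individuals = 1000, birth_year = 1949, end_age = 79),
    space = list(rel = 0.2, rel_delta = 0.4),
    loss = list(w_non = 1, w_adv = 1, w_crc = 4),
    phase1 = list(n_lhs = 100, n_grid = 5, n_orth = 10),
    phase2 = list(strategy = "two-phase-seq", effort = 100, R = 1),
    benchmark = list(efforts = 100, n_runs = 10, R_targets = 1,
                     R_search = 1, R_report = 10, crn = FALSE),
    seed = 1, targets = NULL, life_table = NULL)
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(defaults, user)
  }
  if (!cfg$engine %in% c("event", "cycle")) {
    stop("config: engine must be 'event' or 'cycle'", call. = FALSE)
  }
  if (!cfg$sex %in% c("male", "female")) {
    stop("config: sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!cfg$phase2$strategy %in% c("direct", "two-phase-full",
                                  "two-phase-seq")) {
    stop("config: unknown phase2 strategy '", cfg$phase2$strategy, "'",
         call. = FALSE)
  }
  class(cfg) <- "neocalib_config"
  cfg
}

#' @rdname read_config
#' @param config a `neocalib_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Materialise the objects a config describes.
config_cohort <- function(cfg) {
  cohort_spec(n = cfg$cohort$n_individuals, sex = cfg$sex,
              birth_year = cfg$cohort$birth_year,
              end_age = cfg$cohort$end_age)
}

config_life <- function(cfg) {
  if (is.null(cfg$life_table)) {
    synthetic_life_table(cfg$cohort$birth_year)
  } else {
    read_life_table(cfg$life_table)
  }
}

config_loss_spec <- function(cfg, states = c("NON", "ADV", "CRC")) {
  loss_spec(w_non = cfg$loss$w_non, w_adv = cfg$loss$w_adv,
            w_crc = cfg$loss$w_crc, states = states)
}
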