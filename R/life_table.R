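#' Synthetic calendar-year life table
#'
#' Builds an all-cause life table of annual death probabilities `qx` indexed
#' by calendar year and age, from a Gompertz-Makeham hazard
#' \eqn{\mu(a) = A + B e^{\theta a}} with a constant per-calendar-year
#' mortality-improvement factor applied to the whole hazard.  The table is a
#' stand-in for published year-specific mortality risks: it is synthetic, but
#' its level and age slope are of the order of 20th-century US all-cause
#' mortality.  Age `max_age` is made absorbing (`qx = 1`).
#'
#' @param birth_year first calendar year covered (the cohort's birth year).
#' @param max_age last age covered; death is certain at this age.
#' @param makeham constant (age-independent) hazard component, per year.
#' @param gompertz_b,gompertz_theta level and log-slope of the age-dependent
#'   hazard component.
#' @param improvement proportional hazard reduction per calendar year
#'   (0.005 = 0.5% per year).
#'
#' @return A data.frame with columns `year`, `age`, `qx` covering every age
#'   `0..max_age` for the cohort born in `birth_year`, one row per age on
#'   the cohort diagonal (`year` equals `birth_year` plus `age`), with
#'   class `"life_table"`.
#' @examples
#' lt <- synthetic_life_table(1949)
#' lt[lt$age %in% c(0, 60, 80), ]
#' @export
synthetic_life_table <- function(birth_year = 1949, max_age = 100,
                                 makeham = 2e-4, gompertz_b = 3e-5,
                                 gompertz_theta = 0.086,
                                 improvement = 0.005) {
  age <- 0:max_age
  year <- birth_year + age
  haz <- (makeham + gompertz_b * exp(gompertz_theta * age)) *
    (1 - improvement)^(year - birth_year)
  qx <- 1 - exp(-haz)
  qx[age == max_age] <- 1
  lt <- data.frame(year = year, age = age, qx = qx)
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Read or write a life table as CSV
#'
#' The on-disk dialect is a plain CSV with header `year,age,qx`.
#'
#' @param path file path.
#' @param life a `life_table` data.frame.
#' @return `read_life_table` returns a validated `life_table`;
#'   `write_life_table` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  need <- c("year", "age", "qx")
  if (!all(need %in% names(lt))) {
    stop("life table must have columns year, age, qx", call. = FALSE)
  }
  lt <- lt[need]
  if (any(!is.finite(lt$qx)) || any(lt$qx < 0 | lt$qx > 1)) {
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' @rdname read_life_table
#' @export
write_life_table <- function(life, path) {
  utils::write.csv(as.data.frame(life), path, row.names = FALSE)
  invisible(path)
}

# Check that `life` covers ages 0..end_age for a cohort born in birth_year.
check_life_coverage <- function(life, birth_year, end_age) {
  age <- 0:ceiling(end_age)
  have <- paste(birth_year + age, age) %in% paste(life$year, life$age)
  if (!all(have)) {
    stop("life table does not cover all (year, age) pairs reachable by a ",
         "cohort born in ", birth_year, " up to age ", end_age, call. = FALSE)
  }
  invisible(NULL)
}

# Cumulative survival S(a) at integer ages 0..max for the cohort's diagonal
# of the life table; used to invert one uniform into a death age.
cohort_survival <- function(life, birth_year) {
  idx <- order(life$age)
  lt <- life[idx, ]
  lt <- lt[lt$year == birth_year + lt$age, ]
  c(1, cumprod(1 - lt$qx))
}

# Draw a continuous death age from one uniform: pick the death year from the
# discrete survival curve, then a uniform fraction within the year.
draw_death_age <- function(u_year, u_frac, surv) {
  yr <- findInterval(-u_year, -surv, rightmost.closed = TRUE)
  pmin(yr - 1 + u_frac, length(surv) - 1)
}
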