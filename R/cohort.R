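#' Specify a simulated birth cohort
#'
#' A cohort is a set of same-sex individuals sharing a single birth year,
#' followed from birth to `end_age` (or death, whichever comes first).  The
#' default matches the benchmark setting used throughout the package: 1000
#' individuals born in 1949 followed to age 79, so the five 5-year age
#' groups 55-59 ... 75-79 are observed as snapshots of the same cohort.
#'
#' @param n number of individuals (>= 1).
#' @param sex `"male"` or `"female"`.
#' @param birth_year calendar birth year.
#' @param end_age simulation horizon in years; must be at least 79 so all
#'   five evaluation age groups are reachable.
#' @return A list with class `"cohort_spec"`.
#' @examples
#' cohort_spec(n = 500, sex = "female")
#' @export
cohort_spec <- function(n = 1000, sex = c("male", "female"),
                        birth_year = 1949, end_age = 79) {
  sex <- match.arg(sex)
  stopifnot(n >= 1, n %% 1 == 0, end_age >= 79, birth_year %% 1 == 0)
  structure(list(n = as.integer(n), sex = sex,
                 birth_year = as.integer(birth_year), end_age = end_age),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d %s individuals, born %d, followed to age %g\n",
              x$n, x$sex, x$birth_year, x$end_age))
  invisible(x)
}
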