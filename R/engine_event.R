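#' Fixed constants of the event-based engine
#'
#' The non-calibrated structural constants of the discrete-event engine:
#' the age profile of the baseline adenoma-occurrence hazard, the class
#' probabilities splitting new adenomas into progressive non-advanced
#' (`P_NON`), non-progressive non-advanced (`NP_NON`) and immediately
#' cancerous (`IMMEDIATE_CRC`), and the Johnson SB supports (`xi = 0`,
#' width `lambda`) of the dwell-time distributions.  The occurrence hazard
#' is 0 before `hazard_start_age`, rises linearly to `hazard_plateau`
#' (per person-year, for an individual with risk multiplier 1) at
#' `hazard_plateau_age`, and is flat thereafter.  The `NP_NON` dwell
#' support is deliberately wide (60 y) so that most non-progressive
#' adenomas never advance within a lifetime.
#'
#' @param hazard_plateau plateau occurrence hazard, events per person-year.
#' @param hazard_start_age,hazard_plateau_age ages (years) delimiting the
#'   linear rise of the hazard.
#' @param class_probs probabilities of the three adenoma classes; must sum
#'   to 1.
#' @param dwell_lambda Johnson SB support widths (years) of the
#'   `P_NON -> ADV`, `NP_NON -> ADV` and `ADV -> CRC` dwell distributions.
#' @return A named list of engine constants.
#' @export
event_engine_constants <- function(hazard_plateau = 0.05,
                                   hazard_start_age = 20,
                                   hazard_plateau_age = 60,
                                   class_probs = c(P_NON = 0.30,
                                                   NP_NON = 0.69,
                                                   IMMEDIATE_CRC = 0.01),
                                   dwell_lambda = c(p_non = 30,
                                                    np_non = 60,
                                                    adv = 25)) {
  stopifnot(hazard_plateau >= 0,
            hazard_start_age < hazard_plateau_age,
            length(class_probs) == 3, all(class_probs >= 0),
            abs(sum(class_probs) - 1) < 1e-12,
            all(dwell_lambda > 0))
  list(hazard_plateau = hazard_plateau,
       hazard_start_age = hazard_start_age,
       hazard_plateau_age = hazard_plateau_age,
       class_probs = class_probs,
       dwell_lambda = dwell_lambda)
}

# Cumulative baseline occurrence hazard H(a) = int_0^a h(u) du.
event_cum_hazard <- function(age, constants) {
  a0 <- constants$hazard_start_age
  a1 <- constants$hazard_plateau_age
  hp <- constants$hazard_plateau
  ramp <- pmin(pmax(age - a0, 0), a1 - a0)
  flat <- pmax(age - a1, 0)
  hp * ramp^2 / (2 * (a1 - a0)) + hp * flat
}

# Inverse of event_cum_hazard (for sampling occurrence ages by inversion).
event_inv_cum_hazard <- function(H, constants) {
  a0 <- constants$hazard_start_age
  a1 <- constants$hazard_plateau_age
  hp <- constants$hazard_plateau
  Hramp <- hp * (a1 - a0) / 2
  ifelse(H <= Hramp,
         a0 + sqrt(2 * H * (a1 - a0) / hp),
         a1 + (H - Hramp) / hp)
}

#' Simulate a cohort with the event-based (dwell-time) engine
#'
#' Discrete-event natural-history simulation in the style of event-driven
#' CRC models: each individual draws a death age from the life table and a
#' lifetime adenoma-risk multiplier `r` from Johnson SB(`gamma0`, `delta0`)
#' on (0, 1); adenomas then occur as a nonhomogeneous Poisson process with
#' hazard `r * h(a)`.  Each adenoma is independently classed `P_NON`,
#' `NP_NON` or `IMMEDIATE_CRC`; non-advanced adenomas dwell a Johnson SB
#' time before advancing (`P_NON`: shapes `(gamma1, delta1)` on (0, 30) y;
#' `NP_NON`: `(gamma2, delta2)` on (0, 60) y), and advanced adenomas dwell
#' a Johnson SB time (`(gamma3, delta3)` on (0, 25) y) before becoming
#' cancerous.  Occurrence and growth of different adenomas are independent.
#' Transitions scheduled after the individual's death age or after the
#' cohort horizon are censored (recorded as `NA`).
#'
#' Each individual consumes a private random substream derived from `seed`
#' and their id, so the same seed always reproduces the same trace and
#' enlarging the cohort does not disturb earlier individuals.
#'
#' @param design an [event_design()] (8 parameters).
#' @param cohort a [cohort_spec()].
#' @param life a life table covering the cohort (default: the packaged
#'   synthetic table).
#' @param constants engine constants from [event_engine_constants()].
#' @param seed integer master seed.
#' @return A `trace_statement`: a list with elements `engine`, `seed`,
#'   `cohort`, `individuals` (id, sex, birth_year, death_age) and
#'   `adenomas` (id, adenoma_index, class, occurrence_age, age_to_adv,
#'   age_to_crc; `NA` = censored).
#' @examples
#' tr <- simulate_event_cohort(baseline_design("event", "male"),
#'                             cohort_spec(n = 50), seed = 1)
#' head(tr$adenomas)
#' @export
simulate_event_cohort <- function(design, cohort,
                                  life = synthetic_life_table(cohort$birth_year),
                                  constants = event_engine_constants(),
                                  seed = 1L) {
  if (!inherits(design, "event_design")) design <- event_design(design)
  stopifnot(inherits(cohort, "cohort_spec"))
  seed <- check_seed(seed)
  check_life_coverage(life, cohort$birth_year, cohort$end_age)
  preserve_rng()

  surv <- cohort_survival(life, cohort$birth_year)
  neg_surv <- -surv
  age_cap <- length(surv) - 1
  d <- as.numeric(design)
  names(d) <- names(design)
  g0 <- d[["gamma0"]]; d0 <- d[["delta0"]]
  g1 <- d[["gamma1"]]; d1 <- d[["delta1"]]
  g2 <- d[["gamma2"]]; d2 <- d[["delta2"]]
  g3 <- d[["gamma3"]]; d3 <- d[["delta3"]]
  lam1 <- constants$dwell_lambda[["p_non"]]
  lam2 <- constants$dwell_lambda[["np_non"]]
  lam3 <- constants$dwell_lambda[["adv"]]
  a0 <- constants$hazard_start_age
  a1 <- constants$hazard_plateau_age
  hp <- constants$hazard_plateau
  h_ramp <- hp * (a1 - a0) / 2
  cp <- cumsum(constants$class_probs)
  end_age <- cohort$end_age
  n <- cohort$n

  death_age <- numeric(n)
  cap <- max(16L, 4L * n)
  a_id <- integer(cap); a_occ <- numeric(cap)
  a_cls <- integer(cap); a_adv <- numeric(cap); a_crc <- numeric(cap)
  m <- 0L

  for (i in seq_len(n)) {
    set.seed(hash_seed(seed, 1L, i))
    u <- stats::runif(2)
    yr <- findInterval(-u[1], neg_surv, rightmost.closed = TRUE)
    death <- min(yr - 1 + u[2], age_cap)
    death_age[i] <- death
    z <- stats::rnorm(1)
    r <- 1 / (1 + exp(-(z - g0) / d0))
    horizon <- if (death < end_age) death else end_age
    h_tot <- if (horizon <= a0) 0 else if (horizon <= a1)
      hp * (horizon - a0)^2 / (2 * (a1 - a0)) else
      h_ramp + hp * (horizon - a1)
    nad <- stats::qpois(stats::runif(1), r * h_tot)
    if (nad == 0L) next
    hs <- stats::runif(nad) * h_tot
    occ <- numeric(nad)
    lo <- hs <= h_ramp
    occ[lo] <- a0 + sqrt(2 * hs[lo] * (a1 - a0) / hp)
    occ[!lo] <- a1 + (hs[!lo] - h_ramp) / hp
    cls <- findInterval(stats::runif(nad), cp) + 1L  # 1 P_NON, 2 NP_NON, 3 IMM
    z1 <- stats::rnorm(nad)   # non-advanced dwell draw (class-dependent shape)
    z3 <- stats::rnorm(nad)   # advanced dwell draw
    adv <- rep(NA_real_, nad)
    crc <- rep(NA_real_, nad)
    pn <- cls == 1L
    np <- cls == 2L
    adv[pn] <- occ[pn] + lam1 / (1 + exp(-(z1[pn] - g1) / d1))
    adv[np] <- occ[np] + lam2 / (1 + exp(-(z1[np] - g2) / d2))
    has_adv <- !is.na(adv)
    crc[has_adv] <- adv[has_adv] + lam3 /
      (1 + exp(-(z3[has_adv] - g3) / d3))
    imm <- cls == 3L
    crc[imm] <- occ[imm]
    adv[has_adv & adv > horizon] <- NA_real_
    crc[!is.na(crc) & (crc > horizon | is.na(adv) & !imm)] <- NA_real_

    if (m + nad > cap) {
      cap <- max(2L * cap, m + nad)
      length(a_id) <- cap; length(a_occ) <- cap; length(a_cls) <- cap
      length(a_adv) <- cap; length(a_crc) <- cap
    }
    idx <- (m + 1L):(m + nad)
    a_id[idx] <- i; a_occ[idx] <- occ; a_cls[idx] <- cls
    a_adv[idx] <- adv; a_crc[idx] <- crc
    m <- m + nad
  }

  keep <- seq_len(m)
  adenomas <- data.frame(
    id = a_id[keep],
    adenoma_index = stats::ave(a_id[keep], a_id[keep], FUN = seq_along),
    class = c("P_NON", "NP_NON", "IMMEDIATE_CRC")[a_cls[keep]],
    occurrence_age = a_occ[keep],
    age_to_adv = a_adv[keep],
    age_to_crc = a_crc[keep],
    stringsAsFactors = FALSE)

  new_trace(engine = "event", seed = seed, cohort = cohort,
            death_age = death_age, adenomas = adenomas)
}
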