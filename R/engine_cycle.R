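# Assemble the per-cycle transition probabilities of the cycle engine from a
# 19-parameter design; errors if any assembled probability leaves [0, 1].
cycle_probs <- function(design) {
  d <- as.numeric(design)
  names(d) <- names(design)
  init <- d["init_base"] * d[paste0("init_mult_", 1:5)]
  early <- d[paste0("early_adv_", 1:4)] * d["early_mod_sex"] *
    d["early_mod_size"]
  adv <- c(d["adv_prog_1"] * d["adv_mod_1"],
           d["adv_prog_2"] * d["adv_mod_2"])
  cancer <- d["cancer_prob"] * d["cancer_mod"]
  all_p <- c(init, early, adv, cancer)
  if (any(all_p < 0 | all_p > 1)) {
    stop("cycle engine: assembled per-cycle probabilities outside [0, 1]",
         call. = FALSE)
  }
  list(init = unname(init), early = unname(early), adv = unname(adv),
       cancer = unname(cancer), risk_sd = unname(d["init_risk_sd"]))
}

#' Simulate a cohort with the cycle-based (discrete-time) engine
#'
#' Discrete-time individual-based state-transition simulation in 3-month
#' cycles, in the style of Markov microsimulations of CRC natural history.
#' Each individual draws a death age from the life table and a lognormal
#' risk multiplier (mean 1, log-sd `init_risk_sd`).  New adenomas are
#' initiated each cycle with an age-dependent probability (`init_base`
#' times the age-band multiplier for bands 20-39, 40-49, 50-59, 60-69 and
#' 70+, times the risk multiplier, capped at 1; no initiation before age
#' 20).  Each adenoma then progresses independently through early stages
#' I-IV (per-cycle advance probabilities `early_adv_1..4`, all scaled by
#' the two early modifiers), the advanced stages V-VI (`adv_prog_1..2`
#' scaled by their modifiers), and finally becomes cancerous with
#' per-cycle probability `cancer_prob * cancer_mod`.  Stage dwells are
#' therefore geometric; transitions after death or the cohort horizon are
#' censored.
#'
#' The trace records the first-entry cycle times converted to ages, so the
#' downstream prevalence extraction is shared with the event engine;
#' [cycle_state_matrix()] recovers the full per-cycle state codes.
#'
#' @param design a [cycle_design()] (19 parameters).
#' @inheritParams simulate_event_cohort
#' @return A `trace_statement` (see [simulate_event_cohort()]); cycle-engine
#'   adenomas all carry class `"P_NON"` (the engine has no non-progressive
#'   or immediately-cancerous class) and `cycle_length = 0.25`.
#' @examples
#' tr <- simulate_cycle_cohort(baseline_design("cycle", "male"),
#'                             cohort_spec(n = 50), seed = 1)
#' tr
#' @export
simulate_cycle_cohort <- function(design, cohort,
                                  life = synthetic_life_table(cohort$birth_year),
                                  seed = 1L) {
  if (!inherits(design, "cycle_design")) design <- cycle_design(design)
  stopifnot(inherits(cohort, "cohort_spec"))
  seed <- check_seed(seed)
  check_life_coverage(life, cohort$birth_year, cohort$end_age)
  preserve_rng()

  pr <- cycle_probs(design)
  surv <- cohort_survival(life, cohort$birth_year)
  n <- cohort$n
  cl <- 0.25                                   # cycle length, years
  band_lo <- c(20, 40, 50, 60, 70)             # age-band lower edges, years
  band_hi <- c(40, 50, 60, 70, cohort$end_age)

  death_age <- numeric(n)
  cap <- max(16L, 4L * n)
  a_id <- integer(cap); a_occ <- numeric(cap)
  a_adv <- numeric(cap); a_crc <- numeric(cap)
  m <- 0L

  neg_surv <- -surv
  age_cap <- length(surv) - 1
  lo_full <- floor(band_lo / cl)
  hi_full <- floor(band_hi / cl)
  nb <- length(lo_full)
  p_stage <- c(pr$early, pr$adv, pr$cancer)
  sdl <- pr$risk_sd
  end_age <- cohort$end_age

  for (i in seq_len(n)) {
    set.seed(hash_seed(seed, 1L, i))
    u <- stats::runif(2)
    yr <- findInterval(-u[1], neg_surv, rightmost.closed = TRUE)
    death <- min(yr - 1 + u[2], age_cap)
    death_age[i] <- death
    z <- stats::rnorm(1)
    r <- exp(z * sdl - sdl^2 / 2)
    horizon <- if (death < end_age) death else end_age
    hc <- floor(horizon / cl)                  # cycles available
    lo <- pmin(lo_full, hc)
    hi <- pmin(hi_full, hc)
    ncyc <- hi - lo
    p_band <- pmin(pr$init * r, 1)
    u_band <- stats::runif(nb)
    k_band <- integer(nb)
    open <- ncyc > 0L
    k_band[open] <- stats::qbinom(u_band[open], ncyc[open], p_band[open])
    nad <- sum(k_band)
    if (nad == 0L) next
    b_idx <- rep.int(seq_len(nb), k_band)
    occ_cyc <- lo[b_idx] + floor(stats::runif(nad) * ncyc[b_idx])
    # geometric stage dwells: 4 early, 2 advanced, 1 cancer step
    dwell <- stats::qgeom(stats::runif(nad * 7L),
                          rep(p_stage, each = nad)) + 1
    dim(dwell) <- c(nad, 7L)
    adv_cyc <- occ_cyc + dwell[, 1L] + dwell[, 2L] + dwell[, 3L] +
      dwell[, 4L]
    crc_cyc <- adv_cyc + dwell[, 5L] + dwell[, 6L] + dwell[, 7L]
    occ <- occ_cyc * cl
    adv <- adv_cyc * cl
    crc <- crc_cyc * cl
    adv[adv > horizon] <- NA_real_
    crc[crc > horizon | is.na(adv)] <- NA_real_

    if (m + nad > cap) {
      cap <- max(2L * cap, m + nad)
      length(a_id) <- cap; length(a_occ) <- cap
      length(a_adv) <- cap; length(a_crc) <- cap
    }
    idx <- (m + 1L):(m + nad)
    a_id[idx] <- i; a_occ[idx] <- occ; a_adv[idx] <- adv; a_crc[idx] <- crc
    m <- m + nad
  }

  keep <- seq_len(m)
  adenomas <- data.frame(
    id = a_id[keep],
    adenoma_index = stats::ave(a_id[keep], a_id[keep], FUN = seq_along),
    class = if (m > 0L) "P_NON" else character(0),
    occurrence_age = a_occ[keep],
    age_to_adv = a_adv[keep],
    age_to_crc = a_crc[keep],
    stringsAsFactors = FALSE)

  new_trace(engine = "cycle", seed = seed, cohort = cohort,
            death_age = death_age, adenomas = adenomas, cycle_length = cl)
}

#' Per-cycle state codes of a cycle-engine trace
#'
#' Expands a cycle-engine trace back into the full per-cycle state chart:
#' a matrix with one row per individual and one column per 3-month cycle
#' from birth to the cohort horizon, holding `"HEALTHY"`, `"NON"`, `"ADV"`
#' or `"CRC"` (cumulative definitions), and `NA` for cycles after death.
#'
#' @param trace a cycle-engine `trace_statement`.
#' @return A character matrix of dimension `n x (end_age / 0.25)`.
#' @export
cycle_state_matrix <- function(trace) {
  stopifnot(inherits(trace, "trace_statement"))
  if (trace$engine != "cycle") {
    stop("cycle_state_matrix() requires a cycle-engine trace", call. = FALSE)
  }
  cl <- trace$cycle_length
  fe <- first_entry_ages(trace)
  ages <- seq(0, trace$cohort$end_age - cl, by = cl)
  out <- vapply(ages, function(a) {
    s <- rep("HEALTHY", nrow(fe))
    s[fe$t_non <= a] <- "NON"
    s[fe$t_adv <= a] <- "ADV"
    s[fe$t_crc <= a] <- "CRC"
    s[fe$death_age <= a] <- NA_character_
    s
  }, character(nrow(fe)))
  matrix(out, nrow = nrow(fe), dimnames = list(NULL, sprintf("%.2f", ages)))
}
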