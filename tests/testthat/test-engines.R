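test_that("identical seed and inputs reproduce a byte-identical trace", {
  co <- tiny_cohort(80)
  for (d in list(baseline_design("event", "male"),
                 baseline_design("cycle", "male"))) {
    f <- if (inherits(d, "event_design")) simulate_event_cohort else
      simulate_cycle_cohort
    t1 <- f(d, co, seed = 5)
    t2 <- f(d, co, seed = 5)
    expect_identical(t1, t2)
    t3 <- f(d, co, seed = 6)
    expect_false(identical(t1$adenomas, t3$adenomas))
  }
})

test_that("enlarging the cohort does not perturb earlier individuals", {
  d <- baseline_design("event", "male")
  small <- simulate_event_cohort(d, tiny_cohort(40), seed = 3)
  large <- simulate_event_cohort(d, tiny_cohort(60), seed = 3)
  expect_identical(small$individuals$death_age,
                   large$individuals$death_age[1:40])
  expect_identical(small$adenomas,
                   large$adenomas[large$adenomas$id <= 40, ])
})

test_that("zero occurrence hazard yields an adenoma-free cohort", {
  con <- event_engine_constants(hazard_plateau = 0)
  tr <- simulate_event_cohort(baseline_design("event", "male"),
                              tiny_cohort(30), constants = con, seed = 1)
  expect_identical(nrow(tr$adenomas), 0L)
})

test_that("forcing the immediate-cancer class makes every adenoma cancerous at occurrence", {
  con <- event_engine_constants(class_probs = c(P_NON = 0, NP_NON = 0,
                                                IMMEDIATE_CRC = 1))
  tr <- simulate_event_cohort(baseline_design("event", "male"),
                              tiny_cohort(60), constants = con, seed = 2)
  expect_gt(nrow(tr$adenomas), 0)
  expect_equal(tr$adenomas$age_to_crc, tr$adenomas$occurrence_age)
})

test_that("adenoma events respect the adenoma-carcinoma ordering and censoring", {
  co <- tiny_cohort(150)
  for (d in list(baseline_design("event", "male"),
                 baseline_design("cycle", "female"))) {
    f <- if (inherits(d, "event_design")) simulate_event_cohort else
      simulate_cycle_cohort
    tr <- f(d, co, seed = 11)
    ad <- tr$adenomas
    ok_adv <- !is.na(ad$age_to_adv)
    ok_crc <- !is.na(ad$age_to_crc)
    expect_true(all(ad$age_to_adv[ok_adv] >= ad$occurrence_age[ok_adv]))
    expect_true(all(ad$age_to_crc[ok_crc & ok_adv] >=
                      ad$age_to_adv[ok_crc & ok_adv]))
    horizon <- pmin(tr$individuals$death_age[ad$id], tr$cohort$end_age)
    expect_true(all(ad$occurrence_age <= horizon))
    expect_true(all(ad$age_to_adv[ok_adv] <= horizon[ok_adv]))
    expect_true(all(ad$age_to_crc[ok_crc] <= horizon[ok_crc]))
  }
})

test_that("far more progressive than non-progressive adenomas reach the advanced state", {
  tr <- simulate_event_cohort(baseline_design("event", "male"),
                              cohort_spec(n = 1000), seed = 4)
  ad <- tr$adenomas[!is.na(tr$adenomas$age_to_adv), ]
  n_p <- sum(ad$class == "P_NON")
  n_np <- sum(ad$class == "NP_NON")
  expect_gt(n_p, n_np)
})

test_that("occurrence is monotone in the hazard / initiation scale under common random numbers", {
  co <- tiny_cohort(120)
  carriers <- function(tr) sum(tabulate(tr$adenomas$id, co$n) > 0)
  # event engine: scale the baseline hazard
  n_seen <- vapply(c(0.5, 1, 2), function(s) {
    con <- event_engine_constants(hazard_plateau = 0.05 * s)
    carriers(simulate_event_cohort(baseline_design("event", "male"), co,
                                   constants = con, seed = 9))
  }, numeric(1))
  expect_true(all(diff(n_seen) >= 0))
  # cycle engine: scale the base initiation probability
  base <- baseline_design("cycle", "male")
  n_seen <- vapply(c(0.5, 1, 2), function(s) {
    d <- unclass(base)
    d["init_base"] <- d["init_base"] * s
    carriers(simulate_cycle_cohort(cycle_design(d), co, seed = 9))
  }, numeric(1))
  expect_true(all(diff(n_seen) >= 0))
})

test_that("cycle engine: zero initiation keeps the cohort healthy; certain progression is a deterministic chain", {
  base <- unclass(baseline_design("cycle", "male"))
  d0 <- base
  d0[c("init_base", paste0("init_mult_", 1:5))] <- 0
  tr0 <- simulate_cycle_cohort(cycle_design(d0), tiny_cohort(20), seed = 1)
  expect_identical(nrow(tr0$adenomas), 0L)

  d1 <- base
  d1[paste0("early_adv_", 1:4)] <- 1
  d1[c("early_mod_sex", "early_mod_size")] <- 1
  d1[c("adv_prog_1", "adv_prog_2", "cancer_prob")] <- 1
  d1[c("adv_mod_1", "adv_mod_2", "cancer_mod")] <- 1
  tr1 <- simulate_cycle_cohort(cycle_design(d1), tiny_cohort(50), seed = 1)
  ad <- tr1$adenomas[!is.na(tr1$adenomas$age_to_crc), ]
  expect_gt(nrow(ad), 0)
  # 4 early + 2 advanced + 1 cancer step = 7 cycles of 0.25 y exactly
  expect_equal(ad$age_to_adv - ad$occurrence_age, rep(1.00, nrow(ad)))
  expect_equal(ad$age_to_crc - ad$occurrence_age, rep(1.75, nrow(ad)))
})

test_that("cycle engine exposes one state code per 3-month cycle of follow-up", {
  co <- cohort_spec(n = 2, sex = "male", end_age = 79)
  tr <- simulate_cycle_cohort(baseline_design("cycle", "male"), co,
                              seed = 8)
  m <- cycle_state_matrix(tr)
  expect_identical(dim(m), c(2L, 4L * 79L))     # 316 cycles per individual
  alive_codes <- m[!is.na(m)]
  expect_true(all(alive_codes %in% c("HEALTHY", "NON", "ADV", "CRC")))
})

test_that("invalid assembled per-cycle probabilities are a parameter error", {
  d <- unclass(baseline_design("cycle", "male"))
  d["cancer_prob"] <- 0.5
  d["cancer_mod"] <- 3
  expect_error(simulate_cycle_cohort(cycle_design(d), tiny_cohort(5),
                                     seed = 1),
               "outside")
})

test_that("life-table coverage is enforced", {
  lt <- synthetic_life_table(1949, max_age = 50)
  expect_error(simulate_event_cohort(baseline_design("event", "male"),
                                     tiny_cohort(5), life = lt, seed = 1),
               "cover")
})

test_that("design constructors validate length, names and positivity", {
  expect_error(event_design(1:7), "8 parameters")
  expect_error(cycle_design(1:18), "19 parameters")
  bad <- unclass(baseline_design("event", "male"))
  bad["delta2"] <- -1
  expect_error(event_design(bad), "delta")
  b <- baseline_design("cycle", "female")
  expect_identical(unname(design_blocks(b)),
                   rep(c("initiation", "early", "advanced"), c(7, 6, 6)))
})
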