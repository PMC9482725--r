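test_that("state charts follow the precedence rule and jump at event ages", {
  # no adenomas: constant HEALTHY
  ch <- build_state_chart(NULL, death_age = 80)
  expect_identical(ch$state, "HEALTHY")
  expect_equal(c(ch$from, ch$to), c(0, 80))

  # single adenoma progressing through all states
  h <- data.frame(occurrence_age = 50, age_to_adv = 58, age_to_crc = 66)
  ch <- build_state_chart(h, death_age = 81)
  expect_identical(ch$state, c("HEALTHY", "NON", "ADV", "CRC"))
  expect_equal(ch$from, c(0, 50, 58, 66))
  expect_equal(ch$to, c(50, 58, 66, 81))

  # two adenomas: cancer in one takes precedence from age 59 onward
  h2 <- data.frame(occurrence_age = c(45, 48),
                   age_to_adv = c(60, 52),
                   age_to_crc = c(NA, 59))
  ch2 <- build_state_chart(h2, death_age = 85)
  expect_identical(ch2$state[ch2$from <= 59 & 59 < ch2$to], "CRC")
  expect_identical(classify_state(h2, 59, 85), "CRC")
  expect_identical(classify_state(h2, 55, 85), "ADV")

  expect_error(build_state_chart(
    data.frame(occurrence_age = 60, age_to_adv = 50, age_to_crc = NA),
    death_age = 80), "out of order")
})

test_that("classify_state applies cumulative definitions with CRC > ADV > NON", {
  h <- data.frame(occurrence_age = 50, age_to_adv = 58, age_to_crc = NA)
  expect_identical(classify_state(h, 49, 90), "HEALTHY")
  expect_identical(classify_state(h, 50, 90), "NON")
  expect_identical(classify_state(h, 60, 90), "ADV")
  expect_identical(classify_state(data.frame(occurrence_age = 50,
                                             age_to_adv = NA,
                                             age_to_crc = 50), 51, 90),
                   "CRC")
  expect_identical(classify_state(NULL, 40, 90), "HEALTHY")
  expect_error(classify_state(h, 95, death_age = 90), "died")
})

test_that("prevalence matches a hand count on a four-person cohort", {
  # at the 55-59 midpoint (57.5): HEALTHY, NON, NON, ADV
  ad <- data.frame(id = c(2L, 3L, 4L), adenoma_index = 1L,
                   class = "P_NON",
                   occurrence_age = c(50, 55, 45),
                   age_to_adv = c(NA, NA, 52),
                   age_to_crc = c(NA, NA, NA))
  tr <- make_trace(death_age = rep(90, 4), adenomas = ad)
  pv <- compute_prevalence(tr)
  row <- pv[pv$age_group == "55-59", ]
  expect_equal(row$NON, 0.50)
  expect_equal(row$ADV, 0.25)
  expect_equal(row$CRC, 0.00)
  expect_equal(row$alive, 4)
})

test_that("an all-healthy cohort has zero prevalence everywhere", {
  tr <- make_trace(death_age = rep(85, 6))
  pv <- compute_prevalence(tr)
  expect_true(all(pv$NON == 0 & pv$ADV == 0 & pv$CRC == 0))
})

test_that("state proportions partition the alive population", {
  tr <- simulate_event_cohort(baseline_design("event", "male"),
                              tiny_cohort(200), seed = 13)
  pv <- compute_prevalence(tr)
  expect_true(all(pv$NON >= 0 & pv$ADV >= 0 & pv$CRC >= 0))
  expect_true(all(pv$NON + pv$ADV + pv$CRC <= 1 + 1e-12))
  # HEALTHY share computed independently closes the partition
  fe <- neocalib:::first_entry_ages(tr)
  for (g in seq_len(nrow(pv))) {
    a <- default_age_groups()$midpoint[g]
    alive <- fe$death_age > a
    healthy <- mean(fe$t_non[alive] > a & fe$t_adv[alive] > a &
                      fe$t_crc[alive] > a)
    expect_equal(pv$NON[g] + pv$ADV[g] + pv$CRC[g] + healthy, 1)
  }
})

test_that("prevalence is invariant to the ordering of trace rows", {
  tr <- simulate_cycle_cohort(baseline_design("cycle", "male"),
                              tiny_cohort(100), seed = 21)
  shuffled <- tr
  set.seed(1)
  shuffled$adenomas <- shuffled$adenomas[sample(nrow(shuffled$adenomas)), ]
  expect_equal(compute_prevalence(shuffled), compute_prevalence(tr))
})

test_that("prevalence equals brute-force per-individual classification on tiny cohorts", {
  for (seed in 1:3) {
    tr <- simulate_event_cohort(baseline_design("event", "male"),
                                tiny_cohort(10), seed = seed)
    pv <- compute_prevalence(tr)
    for (g in seq_len(5)) {
      a <- default_age_groups()$midpoint[g]
      alive <- which(tr$individuals$death_age > a)
      states <- vapply(alive, function(i) {
        classify_state(tr$adenomas[tr$adenomas$id == i, ], a,
                       tr$individuals$death_age[i])
      }, character(1))
      expect_equal(pv$NON[g], mean(states == "NON"))
      expect_equal(pv$ADV[g], mean(states == "ADV"))
      expect_equal(pv$CRC[g], mean(states == "CRC"))
    }
  }
})

test_that("state charts never revert in the precedence order", {
  tr <- simulate_cycle_cohort(baseline_design("cycle", "female"),
                              tiny_cohort(60), seed = 31)
  rank <- c(HEALTHY = 0, NON = 1, ADV = 2, CRC = 3)
  for (i in unique(tr$adenomas$id)) {
    ch <- build_state_chart(tr$adenomas[tr$adenomas$id == i, ],
                            tr$individuals$death_age[i])
    expect_true(all(diff(rank[ch$state]) > 0))
  }
})

test_that("aggregation weights by alive counts and handles degenerate weights", {
  tab <- data.frame(age_group = letters[1:5], alive = rep(10, 5),
                    NON = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    ADV = 0.1, CRC = 0.01)
  expect_equal(unname(aggregate_prevalence(tab)["NON"]), 0.3)

  tab$alive <- c(100, 0, 0, 0, 0)
  expect_equal(unname(aggregate_prevalence(tab)["NON"]), 0.1)

  tab$alive <- c(10, 20, 30, 20, 20)
  tab$ADV <- c(0.06, 0.08, 0.09, 0.10, 0.10)
  expect_equal(unname(aggregate_prevalence(tab)["ADV"]), 0.089)

  tab$alive <- rep(0, 5)
  expect_error(aggregate_prevalence(tab), "zero total alive")
})

test_that("an age group with nobody alive is a degenerate-cohort error", {
  tr <- make_trace(death_age = c(60, 62))
  expect_error(compute_prevalence(tr), "degenerate cohort")
})
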