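test_that("synthetic targets are deterministic and self-consistent", {
  base <- baseline_design("cycle", "male")
  co <- tiny_cohort(150)
  t1 <- generate_synthetic_targets(base, co, R = 2, seed = 31)
  t2 <- generate_synthetic_targets(base, co, R = 2, seed = 31)
  expect_identical(t1, t2)
  expect_identical(t1$provenance, "synthetic")
  expect_identical(t1$states, c("NON", "ADV", "CRC"))
  # the truth scores zero against its own targets under shared streams
  expect_identical(evaluate_design(base, co, t1, R = 2, seed = 31)$loss, 0)
})

test_that("a state that never occurs is flagged unusable in the targets", {
  d <- unclass(baseline_design("cycle", "male"))
  d[c("adv_prog_1", "adv_prog_2", "cancer_prob")] <- c(1e-6, 1e-6, 1e-6)
  expect_warning(
    tg <- generate_synthetic_targets(cycle_design(d), tiny_cohort(40),
                                     R = 1, seed = 2),
    "unusable")
  expect_false("CRC" %in% tg$states)
})

test_that("the Monte-Carlo floor is small but nonzero across independent streams", {
  base <- baseline_design("cycle", "male")
  co <- cohort_spec(n = 1000)
  tg <- generate_synthetic_targets(base, co, R = 10, seed = 51)
  floor_loss <- evaluate_design(base, co, tg, R = 10, seed = 52)$loss
  expect_gt(floor_loss, 0)
  # the floor sits well below the loss of a genuinely displaced design
  displaced <- evaluate_design(shifted_design(base, 0.15), co, tg,
                               R = 10, seed = 52)$loss
  expect_lt(floor_loss, displaced / 4)
})

test_that("calibration runs account for both phases and flag phase-1 exhaustion", {
  base <- baseline_design("cycle", "male")
  co <- tiny_cohort(100)
  # absurd targets (scaled far away): nothing passes the 10% screen, and a
  # tiny effort is consumed entirely by phase 1
  tg <- generate_synthetic_targets(base, co, R = 1, seed = 61)
  tg$aggregate <- tg$aggregate * 10
  tg$table[c("NON", "ADV", "CRC")] <-
    tg$table[c("NON", "ADV", "CRC")] * 10
  run <- calibrate(base, co, tg, strategy = "two-phase-seq", effort = 8,
                   seed = 61, n_lhs = 100)
  expect_true(run$excluded)
  expect_identical(unname(run$evaluations["phase1"]), 8L)
  expect_identical(unname(run$evaluations["phase2"]), 0L)
  expect_true(run$phase1$fallback)

  # with reachable targets and a workable effort the run completes
  tg2 <- generate_synthetic_targets(base, co, R = 1, seed = 61)
  run2 <- calibrate(base, co, tg2, strategy = "two-phase-full",
                    effort = 40, seed = 61, n_lhs = 20)
  expect_false(run2$excluded)
  expect_identical(unname(run2$evaluations["total"]),
                   nrow(run2$trajectory))
  expect_lte(unname(run2$evaluations["total"]), 40L)
  expect_true(all(diff(run2$trajectory$incumbent_loss) <= 0))
  expect_equal(run2$loss, min(run2$trajectory$loss))
})

test_that("the comparison harness has the right shape and is seed-deterministic", {
  base <- baseline_design("event", "male")
  co <- tiny_cohort(60)
  cmp <- run_comparison(base, cohort = co, efforts = c(60, 70),
                        strategies = c("direct", "two-phase-seq"),
                        n_runs = 2, seed = 5, R_report = 1)
  expect_identical(nrow(cmp$summary), 4L)   # |strategies| x |efforts|
  expect_true(all(cmp$summary$included + cmp$summary$excluded == 2))
  expect_true(all(is.finite(cmp$summary$mean_loss) |
                    cmp$summary$included == 0))

  cmp2 <- run_comparison(base, cohort = co, efforts = c(60, 70),
                         strategies = c("direct", "two-phase-seq"),
                         n_runs = 2, seed = 5, R_report = 1)
  expect_identical(cmp$summary, cmp2$summary)
})

test_that("trajectory and summary exports are valid CSV", {
  base <- baseline_design("event", "male")
  co <- tiny_cohort(60)
  tg <- generate_synthetic_targets(base, co, R = 1, seed = 71)
  run <- calibrate(base, co, tg, strategy = "direct", effort = 12,
                   seed = 71)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(run, p1)
  tr <- utils::read.csv(p1)
  expect_identical(names(tr), c("evaluation_index", "loss",
                                "incumbent_loss", "phase"))
  expect_identical(nrow(tr), 12L)

  cmp <- run_comparison(base, cohort = co, efforts = 15,
                        strategies = "direct", n_runs = 2, seed = 3,
                        R_report = 1)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_comparison(cmp, p2)
  expect_identical(nrow(utils::read.csv(p2)), 1L)
})
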