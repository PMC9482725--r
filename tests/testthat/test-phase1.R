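test_that("Latin hypercube designs hit every stratum of every dimension exactly once", {
  sp <- design_space(baseline_design("cycle", "male"))
  n <- 100
  X <- lhs_sample(sp, n, seed = 4)
  expect_identical(dim(X), c(100L, 19L))
  for (j in seq_len(ncol(X))) {
    strata <- floor((X[, j] - sp$lower[j]) /
                      ((sp$upper[j] - sp$lower[j]) / n))
    expect_identical(sort(as.integer(strata)), 0:(n - 1))
    expect_true(all(X[, j] >= sp$lower[j] & X[, j] <= sp$upper[j]))
  }
  expect_identical(lhs_sample(sp, n, seed = 4), X)
  expect_false(identical(lhs_sample(sp, n, seed = 5), X))
})

test_that("screening returns the first passing design after exactly that many evaluations", {
  sp <- design_space(baseline_design("event", "male"))
  X <- lhs_sample(sp, 5, seed = 1)
  fail <- c(NON = 0.2, ADV = 0.05, CRC = 0.02)
  pass <- c(NON = 0.05, ADV = 0.03, CRC = 0.01)
  script <- list(fail, fail, pass, pass, pass)
  res <- screen_first_passing(sp, X, scripted_evaluator(script))
  expect_identical(res$evaluations, 3L)
  expect_true(res$passed)
  expect_false(res$fallback)
  expect_equal(as.numeric(res$design), unname(X[3, ]))
  # oracle: evaluate the whole script and scan for the first pass
  first <- which(vapply(script, function(re) all(abs(re) <= 0.10),
                        logical(1)))[1]
  expect_identical(res$evaluations, as.integer(first))
})

test_that("exhausted screening falls back to the minimum-loss design", {
  sp <- design_space(baseline_design("event", "male"))
  X <- lhs_sample(sp, 4, seed = 2)
  script <- list(c(NON = 0.5, ADV = 0.2, CRC = 0.2),
                 c(NON = 0.15, ADV = 0.11, CRC = 0.01),
                 c(NON = 0.4, ADV = 0.3, CRC = 0.2),
                 c(NON = 0.2, ADV = 0.2, CRC = 0.15))
  res <- screen_first_passing(sp, X, scripted_evaluator(script))
  expect_true(res$fallback)
  expect_identical(res$evaluations, 4L)
  losses <- vapply(script, function(re) sum(re^2), numeric(1))
  expect_equal(as.numeric(res$design), unname(X[which.min(losses), ]))
})

test_that("the pair grid is centred on the baseline and matches an exhaustive filter", {
  sp <- design_space(baseline_design("event", "male"))
  ev <- analytic_evaluator(sp, c("delta0", "gamma0"))
  calls <- 0L
  counting <- function(d) { calls <<- calls + 1L; ev(d) }
  res <- grid_search_pair(sp, c("delta0", "gamma0"), counting,
                          threshold = 0.15)
  expect_identical(calls, 25L)
  expect_identical(res$evaluations, 25L)

  # node (2,2) of the 5x5 grid (0-based) is the baseline pair
  b <- sp$baseline[match(c("delta0", "gamma0"), sp$name)]
  i <- match(c("delta0", "gamma0"), sp$name)
  g1 <- seq(sp$lower[i[1]], sp$upper[i[1]], length.out = 5)
  g2 <- seq(sp$lower[i[2]], sp$upper[i[2]], length.out = 5)
  expect_equal(c(g1[3], g2[3]), unname(b))

  # brute-force oracle over the 25 nodes
  nodes <- as.matrix(expand.grid(g1, g2))
  oracle <- t(apply(nodes, 1, function(v) {
    x <- sp$baseline
    x[i] <- v
    e <- ev(neocalib:::space_design(sp, x))
    c(loss = e$loss, pass = max(abs(e$group_rel_err)) <= 0.15)
  }))
  expect_identical(nrow(res$accepted), sum(oracle[, "pass"] == 1))
  pool <- which(oracle[, "pass"] == 1)
  expect_equal(unname(res$best),
               unname(nodes[pool[which.min(oracle[pool, "loss"])], ]))
})

test_that("orthogonal pair samples cover all ten intervals of both dimensions", {
  sp <- design_space(baseline_design("event", "male"))
  v <- orthogonal_sample_pair(sp, c("delta1", "gamma1"), n = 10, seed = 3)
  expect_identical(dim(v), c(10L, 2L))
  i <- match(c("delta1", "gamma1"), sp$name)
  for (k in 1:2) {
    strata <- floor((v[, k] - sp$lower[i[k]]) /
                      ((sp$upper[i[k]] - sp$lower[i[k]]) / 10))
    expect_identical(sort(as.integer(strata)), 0:9)
  }
  expect_identical(orthogonal_sample_pair(sp, c("delta1", "gamma1"),
                                          n = 10, seed = 3), v)
})

test_that("the progressive plan costs 55 evaluations, keeps order, and never worsens", {
  base <- baseline_design("event", "male")
  co <- tiny_cohort(300)
  tg <- generate_synthetic_targets(base, co, R = 1, seed = 23)
  evaluator <- make_evaluator(co, tg, R = 1, seed = 23)
  res <- progressive_search(design_space(base), evaluator, seed = 23)

  expect_identical(res$evaluations, 55L)
  expect_identical(evaluator_count(evaluator), 55L)
  expect_identical(lapply(res$stages, `[[`, "pair"),
                   list(c("delta0", "gamma0"), c("delta1", "gamma1"),
                        c("delta2", "gamma2"), c("delta3", "gamma3")))
  # stage-to-stage incumbent loss is non-increasing
  stage_losses <- vapply(res$stages, `[[`, numeric(1), "loss")
  expect_true(all(diff(stage_losses) <= 1e-12))
  # the selected design stays inside the search space
  sp <- design_space(base)
  expect_true(all(as.numeric(res$design) >= sp$lower - 1e-12 &
                    as.numeric(res$design) <= sp$upper + 1e-12))
})
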