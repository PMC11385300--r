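test_that("the chronological holdout splits 1440 cases into 1110 train / 330 test", {
  rec <- simulate_tillage_data(sim_config())
  sp <- split_cases(rec, split_plan("holdout"))
  expect_equal(nrow(sp$train), 37 * 30)   # 1110
  expect_equal(nrow(sp$test), 11 * 30)    # 330
  expect_true(all(sp$train$year <= 2011))
  expect_true(all(sp$test$year >= 2012))
})

test_that("the decade-block kfold plan partitions the years 10/10/10/10/8", {
  plan <- split_plan("kfold")
  expect_equal(vapply(plan$folds, length, 1L),
               c(K1 = 10L, K2 = 10L, K3 = 10L, K4 = 10L, K5 = 8L))
  rec <- simulate_tillage_data(sim_config(years = 1975:1994, seed = 3))
  folds <- split_cases(rec, plan)
  expect_equal(nrow(folds$K1), 10 * 30)
  expect_equal(nrow(folds$K3), 0)
})

test_that("years outside the plan and empty plans are rejected", {
  rec <- simulate_tillage_data(sim_config(years = 1970:1974, seed = 3))
  expect_error(split_cases(rec, split_plan("holdout")),
               class = "bbn_data_error")
  expect_error(split_plan("holdout", test_years = integer(0)),
               class = "bbn_validation_error")
  expect_error(split_plan("holdout", train_years = 1975:2012),
               class = "bbn_validation_error")  # overlap with test years
  expect_error(split_plan("kfold", folds = list(K1 = 1:5, K2 = 5:9)),
               class = "bbn_validation_error")
})

test_that("error rate is the off-diagonal share in percent, to two decimals", {
  expect_equal(error_rate(matrix(c(8, 2, 1, 9), 2, byrow = TRUE)), 15)
  expect_equal(error_rate(diag(c(5, 9, 3))), 0)
  expect_equal(error_rate(matrix(c(1, 2, 0, 0), 2)), 66.67)
  expect_error(error_rate(matrix(0, 2, 2)), class = "bbn_validation_error")
  expect_error(error_rate(matrix(1, 2, 3)), class = "bbn_validation_error")
})

test_that("scoring rules reproduce closed forms at the perfect and uniform limits", {
  sr <- tillagebbn:::scoring_rules
  perfect <- matrix(c(1, 0, 0, 0, 0,
                      0, 0, 1, 0, 0), 2, byrow = TRUE)
  s <- sr(perfect, c(1L, 3L))
  expect_equal(s$logarithmic_loss, 0)
  expect_equal(s$quadratic_loss, 0)
  expect_equal(s$spherical_payoff, 1)
  uniform <- matrix(0.2, 4, 5)
  u <- sr(uniform, c(1L, 2L, 5L, 3L))
  expect_equal(u$logarithmic_loss, log(5))
  expect_equal(u$quadratic_loss, 0.8)
  expect_equal(u$spherical_payoff, 1 / sqrt(5), tolerance = 1e-12)
})

test_that("scoring rules equal hand arithmetic on a three-case toy", {
  probs <- rbind(c(0.7, 0.2, 0.1),
                 c(0.1, 0.3, 0.6),
                 c(0.5, 0.25, 0.25))
  actual <- c(1L, 3L, 2L)
  s <- tillagebbn:::scoring_rules(probs, actual)
  # hand computation, written out term by term
  expect_equal(s$logarithmic_loss, -(log(0.7) + log(0.6) + log(0.25)) / 3)
  q1 <- 1 - 2 * 0.7 + (0.49 + 0.04 + 0.01)
  q2 <- 1 - 2 * 0.6 + (0.01 + 0.09 + 0.36)
  q3 <- 1 - 2 * 0.25 + (0.25 + 0.0625 + 0.0625)
  expect_equal(s$quadratic_loss, (q1 + q2 + q3) / 3)
  expect_equal(s$spherical_payoff,
               (0.7 / sqrt(0.54) + 0.6 / sqrt(0.46) + 0.25 / sqrt(0.375)) / 3)
})

test_that("zero posterior mass on the actual state is floored and flagged", {
  probs <- rbind(c(1, 0), c(0.5, 0.5))
  s <- tillagebbn:::scoring_rules(probs, c(2L, 1L), floor = 1e-12)
  expect_equal(s$n_floored, 1L)
  expect_true(is.finite(s$logarithmic_loss))
})

test_that("holdout evaluation ties the matrix, the scores and the case count together", {
  rec <- small_records()
  sp <- split_cases(rec, split_plan("holdout", train_years = 1975:1989,
                                    test_years = 1990:1994))
  schemes <- fit_tillage_schemes(sp$train)
  fit <- bbn_fit(tillage_network(), cases_to_states(sp$train, schemes), 1)
  ev <- evaluate_network(fit, cases_to_states(sp$test, schemes), "yield")
  expect_equal(sum(ev$confusion), nrow(sp$test))
  expect_equal(ev$n, nrow(sp$test))
  expect_equal(ev$error_rate, error_rate(ev$confusion))
  expect_equal(rownames(ev$confusion), fit$spec$nodes$yield$states)
  expect_gte(ev$logarithmic_loss, 0)
  expect_gte(ev$quadratic_loss, 0); expect_lte(ev$quadratic_loss, 2)
  expect_gte(ev$spherical_payoff, 0); expect_lte(ev$spherical_payoff, 1)
})

test_that("the kfold report matches a hand-run of the same procedure", {
  rec <- small_records()
  plan <- split_plan("kfold", folds = list(KA = 1975:1984, KB = 1985:1989,
                                           KC = 1990:1994))
  rep_out <- kfold_report(rec, "runoff", plan = plan)
  expect_equal(rep_out$fold, c("KA", "KB", "Average", "Final test"))
  expect_equal(rep_out$error_rate[3],
               round(mean(rep_out$error_rate[1:2]), 2))
  # manual rerun of fold KB: train on all other years, test on 1985-1989
  train <- rec[rec$year %in% c(1975:1984, 1990:1994), ]
  test <- rec[rec$year %in% 1985:1989, ]
  schemes <- fit_tillage_schemes(train)
  fit <- bbn_fit(tillage_network(), cases_to_states(train, schemes), 1)
  ev <- evaluate_network(fit, cases_to_states(test, schemes), "runoff")
  expect_equal(rep_out$error_rate[2], ev$error_rate)
  # final row trains on the earlier folds only
  expect_equal(rep_out$n_train[4], sum(rec$year <= 1989))
})

test_that("fitting on training years only keeps test predictions leakage-free", {
  rec <- small_records()
  sp <- split_cases(rec, split_plan("holdout", train_years = 1975:1989,
                                    test_years = 1990:1994))
  schemes <- fit_tillage_schemes(sp$train)
  fit <- bbn_fit(tillage_network(), cases_to_states(sp$train, schemes), 1)
  test_states <- cases_to_states(sp$test, schemes)
  p1 <- predict(fit, test_states, "ghg")
  # perturb raw test values without crossing any fitted band boundary
  jitter_within_band <- function(x, scheme) {
    b <- scheme$boundaries
    lo <- c(-Inf, b)[findInterval(x, b) + 1L]
    pmax(x - pmin((x - lo) / 2, 1e-4), lo)
  }
  pert <- sp$test
  for (v in c("rainfall", "csom", "biomass"))
    pert[[v]] <- jitter_within_band(pert[[v]], schemes[[v]])
  expect_false(identical(pert$rainfall, sp$test$rainfall))
  p2 <- predict(fit, cases_to_states(pert, schemes), "ghg")
  expect_identical(p1, p2)
  # permuting test row order permutes predictions identically
  idx <- rev(seq_len(nrow(test_states)))
  p3 <- predict(fit, test_states[idx, ], "ghg")
  expect_identical(as.character(p3), as.character(p1)[idx])
})
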