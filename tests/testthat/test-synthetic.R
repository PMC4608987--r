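# Synthetic-cohort generator: determinism, marginal recovery, the
# fatigue/self-rated-health copula, and register/aggregate consistency.

test_that("default parameters carry the emulated cohort's marginals", {
  p <- default_params()
  expect_equal(p$age_mean, 44.4)
  expect_equal(p$age_sd, 9.3)
  expect_equal(p$fatigue_mean, 51.2)
  expect_equal(p$fatigue_sd, 21.0)
  expect_equal(unname(p$srh_probs), c(143, 330, 103, 3) / 579)
  expect_equal(sum(p$prior_days_probs), 1)
  expect_equal(sum(p$prior_episodes_probs), 1)
  expect_equal(p$fatigue_srh_corr, -0.44)
})

test_that("generation is deterministic given the seed and preserves n", {
  a <- generate_cohort(default_params(n = 579, seed = 1))
  b <- generate_cohort(default_params(n = 579, seed = 1))
  expect_identical(a, b)
  expect_equal(nrow(a), 579)
  c2 <- generate_cohort(default_params(n = 579, seed = 2))
  expect_false(identical(a, c2))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(generate_cohort(default_params(n = 20, seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("large-sample marginals match the targets", {
  co <- big_cohort()
  n <- nrow(co)
  expect_lt(abs(mean(co$age) - 44.4) / 44.4, 0.02)
  expect_lt(abs(sd(co$age) - 9.3) / 9.3, 0.02)
  expect_lt(abs(mean(co$fatigue) - 51.2) / 51.2, 0.02)
  expect_lt(abs(sd(co$fatigue) - 21.0) / 21.0, 0.02)
  expect_lt(abs(mean(co$gender == "M") - 361 / 579), 0.02)
  srh_props <- as.numeric(table(factor(co$srh, 1:4)) / n)
  expect_true(all(abs(srh_props - c(3, 103, 330, 143) / 579) < 0.02))
  days_bins <- cut(co$prior_sa_days, c(-1, 0, 7, 14, 30, 60, Inf))
  expect_true(all(abs(as.numeric(table(days_bins) / n) -
                      c(118, 143, 104, 94, 60, 60) / 579) < 0.02))
  eps_bins <- cut(co$prior_sa_episodes, c(-1, 0, 1, 2, 3, 4, Inf))
  expect_true(all(abs(as.numeric(table(eps_bins) / n) -
                      c(118, 130, 115, 74, 64, 78) / 579) < 0.02))
  expect_true(all(co$fatigue >= 20 & co$fatigue <= 140))
  expect_true(all(co$srh %in% 1:4))
})

test_that("fatigue and self-rated health correlate at the target strength", {
  co <- big_cohort()
  expect_lt(abs(cor(co$fatigue, co$srh) - (-0.44)), 0.03)
})

test_that("outcome prevalences sit near the emulated study's 10% and 11%", {
  co <- big_cohort()
  prev_days <- mean(label_high_sa_days(co$fu_sa_days))
  prev_eps <- mean(label_high_sa_episodes(co$fu_sa_episodes))
  expect_gt(prev_days, 0.08); expect_lt(prev_days, 0.12)
  expect_gt(prev_eps, 0.09); expect_lt(prev_eps, 0.13)
})

test_that("calibrate_intercepts recovers the shipped intercepts", {
  p <- calibrate_intercepts(default_params(), n = 100000, seed = 2025)
  expect_lt(abs(p$outcome_models$high_sa_days$intercept - (-1.4502)), 0.05)
  expect_lt(abs(p$outcome_models$high_sa_episodes$intercept - (-2.1708)), 0.05)
})

test_that("generated registers aggregate back to every worker's follow-up counts", {
  co <- generate_cohort(default_params(n = 300, seed = 13))
  reg <- generate_register(co, split_fraction = 0.5, seed = 14)
  agg <- aggregate_register(reg, min_gap_days = 28,
                            window = as.Date(c("2007-01-01", "2007-12-31")))
  merged <- merge(co[c("worker_id", "fu_sa_days", "fu_sa_episodes")], agg,
                  by = "worker_id", all.x = TRUE)
  merged$sa_days[is.na(merged$sa_days)] <- 0
  merged$sa_episodes[is.na(merged$sa_episodes)] <- 0
  expect_equal(merged$sa_days, merged$fu_sa_days)
  expect_equal(merged$sa_episodes, merged$fu_sa_episodes)
  # workers with no absence have no register rows
  expect_false(any(reg$worker_id %in% co$worker_id[co$fu_sa_days == 0]))
  # splitting produced more raw rows than merged episodes for someone
  expect_gt(nrow(reg), sum(co$fu_sa_episodes))
})

test_that("register generation exercises the sub-28-day merge rule on a planted case", {
  co <- generate_cohort(default_params(n = 1, seed = 21))
  co$fu_sa_days <- 16; co$fu_sa_episodes <- 1
  reg <- generate_register(co, split_fraction = 1, seed = 22)
  expect_equal(nrow(reg), 2)                       # split into two raw episodes
  gap <- as.numeric(reg$start[2] - reg$end[1]) - 1
  expect_lt(gap, 28); expect_gte(gap, 1)
  agg <- aggregate_register(reg)
  expect_equal(agg$sa_days, 16)
  expect_equal(agg$sa_episodes, 1)
})

test_that("infeasible follow-up combinations are rejected", {
  co <- generate_cohort(default_params(n = 1, seed = 31))
  co$fu_sa_days <- 10; co$fu_sa_episodes <- 0
  expect_error(generate_register(co), "infeasible")
  co$fu_sa_days <- 2; co$fu_sa_episodes <- 5
  expect_error(generate_register(co), "infeasible")
})

test_that("joint logistic fits at large n recover the generating coefficients", {
  co <- big_cohort()
  for (outcome in c("high_sa_days", "high_sa_episodes")) {
    gen <- generating_coefs(outcome)
    spec <- if (outcome == "high_sa_days")
      model_spec(outcome, c(age = 10, srh = 1, prior_sa_days = 10, fatigue = 10))
    else
      model_spec(outcome, c(age = 10, srh = 1, prior_sa_episodes = 1, fatigue = 10))
    fit <- fit_logistic(co, spec)
    est <- unname(c(fit$intercept, fit$coefficients))
    truth <- unname(gen)
    strong <- abs(truth) >= 0.1
    expect_true(all(abs(est[strong] - truth[strong]) / abs(truth[strong]) < 0.10))
    expect_true(all(abs(est[!strong] - truth[!strong]) < 0.05))
  }
})
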