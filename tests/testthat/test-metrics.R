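# Reclassification statistics: stratification, tables, NRI components,
# category-free NRI, discrimination slope, IDI, bootstrap.

test_that("stratification puts the boundary in the low category", {
  expect_equal(stratify(0.10, 0.10), "low")
  expect_equal(stratify(0.101, 0.10), "high")
  expect_equal(stratify(0.05, 0.20), "low")
  expect_equal(stratify(c(0.1, 0.2, 0.3), 0.2), c("low", "low", "high"))
})

test_that("reclassification tables count each subject once in the right stratum", {
  old <- c(0.05, 0.15); new <- c(0.15, 0.05); event <- c(TRUE, FALSE)
  tab <- build_reclass_table(old, new, event, 0.10)
  expect_equal(tab$events["low", "high"], 1)
  expect_equal(tab$nonevents["high", "low"], 1)
  expect_equal(sum(tab$events) + sum(tab$nonevents), 2)

  set.seed(77)
  inst <- random_instance(200)
  tab2 <- build_reclass_table(inst$old, inst$new, inst$event, 0.2)
  expect_equal(tab2$n_events + tab2$n_nonevents, 200)
  oracle <- oracle_reclass_counts(inst$old, inst$new, inst$event, 0.2)
  expect_equal(unname(tab2$events), unname(oracle$events))
  expect_equal(unname(tab2$nonevents), unname(oracle$nonevents))

  # old = new: off-diagonals all zero
  tab3 <- build_reclass_table(inst$old, inst$old, inst$event, 0.2)
  expect_equal(tab3$events["low", "high"] + tab3$events["high", "low"], 0)
  expect_equal(count_reclassified(tab3)$count, 0)
})

test_that("relabelling events as nonevents exchanges the two cross-tabs", {
  set.seed(78)
  inst <- random_instance(150)
  a <- build_reclass_table(inst$old, inst$new, inst$event, 0.15)
  b <- build_reclass_table(inst$old, inst$new, !inst$event, 0.15)
  expect_equal(a$events, b$nonevents)
  expect_equal(a$nonevents, b$events)
})

test_that("NRI components reproduce the reference tables and flag n.a. strata", {
  tabs <- reference_tables()
  e <- nri_events(tabs$days_10)
  expect_equal(100 * e$estimate, 300 / 59, tolerance = 1e-12)  # 5.0847%
  expect_equal(e$movers_up, 7); expect_equal(e$movers_down, 4)
  ne <- nri_nonevents(tabs$days_10)
  expect_equal(100 * ne$estimate, -2500 / 520, tolerance = 1e-12) # -4.8077%
  expect_equal(nri_events(tabs$days_20)$estimate, -1 / 59)
  expect_true(nri_events(tabs$episodes_10)$not_available)
  expect_true(nri_events(tabs$episodes_20)$not_available)
  expect_true(is.na(nri_events(tabs$episodes_10)$p_value))

  ov <- nri_overall(tabs$days_10)
  expect_equal(ov$estimate, e$estimate + ne$estimate)
  expect_equal(ov$se, sqrt(e$se^2 + ne$se^2))
  # either component unavailable makes the overall unavailable
  expect_true(nri_overall(tabs$episodes_10)$not_available)
})

test_that("NRI component inference uses the binomial standard error", {
  tab <- reclass_table(events = matrix(c(21, 4, 7, 27), 2),
                       nonevents = matrix(c(318, 24, 49, 129), 2),
                       threshold = 0.10)
  e <- nri_events(tab)
  p_up <- 7 / 59; p_dn <- 4 / 59
  expect_equal(e$se, sqrt((p_up + p_dn) / 59))
  expect_equal(e$ci, e$estimate + c(-1, 1) * qnorm(0.975) * e$se)
  z <- e$estimate / e$se
  expect_equal(e$p_value, 2 * pnorm(-abs(z)))
  # NRI components are bounded proportions
  expect_true(abs(e$estimate) <= 1)
})

test_that("a symmetric up/down flow gives zero NRI in both strata", {
  tab <- reclass_table(events = matrix(c(10, 3, 3, 10), 2),
                       nonevents = matrix(c(50, 6, 6, 50), 2),
                       threshold = 0.10)
  expect_equal(nri_events(tab)$estimate, 0)
  expect_equal(nri_nonevents(tab)$estimate, 0)
  expect_equal(nri_overall(tab)$estimate, 0)
})

test_that("category-free NRI counts directional moves and carries its caveat", {
  old <- c(0.2, 0.6, 0.3, 0.4); new <- c(0.3, 0.5, 0.2, 0.3)
  event <- c(TRUE, TRUE, FALSE, FALSE)
  cf <- category_free_nri(old, new, event)
  expect_equal(cf$events$estimate, 0)       # one up, one down
  expect_equal(cf$nonevents$estimate, 1)    # both nonevents moved down
  expect_true(cf$events$caveat)

  # identical risks: no movers in either stratum
  cf2 <- category_free_nri(old, old, event)
  expect_true(cf2$events$not_available)
  expect_true(cf2$nonevents$not_available)
})

test_that("discrimination slope and IDI match hand arithmetic and limits", {
  expect_equal(discrimination_slope(c(0.6, 0.2, 0.3),
                                    c(TRUE, FALSE, FALSE)), 0.35)
  expect_equal(discrimination_slope(rep(0.4, 6), rep(c(TRUE, FALSE), 3)), 0)
  eps <- 1e-6
  r <- c(rep(1 - eps, 5), rep(eps, 5))
  e <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(discrimination_slope(r, e), 1 - 2 * eps)
  expect_error(discrimination_slope(c(0.2, 0.3), c(TRUE, TRUE)),
               "one outcome class")

  old <- c(0.6, 0.2, 0.3); new <- c(0.7, 0.2, 0.2)
  event <- c(TRUE, FALSE, FALSE)
  m <- idi(old, new, event)
  expect_equal(m$estimate, 0.15)
  expect_equal(m$estimate,
               discrimination_slope(new, event) -
                 discrimination_slope(old, event))
  m0 <- idi(old, old, event)
  expect_equal(m0$estimate, 0)
})

test_that("IDI equals the sum of stratum mean risk changes to machine precision", {
  set.seed(91)
  for (rep in 1:25) {
    inst <- random_instance(sample(5:60, 1))
    m <- idi(inst$old, inst$new, inst$event)
    d <- inst$new - inst$old
    identity_form <- mean(d[inst$event]) + mean(-d[!inst$event])
    slope_form <- discrimination_slope(inst$new, inst$event) -
      discrimination_slope(inst$old, inst$event)
    expect_lt(abs(m$estimate - identity_form), 1e-12)
    expect_lt(abs(m$estimate - slope_form), 1e-12)
  }
})

test_that("vectorised metrics agree with brute-force per-subject enumeration", {
  set.seed(92)
  for (rep in 1:60) {
    inst <- random_instance(sample(4:50, 1))
    th <- runif(1, 0.1, 0.9)
    tab <- build_reclass_table(inst$old, inst$new, inst$event, th)
    oracle <- oracle_nri_components(inst$old, inst$new, inst$event, th)
    expect_equal(nri_events(tab)$estimate, unname(oracle["nrie"]))
    expect_equal(nri_nonevents(tab)$estimate, unname(oracle["nrine"]))
    cf <- category_free_nri(inst$old, inst$new, inst$event)
    cfo <- oracle_cfnri_components(inst$old, inst$new, inst$event)
    expect_equal(cf$events$estimate, unname(cfo["nrie"]))
    expect_equal(cf$nonevents$estimate, unname(cfo["nrine"]))
    expect_lt(abs(idi(inst$old, inst$new, inst$event)$estimate -
                    oracle_idi(inst$old, inst$new, inst$event)), 1e-12)
  }
})

test_that("category-free NRI on pairs never crossing a threshold matches the categorical n.a.", {
  # all risks stay strictly below 0.10; categorical table has no movers
  old <- c(0.02, 0.04, 0.06, 0.08); new <- c(0.03, 0.03, 0.07, 0.07)
  event <- c(TRUE, FALSE, TRUE, FALSE)
  tab <- build_reclass_table(old, new, event, 0.10)
  expect_true(nri_events(tab)$not_available)
  expect_true(nri_nonevents(tab)$not_available)
  cf <- category_free_nri(old, new, event)   # still sees the tiny moves
  expect_false(cf$events$not_available)
})

test_that("bootstrap intervals are deterministic, collapse when degenerate, and track asymptotics", {
  # every event moves up, every nonevent moves down: metric constant = 2
  old <- c(rep(0.05, 6), rep(0.15, 6))
  new <- c(rep(0.15, 6), rep(0.05, 6))
  event <- rep(c(TRUE, FALSE), each = 6)
  b <- bootstrap_ci(old, new, event, "nri_overall", threshold = 0.10,
                    replicates = 200, seed = 5)
  expect_equal(unname(diff(b$ci)), 0)

  set.seed(93)
  inst <- random_instance(400)
  b1 <- bootstrap_ci(inst$old, inst$new, inst$event, "idi",
                     replicates = 300, seed = 11)
  b2 <- bootstrap_ci(inst$old, inst$new, inst$event, "idi",
                     replicates = 300, seed = 11)
  expect_identical(b1$ci, b2$ci)

  # mostly-unavailable metric is flagged rather than reported
  old2 <- rep(0.05, 30); new2 <- rep(0.05, 30)
  ev2 <- rep(c(TRUE, FALSE), 15)
  bna <- bootstrap_ci(old2, new2, ev2, "nri_events", threshold = 0.10,
                      replicates = 100, seed = 2)
  expect_true(bna$not_available)

  expect_error(bootstrap_ci(inst$old, inst$new, inst$event, "nri_events",
                            replicates = 200, seed = 1),
               "threshold")
})

test_that("bootstrap and asymptotic intervals agree at moderate n", {
  set.seed(94)
  n <- 5000
  inst <- random_instance(n)
  # give the risk pairs some signal so the NRI is away from the boundary
  inst$new <- pmin(pmax(inst$old + ifelse(inst$event, 0.05, -0.05) +
                          rnorm(n, 0, 0.05), 0.01), 0.99)
  tab <- build_reclass_table(inst$old, inst$new, inst$event, 0.3)
  asym <- nri_events(tab)
  boot <- bootstrap_ci(inst$old, inst$new, inst$event, "nri_events",
                       threshold = 0.3, replicates = 500, seed = 3)
  w_asym <- diff(asym$ci); w_boot <- diff(boot$ci)
  expect_lt(abs(w_boot - w_asym) / w_asym, 0.20)
})
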