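# Episode handling, outcome labelling and cohort CSV I/O.

test_that("episodes separated by fewer than 28 intervening days merge, a gap of exactly 28 does not", {
  ep <- data.frame(start = c(1, 30), end = c(10, 35))   # 19 days between
  m <- merge_episodes(ep)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1, 35))

  ep28 <- data.frame(start = c(1, 39), end = c(10, 40)) # exactly 28 between
  expect_equal(nrow(merge_episodes(ep28)), 2)

  single <- data.frame(start = 5, end = 9)
  expect_identical(merge_episodes(single), single)

  # transitive chaining: three episodes each within 28 days of the next
  chain <- data.frame(start = c(1, 15, 40), end = c(10, 20, 45))
  expect_equal(nrow(merge_episodes(chain)), 1)
})

test_that("merge_episodes validates input and is idempotent", {
  overlap <- data.frame(start = c(1, 5), end = c(10, 20))
  expect_error(merge_episodes(overlap), "overlap")
  expect_error(merge_episodes(data.frame(start = 10, end = 1)),
               "end before start")

  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    starts <- cumsum(sample(1:60, k))
    ends <- starts + sample(0:15, k, replace = TRUE)
    starts[-1] <- pmax(starts[-1], ends[-k] + 1)
    ends <- pmax(ends, starts)
    ep <- data.frame(start = starts, end = ends)
    once <- merge_episodes(ep)
    expect_identical(merge_episodes(once), once)
  }
})

test_that("aggregate_register counts inclusive days of constituents and merged episodes", {
  reg <- data.frame(worker_id = "w1", start = c(1, 30), end = c(10, 35))
  agg <- aggregate_register(reg)
  expect_equal(agg$sa_days, 16)        # 10 + 6, gap days not counted
  expect_equal(agg$sa_episodes, 1)

  reg2 <- data.frame(worker_id = "w1", start = c(1, 39), end = c(10, 40))
  agg2 <- aggregate_register(reg2)
  expect_equal(agg2$sa_days, 12)
  expect_equal(agg2$sa_episodes, 2)

  empty <- data.frame(worker_id = character(0), start = numeric(0),
                      end = numeric(0))
  expect_equal(nrow(aggregate_register(empty)), 0)
})

test_that("day totals are invariant under merging; min_gap 0 keeps raw episode count", {
  set.seed(22)
  for (rep in 1:15) {
    k <- sample(1:6, 1)
    starts <- cumsum(sample(1:50, k))
    ends <- starts + sample(0:20, k, replace = TRUE)
    starts[-1] <- pmax(starts[-1], ends[-k] + 2)
    ends <- pmax(ends, starts)
    reg <- data.frame(worker_id = "w", start = starts, end = ends)
    raw_days <- sum(ends - starts + 1)
    for (gap in c(0, 7, 28, 90)) {
      agg <- aggregate_register(reg, min_gap_days = gap)
      expect_equal(agg$sa_days, raw_days)
    }
    expect_equal(aggregate_register(reg, min_gap_days = 0)$sa_episodes, k)
  }
})

test_that("aggregate_register clips episodes to the observation window", {
  reg <- data.frame(worker_id = "w", start = c(-5, 360), end = c(3, 400))
  agg <- aggregate_register(reg, window = c(1, 365))
  # clipped to 1..3 (3 days) and 360..365 (6 days); far apart: 2 episodes
  expect_equal(agg$sa_days, 9)
  expect_equal(agg$sa_episodes, 2)
  # an episode entirely outside the window is dropped
  reg2 <- data.frame(worker_id = "w", start = 400, end = 410)
  expect_equal(nrow(aggregate_register(reg2, window = c(1, 365))), 0)
})

test_that("outcome labels use the >=30 days and >=3 episodes cut-offs and are monotone", {
  expect_true(label_high_sa_days(30))
  expect_false(label_high_sa_days(29))
  expect_false(label_high_sa_days(0))
  expect_true(label_high_sa_episodes(3))
  expect_false(label_high_sa_episodes(2))
  expect_false(label_high_sa_episodes(0))
  # monotone nondecreasing in the input
  x <- 0:60
  expect_true(all(diff(label_high_sa_days(x)) >= 0))
  expect_true(all(diff(label_high_sa_episodes(0:10)) >= 0))
})

test_that("cohort CSV round-trips and rejects malformed input", {
  cohort <- generate_cohort(default_params(n = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, cohort)

  # out-of-range and unparseable cells become missing with a warning
  bad <- cohort
  bad$srh[1] <- 5
  bad$fatigue[2] <- 10
  write_cohort(bad, path)
  expect_warning(expect_warning(got <- read_cohort(path), "srh"), "fatigue")
  expect_true(is.na(got$srh[1]))
  expect_true(is.na(got$fatigue[2]))
  expect_equal(nrow(got), nrow(bad))   # row count preserved

  writeLines(c("worker_id,age", "w1,44"), path)
  expect_error(read_cohort(path), "missing mandatory column")

  dup <- rbind(cohort[1, ], cohort[1, ])
  write_cohort(dup, path)
  expect_error(read_cohort(path), "duplicate worker_id")
})

test_that("register CSV round-trips with ISO dates", {
  reg <- data.frame(worker_id = c("w1", "w1", "w2"),
                    start = as.Date(c("2007-01-03", "2007-03-01", "2007-06-01")),
                    end = as.Date(c("2007-01-12", "2007-03-05", "2007-06-02")),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_register(reg, path)
  expect_equal(read_register(path), reg)
})

test_that("complete-case filtering removes exactly the planted incomplete records", {
  cohort <- suppressMessages(
    generate_cohort(default_params(n = 633, seed = 5, missing_rate = 54 / 633)))
  expect_equal(nrow(cohort), 633)
  expect_message(cc <- complete_cases(cohort), "removed 54")
  expect_equal(nrow(cc), 579)
  expect_false(anyNA(cc))

  expect_identical(suppressMessages(complete_cases(cc)), cc)

  all_na <- cohort[1:3, ]
  all_na$fatigue <- NA
  expect_warning(suppressMessages(out <- complete_cases(all_na)),
                 "no complete cases")
  expect_equal(nrow(out), 0)

  expect_error(complete_cases(cohort, "nope"), "unknown field")
})
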