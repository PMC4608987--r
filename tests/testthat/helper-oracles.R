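# Independent brute-force oracles: explicit per-subject loops, no shared code
# with the package implementations they check.

oracle_reclass_counts <- function(old, new, event, threshold) {
  cat_of <- function(r) if (r <= threshold) "low" else "high"
  ev <- matrix(0, 2, 2, dimnames = list(c("low", "high"), c("low", "high")))
  ne <- ev
  for (i in seq_along(old)) {
    o <- cat_of(old[i]); n <- cat_of(new[i])
    if (event[i]) ev[o, n] <- ev[o, n] + 1 else ne[o, n] <- ne[o, n] + 1
  }
  list(events = ev, nonevents = ne)
}

oracle_nri_components <- function(old, new, event, threshold) {
  up_e <- down_e <- up_n <- down_n <- 0
  for (i in seq_along(old)) {
    was_low <- old[i] <= threshold
    is_low <- new[i] <= threshold
    up <- was_low && !is_low
    down <- !was_low && is_low
    if (event[i]) { up_e <- up_e + up; down_e <- down_e + down }
    else { up_n <- up_n + up; down_n <- down_n + down }
  }
  c(nrie = (up_e - down_e) / sum(event),
    nrine = (down_n - up_n) / sum(!event))
}

oracle_cfnri_components <- function(old, new, event) {
  up_e <- down_e <- up_n <- down_n <- 0
  for (i in seq_along(old)) {
    up <- new[i] > old[i]
    down <- new[i] < old[i]
    if (event[i]) { up_e <- up_e + up; down_e <- down_e + down }
    else { up_n <- up_n + up; down_n <- down_n + down }
  }
  c(nrie = (up_e - down_e) / sum(event),
    nrine = (down_n - up_n) / sum(!event))
}

oracle_slope <- function(risks, event) {
  se <- sn <- 0
  for (i in seq_along(risks))
    if (event[i]) se <- se + risks[i] else sn <- sn + risks[i]
  se / sum(event) - sn / sum(!event)
}

oracle_idi <- function(old, new, event) {
  oracle_slope(new, event) - oracle_slope(old, event)
}

# Random small reclassification instance with both classes present.
random_instance <- function(n) {
  event <- c(TRUE, FALSE,
             if (n > 2) stats::runif(n - 2) < 0.4 else logical(0))
  list(old = stats::runif(n, 0.01, 0.99),
       new = stats::runif(n, 0.01, 0.99),
       event = event)
}

# Memoised large synthetic cohort shared across expensive tests.
.fixture_cache <- new.env(parent = emptyenv())

big_cohort <- function(n = 50000, seed = 101) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <-
      add_outcome_labels(generate_cohort(default_params(n = n, seed = seed)))
  .fixture_cache[[key]]
}

generating_coefs <- function(outcome) {
  m <- default_params()$outcome_models[[outcome]]
  c(intercept = m$intercept, m$coef)
}
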