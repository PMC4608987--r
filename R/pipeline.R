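#' Configure an end-to-end reclassification study
#'
#' Bundles everything [run_study()] needs: where the cohort comes from (a
#' CSV path or synthetic-generator parameters), which outcomes to analyse,
#' the established and added predictor sets (with scaling divisors), risk
#' thresholds, calibration grouping, and the seed.
#'
#' @param cohort_path Optional path to a cohort CSV ([read_cohort()] dialect);
#'   when `NULL` the cohort is generated from `params`.
#' @param params `sa_params` for the synthetic generator (used when
#'   `cohort_path` is `NULL`).
#' @param outcomes Outcomes to analyse; subset of
#'   `c("high_sa_days", "high_sa_episodes")`.
#' @param established Named list (per outcome) of named divisor vectors for
#'   the established model's predictors.
#' @param added Named divisor vector for the added predictor(s).
#' @param thresholds Strictly increasing risk cut-points in (0, 1).
#' @param hl_groups Hosmer--Lemeshow groups.
#' @param level Confidence level.
#' @param seed Integer seed covering every random element of the run.
#' @return Object of class `sa_config` (a list).
#' @export
study_config <- function(cohort_path = NULL,
                         params = default_params(),
                         outcomes = c("high_sa_days", "high_sa_episodes"),
                         established = list(
                           high_sa_days = c(age = 10, srh = 1,
                                            prior_sa_days = 10),
                           high_sa_episodes = c(age = 10, srh = 1,
                                                prior_sa_episodes = 1)),
                         added = c(fatigue = 10),
                         thresholds = c(0.10, 0.20),
                         hl_groups = 10,
                         level = 0.95,
                         seed = 7L) {
  stopifnot(all(outcomes %in% names(established)),
            all(thresholds > 0), all(thresholds < 1),
            !is.unsorted(thresholds, strictly = TRUE))
  structure(list(cohort_path = cohort_path, params = params,
                 outcomes = outcomes, established = established,
                 added = added, thresholds = thresholds,
                 hl_groups = hl_groups, level = level,
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' Read a study configuration from JSON
#'
#' Accepts the JSON rendering of [study_config()] (divisor vectors as named
#' objects); unspecified fields fall back to the defaults.
#'
#' @param path Path to a JSON file.
#' @return An `sa_config` object.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("cohort_path", "outcomes", "thresholds", "hl_groups",
               "level", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$established))
    args$established <- lapply(raw$established, unlist)
  if (!is.null(raw$added)) args$added <- unlist(raw$added)
  if (!is.null(raw$params)) {
    p <- do.call(default_params, raw$params[intersect(names(raw$params),
                                                      c("n", "seed",
                                                        "missing_rate"))])
    args$params <- p
  }
  do.call(study_config, args)
}

## Formula term for one predictor with its divisor, e.g. I(age/10).
divisor_terms <- function(div)
  ifelse(div == 1, names(div), sprintf("I(%s/%g)", names(div), div))

spec_formula <- function(outcome, div) {
  stats::as.formula(paste(outcome, "~", paste(divisor_terms(div),
                                              collapse = " + ")))
}

#' Run the reclassification study end-to-end
#'
#' Obtains the cohort (CSV or synthetic), complete-case filters on the
#' variables in play, labels the outcomes, and for each configured outcome
#' fits the established and extended models, tests calibration of both,
#' builds reclassification tables with NRIe/NRIne/overall at every
#' threshold, and computes the category-free NRI, discrimination slopes and
#' IDI.  A model that fails to converge marks that outcome failed; the
#' remaining outcomes still run.  Fully deterministic given the config seed.
#'
#' @param config An `sa_config` from [study_config()].
#' @return Object of class `sa_study_report`: per-outcome `sa_reclass` fits
#'   (under `$fits`), a compact numeric summary (under `$results`), cohort
#'   sizes and provenance.
#' @examples
#' report <- run_study(study_config(params = default_params(n = 579, seed = 7)))
#' report$results$high_sa_days$nri[["10%"]]
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "sa_config"))
  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort(config$cohort_path)
  } else {
    p <- config$params
    p$seed <- config$seed
    generate_cohort(p)
  }
  message(sprintf("run_study: cohort of %d records", nrow(cohort)))
  vars <- unique(c(unlist(lapply(config$established, names)),
                   names(config$added), "fu_sa_days", "fu_sa_episodes"))
  cohort <- complete_cases(cohort, intersect(vars, names(cohort)))
  cohort <- add_outcome_labels(cohort)
  message(sprintf("run_study: %d complete cases", nrow(cohort)))

  fits <- list(); results <- list()
  for (outcome in config$outcomes) {
    div <- config$established[[outcome]]
    fml <- spec_formula(outcome, div)
    add <- stats::as.formula(paste("~", paste(divisor_terms(config$added),
                                              collapse = " + ")))
    fit <- tryCatch(
      suppressWarnings(
        sa_reclass(fml, cohort, add, thresholds = config$thresholds,
                   hl_groups = config$hl_groups, level = config$level)),
      error = function(e) e)
    if (!inherits(fit, "error") &&
        (!fit$model_old$converged || !fit$model_new$converged))
      fit <- simpleError("logistic model did not converge")
    if (inherits(fit, "error")) {
      message(sprintf("run_study: outcome '%s' failed: %s", outcome,
                      conditionMessage(fit)))
      results[[outcome]] <- list(failed = TRUE,
                                 reason = conditionMessage(fit))
      next
    }
    fits[[outcome]] <- fit
    results[[outcome]] <- summarise_fit(fit)
  }
  structure(list(config = config, n = nrow(cohort), fits = fits,
                 results = results,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("sareclass")),
                   seed = config$seed,
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "sa_study_report")
}

metric_list <- function(m) {
  out <- list(estimate_pct = 100 * m$estimate, n = m$n,
              not_available = m$not_available)
  if (!is.na(m$se)) out$se_pct <- 100 * m$se
  if (!anyNA(m$ci)) out$ci_pct <- 100 * m$ci
  if (!is.na(m$p_value)) out$p_value <- m$p_value
  if (!is.na(m$movers_up)) out$movers_up <- m$movers_up
  if (!is.na(m$movers_down)) out$movers_down <- m$movers_down
  out
}

summarise_fit <- function(fit) {
  s <- summary(fit)
  list(
    failed = FALSE,
    n = fit$n, n_events = fit$n_events,
    odds_ratios = list(established = s$or_old, extended = s$or_new),
    hosmer_lemeshow = list(
      established = fit$hl_old[c("chi2", "df", "p_value")],
      extended = fit$hl_new[c("chi2", "df", "p_value")]),
    nri = lapply(fit$nri, function(x) list(
      events = metric_list(x$events),
      nonevents = metric_list(x$nonevents),
      overall = metric_list(x$overall),
      reclassified = x$reclassified)),
    tables = lapply(fit$tables, function(t) list(
      threshold = t$threshold,
      events = unname(split(t$events, row(t$events))),
      nonevents = unname(split(t$nonevents, row(t$nonevents))))),
    slopes = as.list(fit$slopes),
    idi = metric_list(fit$idi),
    category_free_nri = list(events = metric_list(fit$cfnri$events),
                             nonevents = metric_list(fit$cfnri$nonevents),
                             overall = metric_list(fit$cfnri$overall))
  )
}

#' @export
print.sa_study_report <- function(x, ...) {
  cat(sprintf("Reclassification study report (n = %d, seed = %d)\n",
              x$n, x$config$seed))
  for (outcome in names(x$results)) {
    r <- x$results[[outcome]]
    if (isTRUE(r$failed)) {
      cat(sprintf("  %s: FAILED (%s)\n", outcome, r$reason)); next
    }
    cat(sprintf("  %s: %d events; IDI %.2f%%\n", outcome, r$n_events,
                r$idi$estimate_pct))
  }
  invisible(x)
}

#' Render a study report to JSON or markdown
#'
#' JSON output round-trips losslessly through [jsonlite::read_json()];
#' markdown renders the odds-ratio and reclassification tables per outcome
#' and threshold.
#'
#' @param report An `sa_study_report`.
#' @param format `"json"` or `"markdown"`.
#' @param path Optional output file.
#' @return The document as a character string (invisibly when written to
#'   `path`).
#' @export
render_report <- function(report, format = c("json", "markdown"),
                          path = NULL) {
  stopifnot(inherits(report, "sa_study_report"))
  format <- match.arg(format)
  doc <- if (format == "json") render_json(report) else render_markdown(report)
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

render_json <- function(report) {
  payload <- list(
    n = report$n,
    seed = report$config$seed,
    thresholds = report$config$thresholds,
    results = report$results,
    provenance = report$provenance
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

render_markdown <- function(report) {
  lines <- c("# Risk reclassification study report", "",
             sprintf("Cohort: n = %d complete cases; seed %d.",
                     report$n, report$config$seed), "")
  fmt_or <- function(tab) {
    c("| predictor | OR | 95% CI | p |", "|---|---|---|---|",
      sprintf("| %s | %.2f | %.2f-%.2f | %.2g |", tab$predictor, tab$or,
              tab$ci_low, tab$ci_high, tab$p_value))
  }
  fmt_metric <- function(m, name) {
    if (isTRUE(m$not_available))
      sprintf("%s: n.a. (no movers)", name)
    else
      sprintf("%s: %.2f%% (95%% CI %.2f to %.2f%%), p = %.2g", name,
              m$estimate_pct, m$ci_pct[1], m$ci_pct[2], m$p_value)
  }
  for (outcome in names(report$results)) {
    r <- report$results[[outcome]]
    lines <- c(lines, sprintf("## Outcome: %s", outcome), "")
    if (isTRUE(r$failed)) {
      lines <- c(lines, sprintf("Model failed: %s", r$reason), "")
      next
    }
    lines <- c(lines, sprintf("%d events among %d workers.", r$n_events, r$n),
               "", "### Odds ratios (established model)", "",
               fmt_or(r$odds_ratios$established), "",
               "### Odds ratios (extended model)", "",
               fmt_or(r$odds_ratios$extended), "",
               sprintf("Hosmer-Lemeshow: established chi2 = %.1f (df %d, p = %.2f); extended chi2 = %.1f (df %d, p = %.2f)",
                       r$hosmer_lemeshow$established$chi2,
                       r$hosmer_lemeshow$established$df,
                       r$hosmer_lemeshow$established$p_value,
                       r$hosmer_lemeshow$extended$chi2,
                       r$hosmer_lemeshow$extended$df,
                       r$hosmer_lemeshow$extended$p_value), "")
    for (th in names(r$nri)) {
      tab <- r$tables[[th]]
      lines <- c(lines,
        sprintf("### Reclassification at %s", th), "",
        "| | new low | new high |", "|---|---|---|",
        sprintf("| events, old low | %d | %d |", tab$events[[1]][1],
                tab$events[[1]][2]),
        sprintf("| events, old high | %d | %d |", tab$events[[2]][1],
                tab$events[[2]][2]),
        sprintf("| nonevents, old low | %d | %d |", tab$nonevents[[1]][1],
                tab$nonevents[[1]][2]),
        sprintf("| nonevents, old high | %d | %d |", tab$nonevents[[2]][1],
                tab$nonevents[[2]][2]), "",
        fmt_metric(r$nri[[th]]$events, "NRIe"),
        fmt_metric(r$nri[[th]]$nonevents, "NRIne"),
        sprintf("Reclassified: %d (%.0f%%)", r$nri[[th]]$reclassified$count,
                100 * r$nri[[th]]$reclassified$proportion), "")
    }
    lines <- c(lines, fmt_metric(r$idi, "IDI"),
               sprintf("Discrimination slope: %.4f -> %.4f",
                       r$slopes$old, r$slopes$new), "")
  }
  paste(lines, collapse = "\n")
}
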