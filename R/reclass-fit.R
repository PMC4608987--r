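#' @importFrom stats update model.frame terms as.formula predict simulate
#'   residuals fitted family formula
#' @importFrom graphics abline legend plot points
NULL

#' Risk reclassification analysis of an added predictor
#'
#' Fits the established prognostic model given by `formula` (binary outcome,
#' logistic link) and the extended model obtained by adding the terms of
#' `add`, on the complete cases of all variables involved; then quantifies
#' the added predictive value of the new terms with reclassification tables
#' at each risk threshold, event/nonevent Net Reclassification Indices,
#' the category-free NRI, discrimination slopes and the integrated
#' discrimination improvement, plus Hosmer--Lemeshow calibration of both
#' models.  Risks are in-sample (both models are fit and evaluated on the
#' same cohort), the design the reclassification literature describes.
#'
#' @param formula Established model, e.g.
#'   `high_sa_days ~ I(age/10) + srh + I(prior_sa_days/10)`.
#' @param data A `data.frame` (e.g. a cohort from [generate_cohort()] with
#'   [add_outcome_labels()] applied).
#' @param add One-sided formula with the new predictor term(s), e.g.
#'   `~ I(fatigue/10)`.
#' @param thresholds Risk cut-points in (0, 1), strictly increasing; default
#'   `c(0.10, 0.20)`.
#' @param hl_groups Groups for the Hosmer--Lemeshow test, default 10.
#' @param level Confidence level for all intervals, default 0.95.
#' @return Object of class `sa_reclass`; see [summary.sa_reclass()].
#'   Components include `model_old`/`model_new` (`glm` fits), `risks`
#'   (data.frame old/new/event), `hl_old`/`hl_new`, `tables` (one
#'   `reclass_table` per threshold), `nri` (per threshold: events,
#'   nonevents, overall, reclassified), `cfnri`, `idi`, `slopes`.
#' @examples
#' cohort <- add_outcome_labels(generate_cohort(default_params(n = 579, seed = 7)))
#' fit <- sa_reclass(high_sa_days ~ I(age/10) + srh + I(prior_sa_days/10),
#'                   data = cohort, add = ~ I(fatigue/10))
#' summary(fit)
#' @export
sa_reclass <- function(formula, data, add, thresholds = c(0.10, 0.20),
                       hl_groups = 10, level = 0.95) {
  stopifnot(inherits(formula, "formula"), inherits(add, "formula"),
            all(thresholds > 0), all(thresholds < 1),
            !is.unsorted(thresholds, strictly = TRUE))
  cl <- match.call()
  vars <- unique(c(all.vars(formula), all.vars(add)))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("data lacks variable(s): ", paste(missing_vars, collapse = ", "))
  cc <- complete_cases(data, vars)
  if (nrow(cc) < 2) stop("too few complete cases")

  new_formula <- update(formula,
                        as.formula(paste(". ~ . +",
                                         paste(attr(terms(add), "term.labels"),
                                               collapse = " + "))))
  ctrl <- glm.control(epsilon = 1e-8, maxit = 100)
  model_old <- glm(formula, family = binomial(), data = cc, control = ctrl)
  model_new <- glm(new_formula, family = binomial(), data = cc, control = ctrl)
  for (m in list(model_old, model_new))
    if (!m$converged)
      warning("logistic model did not converge", call. = FALSE)

  event <- as.logical(model.frame(model_old)[[1]])
  old_risk <- unname(fitted(model_old))
  new_risk <- unname(fitted(model_new))

  tables <- lapply(thresholds, function(th)
    build_reclass_table(old_risk, new_risk, event, th))
  names(tables) <- sprintf("%g%%", 100 * thresholds)
  nri <- lapply(tables, function(tab) list(
    events = nri_events(tab, level),
    nonevents = nri_nonevents(tab, level),
    overall = nri_overall(tab, level),
    reclassified = count_reclassified(tab)))

  structure(list(
    call = cl,
    outcome = all.vars(formula)[1],
    n = nrow(cc),
    n_events = sum(event),
    level = level,
    thresholds = thresholds,
    model_old = model_old,
    model_new = model_new,
    risks = data.frame(old = old_risk, new = new_risk, event = event),
    hl_old = hosmer_lemeshow(old_risk, event, hl_groups),
    hl_new = hosmer_lemeshow(new_risk, event, hl_groups),
    tables = tables,
    nri = nri,
    cfnri = category_free_nri(old_risk, new_risk, event, level),
    slopes = c(old = discrimination_slope(old_risk, event),
               new = discrimination_slope(new_risk, event)),
    idi = idi(old_risk, new_risk, event, level)
  ), class = "sa_reclass")
}

#' @export
print.sa_reclass <- function(x, ...) {
  cat("Risk reclassification analysis\n")
  cat("  call: "); print(x$call)
  cat(sprintf("  outcome '%s': %d events / %d subjects (%.1f%%)\n",
              x$outcome, x$n_events, x$n, 100 * x$n_events / x$n))
  for (th in names(x$nri)) {
    e <- x$nri[[th]]$events; ne <- x$nri[[th]]$nonevents
    cat(sprintf("  threshold %s: NRIe %s, NRIne %s, reclassified %d (%.0f%%)\n",
                th,
                if (e$not_available) "n.a." else sprintf("%.2f%%", 100 * e$estimate),
                if (ne$not_available) "n.a." else sprintf("%.2f%%", 100 * ne$estimate),
                x$nri[[th]]$reclassified$count,
                100 * x$nri[[th]]$reclassified$proportion))
  }
  cat(sprintf("  IDI %.2f%% (p = %.2g)\n", 100 * x$idi$estimate,
              x$idi$p_value))
  invisible(x)
}

#' Summarise a reclassification analysis
#'
#' @param object An `sa_reclass` fit.
#' @param ... Unused.
#' @return An object of class `summary.sa_reclass` printed as odds-ratio
#'   tables for both models, calibration tests, per-threshold
#'   reclassification tables with NRI components, discrimination slopes and
#'   IDI.
#' @export
summary.sa_reclass <- function(object, ...) {
  or_table <- function(m) {
    cf <- coef(m)[-1]
    se <- sqrt(diag(vcov(m)))[-1]
    z <- qnorm(1 - (1 - object$level) / 2)
    data.frame(predictor = names(cf), or = exp(cf),
               ci_low = exp(cf - z * se), ci_high = exp(cf + z * se),
               p_value = 2 * pnorm(-abs(cf / se)), row.names = NULL)
  }
  structure(list(fit = object,
                 or_old = or_table(object$model_old),
                 or_new = or_table(object$model_new)),
            class = "summary.sa_reclass")
}

#' @export
print.summary.sa_reclass <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f)
  cat("\nEstablished model odds ratios:\n")
  print(format_or(x$or_old, digits))
  cat("Extended model odds ratios:\n")
  print(format_or(x$or_new, digits))
  cat("\nCalibration (Hosmer-Lemeshow):\n  established: ")
  print(f$hl_old)
  cat("  extended:    "); print(f$hl_new)
  for (th in names(f$tables)) {
    cat("\n"); print(f$tables[[th]])
    print(f$nri[[th]]$events); print(f$nri[[th]]$nonevents)
    print(f$nri[[th]]$overall)
  }
  cat(sprintf("\nDiscrimination slope: %.4f (established) -> %.4f (extended)\n",
              f$slopes["old"], f$slopes["new"]))
  print(f$idi)
  invisible(x)
}

format_or <- function(tab, digits) {
  data.frame(predictor = tab$predictor,
             OR = round(tab$or, digits),
             CI = sprintf("%.*f-%.*f", digits - 1, tab$ci_low,
                          digits - 1, tab$ci_high),
             p = signif(tab$p_value, 2))
}

#' @export
coef.sa_reclass <- function(object, model = c("both", "established", "extended"),
                            ...) {
  model <- match.arg(model)
  switch(model,
         established = coef(object$model_old),
         extended = coef(object$model_new),
         both = list(established = coef(object$model_old),
                     extended = coef(object$model_new)))
}

#' Predicted risks from a reclassification fit
#'
#' @param object An `sa_reclass` fit.
#' @param newdata Optional data frame; defaults to the fitted risks.
#' @param model `"extended"` (default), `"established"`, or `"both"` (a
#'   two-column data frame).
#' @param ... Unused.
#' @return Numeric vector of probabilities (or data frame for `"both"`).
#' @export
predict.sa_reclass <- function(object, newdata = NULL,
                               model = c("extended", "established", "both"),
                               ...) {
  model <- match.arg(model)
  if (is.null(newdata)) {
    r <- object$risks
    return(switch(model, extended = r$new, established = r$old,
                  both = data.frame(established = r$old, extended = r$new)))
  }
  po <- unname(predict(object$model_old, newdata = newdata, type = "response"))
  pn <- unname(predict(object$model_new, newdata = newdata, type = "response"))
  switch(model, extended = pn, established = po,
         both = data.frame(established = po, extended = pn))
}

#' @export
residuals.sa_reclass <- function(object, type = "response",
                                 model = c("extended", "established"), ...) {
  model <- match.arg(model)
  residuals(if (model == "extended") object$model_new else object$model_old,
            type = type)
}

#' Simulate outcomes from the extended model
#'
#' Bernoulli draws from the extended model's fitted risks; useful for
#' parametric-bootstrap checks of calibration statistics.
#'
#' @param object An `sa_reclass` fit.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A `data.frame` with `nsim` logical columns.
#' @export
simulate.sa_reclass <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$risks$new
  draw <- function() rbinom(length(p), 1, p) == 1
  sims <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
          else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot old against new predicted risks
#'
#' Scatter of established-model against extended-model risk, events
#' highlighted, with the risk thresholds drawn; points off the diagonal
#' crossing a threshold line are the reclassified subjects.
#'
#' @param x An `sa_reclass` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sa_reclass <- function(x, ...) {
  r <- x$risks
  lim <- range(0, r$old, r$new)
  plot(r$old[!r$event], r$new[!r$event], xlim = lim, ylim = lim,
       col = "grey50", pch = 1,
       xlab = "Risk, established model", ylab = "Risk, extended model",
       main = sprintf("Reclassification: %s", x$outcome), ...)
  points(r$old[r$event], r$new[r$event], col = "firebrick", pch = 16)
  abline(0, 1, lty = 1)
  abline(v = x$thresholds, h = x$thresholds, lty = 3, col = "grey40")
  legend("topleft", legend = c("event", "nonevent"),
         col = c("firebrick", "grey50"), pch = c(16, 1), bty = "n")
  invisible(x)
}
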