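#' @importFrom stats glm binomial glm.control coef vcov logLik pchisq
#'   complete.cases setNames
NULL

#' Specify a binary-outcome risk model
#'
#' A model specification names the outcome column and an ordered set of
#' predictors with scaling divisors, e.g. age per 10 years or fatigue per 10
#' CIS points, so reported odds ratios are per the conventional unit.
#'
#' @param outcome Name of a logical/0-1 outcome column
#'   (`"high_sa_days"` or `"high_sa_episodes"` in the shipped workflow).
#' @param predictors Named numeric vector of divisors, e.g.
#'   `c(age = 10, srh = 1, prior_sa_days = 10)`; may be empty for an
#'   intercept-only model.
#' @return An object of class `sa_modelspec`.
#' @export
model_spec <- function(outcome, predictors = numeric(0)) {
  stopifnot(is.character(outcome), length(outcome) == 1)
  if (length(predictors)) {
    stopifnot(is.numeric(predictors), !is.null(names(predictors)),
              all(nzchar(names(predictors))), all(predictors > 0))
  }
  structure(list(outcome = outcome, predictors = predictors),
            class = "sa_modelspec")
}

spec_term_names <- function(spec) {
  div <- spec$predictors
  ifelse(div == 1, names(div), sprintf("%s/%g", names(div), div))
}

## Scaled design matrix (no intercept column) for a spec on a cohort.
spec_design <- function(spec, data) {
  div <- spec$predictors
  if (!length(div)) return(matrix(numeric(0), nrow(data), 0))
  missing_cols <- setdiff(names(div), names(data))
  if (length(missing_cols))
    stop("cohort lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- vapply(names(div), function(nm) as.numeric(data[[nm]]) / div[[nm]],
              numeric(nrow(data)))
  x <- matrix(x, nrow = nrow(data),
              dimnames = list(NULL, spec_term_names(spec)))
  x
}

#' Fit a logistic risk model
#'
#' Maximum-likelihood logistic regression of a binary outcome on the scaled
#' predictors of a [model_spec()], via iteratively reweighted least squares
#' (convergence tolerance 1e-8 on the deviance change, at most 100
#' iterations).  Records with a missing outcome or predictor are dropped.
#' A constant predictor is an error naming the column; (quasi-)complete
#' separation is flagged as non-convergence with a diagnostic rather than
#' returned silently.
#'
#' @param cohort A cohort `data.frame` containing the outcome and predictor
#'   columns.
#' @param spec An `sa_modelspec`.
#' @return An object of class `sa_riskmodel`: list with `spec`, `intercept`,
#'   `coefficients` (log-odds per scaled unit), `vcov`, `n_used`,
#'   `converged`, `log_likelihood` and the underlying `glm` fit.
#' @examples
#' cohort <- add_outcome_labels(generate_cohort(default_params(n = 400)))
#' m <- fit_logistic(cohort, model_spec("high_sa_days",
#'                   c(age = 10, srh = 1, prior_sa_days = 10)))
#' odds_ratios(m)
#' @export
fit_logistic <- function(cohort, spec) {
  stopifnot(inherits(spec, "sa_modelspec"))
  y <- cohort[[spec$outcome]]
  if (is.null(y)) stop("outcome column not found: ", spec$outcome)
  x <- spec_design(spec, cohort)
  keep <- !is.na(y) & complete.cases(x)
  y <- as.numeric(y[keep]); x <- x[keep, , drop = FALSE]
  if (length(unique(y)) < 2)
    stop("outcome has fewer than 2 classes after complete-case filtering")
  for (j in seq_len(ncol(x)))
    if (length(unique(x[, j])) < 2)
      stop("degenerate (constant) predictor: ", names(spec$predictors)[j])

  df <- data.frame(.y = y, x, check.names = FALSE)
  fm <- if (ncol(x)) {
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(x)),
                                          collapse = " + ")))
  } else stats::as.formula(".y ~ 1")
  fit <- suppressWarnings(
    glm(fm, family = binomial(), data = df,
        control = glm.control(epsilon = 1e-8, maxit = 100))
  )
  eps <- 1e-8
  separated <- any(fit$fitted.values > 1 - eps) || any(fit$fitted.values < eps)
  converged <- fit$converged && !separated
  if (!converged)
    warning(if (separated) "perfect/quasi-complete separation detected; estimates unreliable"
            else "IRLS did not converge within 100 iterations", call. = FALSE)
  cf <- coef(fit)
  structure(list(
    spec = spec,
    intercept = unname(cf[1]),
    coefficients = if (length(cf) > 1) setNames(cf[-1], spec_term_names(spec))
                   else setNames(numeric(0), character(0)),
    vcov = vcov(fit),
    n_used = length(y),
    converged = converged,
    separation = separated,
    log_likelihood = as.numeric(logLik(fit)),
    fit = fit
  ), class = "sa_riskmodel")
}

#' @export
print.sa_riskmodel <- function(x, digits = 4, ...) {
  cat(sprintf("Logistic risk model for '%s' (n = %d%s)\n", x$spec$outcome,
              x$n_used, if (x$converged) "" else ", NOT CONVERGED"))
  print(round(c("(Intercept)" = x$intercept, x$coefficients), digits))
  invisible(x)
}

#' Predicted risks from a fitted model
#'
#' Inverse-logit of the linear predictor on the scaled inputs; records with
#' a missing predictor get a missing risk.
#'
#' @param model An `sa_riskmodel`.
#' @param cohort A cohort `data.frame` with the predictor columns.
#' @return Numeric vector of probabilities aligned to `cohort` rows.
#' @export
predict_risk <- function(model, cohort) {
  stopifnot(inherits(model, "sa_riskmodel"))
  if (!model$converged)
    warning("predicting from a non-converged model", call. = FALSE)
  x <- spec_design(model$spec, cohort)
  eta <- model$intercept + drop(x %*% unname(model$coefficients))
  if (!ncol(x)) eta <- rep(model$intercept, nrow(cohort))
  plogis(eta)
}

#' Odds ratios with Wald confidence intervals
#'
#' One row per predictor: OR = exp(coefficient) per scaled unit, symmetric
#' Wald interval on the log scale, two-sided Wald p-value.
#'
#' @param model An `sa_riskmodel`.
#' @param level Confidence level, default 0.95.
#' @return `data.frame` with columns `predictor`, `or`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
odds_ratios <- function(model, level = 0.95) {
  stopifnot(inherits(model, "sa_riskmodel"), level > 0, level < 1)
  if (!model$converged) warning("model did not converge", call. = FALSE)
  k <- length(model$coefficients)
  if (!k) return(data.frame(predictor = character(0), or = numeric(0),
                            ci_low = numeric(0), ci_high = numeric(0),
                            p_value = numeric(0)))
  beta <- unname(model$coefficients)
  se <- sqrt(diag(model$vcov))[-1]
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(
    predictor = names(model$coefficients),
    or = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_value = 2 * pnorm(-abs(beta / se)),
    row.names = NULL
  )
}

#' Hosmer--Lemeshow calibration test
#'
#' Partitions subjects into `groups` risk-ordered groups of near-equal size
#' (rank-based deciles by default; tied risks stay together in the lower
#' group) and compares observed with expected event counts:
#' \deqn{\chi^2 = \sum_g (O_g - E_g)^2 / (n_g \bar\pi_g (1 - \bar\pi_g))}
#' with \eqn{\bar\pi_g} the mean predicted risk in group \eqn{g}, referred to
#' a chi-square distribution with `groups - 2` degrees of freedom.  Adequate
#' calibration is conventionally concluded for p >= 0.05.  A group whose mean
#' risk is 0 or 1 contributes nothing (skipped with a warning).
#'
#' @param risks Predicted probabilities.
#' @param events Logical (or 0/1) outcome vector of the same length.
#' @param groups Number of groups, default 10 (so df = 8).
#' @return Object of class `sa_hl`: `chi2`, `df`, `p_value` and a per-group
#'   `table` (n, mean predicted risk, observed and expected events).
#' @export
hosmer_lemeshow <- function(risks, events, groups = 10) {
  events <- as.logical(events)
  stopifnot(length(risks) == length(events), groups >= 2,
            length(risks) >= groups, !anyNA(risks), !anyNA(events))
  n <- length(risks)
  # rank-based groups; ties kept intact in the lower group
  ord <- order(risks)
  grp_sorted <- ceiling(seq_len(n) * groups / n)
  grp <- integer(n)
  grp[ord] <- grp_sorted
  # pull ties down: every subject with a given risk value gets the minimum
  # group seen for that value
  grp <- ave(grp, risks, FUN = min)
  gs <- sort(unique(grp))
  tab <- do.call(rbind, lapply(gs, function(g) {
    i <- grp == g
    data.frame(n = sum(i), mean_risk = mean(risks[i]),
               observed = sum(events[i]), expected = sum(risks[i]))
  }))
  pibar <- tab$expected / tab$n
  denom <- tab$n * pibar * (1 - pibar)
  usable <- denom > 0
  if (any(!usable))
    warning(sprintf("%d group(s) with mean risk 0 or 1 skipped", sum(!usable)),
            call. = FALSE)
  chi2 <- sum((tab$observed[usable] - tab$expected[usable])^2 / denom[usable])
  df <- groups - 2
  structure(list(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 table = tab),
            class = "sa_hl")
}

#' @export
print.sa_hl <- function(x, digits = 3, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.*f, df = %d, p = %.*f\n",
              digits, x$chi2, x$df, digits, x$p_value))
  invisible(x)
}
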