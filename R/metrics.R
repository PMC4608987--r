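#' @importFrom stats sd var
NULL

#' Stratify a predicted risk at a threshold
#'
#' `"low"` iff risk <= threshold (the boundary belongs to the low category,
#' matching the `<=10% / >10%` table convention), else `"high"`.  Vectorised
#' over `risk`.
#'
#' @param risk Probabilities in (0, 1).
#' @param threshold Risk cut-point in (0, 1).
#' @return Character vector, `"low"`/`"high"`.
#' @export
stratify <- function(risk, threshold) {
  stopifnot(all(risk > 0 & risk < 1), threshold > 0, threshold < 1)
  ifelse(risk <= threshold, "low", "high")
}

risk_categories <- c("low", "high")

#' Build a reclassification table at one risk threshold
#'
#' Cross-tabulates old-model against new-model risk categories at a single
#' threshold, separately for subjects with the outcome (events) and without
#' (nonevents).  Rows are the established-model category, columns the
#' extended-model category.
#'
#' @param old_risk,new_risk Predicted probabilities from the established and
#'   the extended model, aligned.
#' @param event Logical outcome vector.
#' @param threshold Risk cut-point in (0, 1).
#' @return Object of class `reclass_table`: `threshold`, `events` and
#'   `nonevents` (2x2 integer matrices, dimnames low/high), `n_events`,
#'   `n_nonevents`.
#' @export
build_reclass_table <- function(old_risk, new_risk, event, threshold) {
  event <- as.logical(event)
  stopifnot(length(old_risk) == length(new_risk),
            length(old_risk) == length(event), length(old_risk) > 0,
            !anyNA(old_risk), !anyNA(new_risk), !anyNA(event))
  oc <- factor(stratify(old_risk, threshold), levels = risk_categories)
  nc <- factor(stratify(new_risk, threshold), levels = risk_categories)
  ev <- table(old = oc[event], new = nc[event])
  ne <- table(old = oc[!event], new = nc[!event])
  reclass_table(unclass(as.matrix(ev)), unclass(as.matrix(ne)), threshold)
}

#' Construct a reclassification table from counts
#'
#' Low-level constructor used by [build_reclass_table()] and when entering
#' published count tables directly.
#'
#' @param events,nonevents 2x2 count matrices, old category in rows, new in
#'   columns, ordered low then high.
#' @param threshold Risk cut-point the categories refer to.
#' @return A `reclass_table` object.
#' @export
reclass_table <- function(events, nonevents, threshold) {
  events <- as.matrix(events); nonevents <- as.matrix(nonevents)
  stopifnot(all(dim(events) == c(2, 2)), all(dim(nonevents) == c(2, 2)),
            all(events >= 0), all(nonevents >= 0),
            threshold > 0, threshold < 1)
  dimnames(events) <- dimnames(nonevents) <-
    list(old = risk_categories, new = risk_categories)
  structure(list(threshold = threshold,
                 events = events, nonevents = nonevents,
                 n_events = sum(events), n_nonevents = sum(nonevents)),
            class = "reclass_table")
}

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf("Reclassification table at threshold %.0f%% (events n = %d, nonevents n = %d)\n",
              100 * x$threshold, x$n_events, x$n_nonevents))
  cat("Events:\n"); print(x$events)
  cat("Nonevents:\n"); print(x$nonevents)
  invisible(x)
}

## ---- metric results ---------------------------------------------------

metric_result <- function(name, up, down, n, level = 0.95, sign = +1,
                          caveat = FALSE) {
  ## sign = +1: net-up is the estimate (events); -1: net-down (nonevents)
  not_available <- (n == 0) || (up == 0 && down == 0)
  estimate <- if (n > 0) sign * (up - down) / n else 0
  if (not_available) {
    se <- ci <- p <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    p_up <- up / n; p_down <- down / n
    se <- sqrt((p_up + p_down) / n)
    z <- qnorm(1 - (1 - level) / 2)
    ci <- estimate + c(-1, 1) * z * se
    p <- 2 * pnorm(-abs(estimate / se))
  }
  structure(list(name = name, estimate = estimate, se = se,
                 ci = ci, p_value = p, level = level, n = n,
                 movers_up = up, movers_down = down,
                 not_available = not_available, caveat = caveat),
            class = "sa_metric")
}

metric_from_moments <- function(name, estimate, se, n, level = 0.95,
                                caveat = FALSE) {
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(name = name, estimate = estimate, se = se,
                 ci = estimate + c(-1, 1) * z * se,
                 p_value = 2 * pnorm(-abs(estimate / se)),
                 level = level, n = n,
                 movers_up = NA_integer_, movers_down = NA_integer_,
                 not_available = FALSE, caveat = caveat),
            class = "sa_metric")
}

#' @export
print.sa_metric <- function(x, digits = 2, ...) {
  if (x$not_available) {
    cat(sprintf("%s: n.a. (no subject in the stratum changed category; n = %d)\n",
                x$name, x$n))
  } else {
    cat(sprintf("%s = %.*f%% (%.0f%% CI %.*f to %.*f%%), p = %.2g, n = %d\n",
                x$name, digits, 100 * x$estimate, 100 * x$level,
                digits, 100 * x$ci[1], digits, 100 * x$ci[2],
                x$p_value, x$n))
  }
  if (isTRUE(x$caveat))
    cat("  caveat: category-free reclassification counts every directional\n",
        " change and is prone to false-positive conclusions\n", sep = "")
  invisible(x)
}

#' Net Reclassification Index components and total
#'
#' `nri_events()` is the net proportion of subjects *with* the outcome moved
#' to a higher risk category when the new predictor is added:
#' \eqn{NRI_e = P(up|event) - P(down|event)}.  `nri_nonevents()` is the net
#' proportion of subjects *without* the outcome moved to a lower category:
#' \eqn{NRI_{ne} = P(down|nonevent) - P(up|nonevent)}.  Each ranges over
#' \[-100%, 100%\]; positive values mean improved classification.
#' `nri_overall()` is their sum, with the standard error combined in
#' quadrature.
#'
#' Inference is the asymptotic two-proportion form: the standard error of a
#' component is \eqn{\sqrt{(p_{up} + p_{down})/n}}, with a symmetric Wald
#' interval and a two-sided normal p-value.  When no subject in the stratum
#' changed category the estimate is 0 but the result is flagged
#' `not_available` (reported "n.a."), mirroring how such tables are
#' published.
#'
#' @param table A `reclass_table`.
#' @param level Confidence level, default 0.95.
#' @return An `sa_metric` object: `estimate` (proportion), `se`, `ci`,
#'   `p_value`, `n`, `movers_up`, `movers_down`, `not_available`.
#' @examples
#' tab <- reclass_table(events = matrix(c(21, 4, 7, 27), 2),
#'                      nonevents = matrix(c(318, 24, 49, 129), 2),
#'                      threshold = 0.10)
#' nri_events(tab)      # 5.09%
#' nri_nonevents(tab)   # -4.81%
#' @export
nri_events <- function(table, level = 0.95) {
  stopifnot(inherits(table, "reclass_table"))
  up <- table$events["low", "high"]; down <- table$events["high", "low"]
  metric_result("NRIe", up, down, table$n_events, level, sign = +1)
}

#' @rdname nri_events
#' @export
nri_nonevents <- function(table, level = 0.95) {
  stopifnot(inherits(table, "reclass_table"))
  up <- table$nonevents["low", "high"]; down <- table$nonevents["high", "low"]
  metric_result("NRIne", up, down, table$n_nonevents, level, sign = -1)
}

#' @rdname nri_events
#' @export
nri_overall <- function(table, level = 0.95) {
  e <- nri_events(table, level)
  ne <- nri_nonevents(table, level)
  if (e$not_available || ne$not_available) {
    out <- metric_result("NRI", 0, 0, table$n_events + table$n_nonevents,
                         level)
    out$estimate <- e$estimate + ne$estimate
    out$name <- "NRI"
    return(out)
  }
  se <- sqrt(e$se^2 + ne$se^2)
  out <- metric_from_moments("NRI", e$estimate + ne$estimate, se,
                             table$n_events + table$n_nonevents, level)
  out$movers_up <- e$movers_up + ne$movers_up
  out$movers_down <- e$movers_down + ne$movers_down
  out
}

#' Category-free Net Reclassification Index
#'
#' Counts *any* increase in predicted risk as an upward move and any decrease
#' as a downward move (exact ties stay), without risk categories.  Reported
#' with a prominent caveat: this variant is known to produce high rates of
#' false-positive conclusions and should not be interpreted on the same
#' scale as the categorical NRI.
#'
#' @param old_risk,new_risk Aligned probabilities from the two models.
#' @param event Logical outcome vector.
#' @param level Confidence level.
#' @return List of class `sa_cfnri` with elements `events`, `nonevents`,
#'   `overall` (each `sa_metric` with `caveat = TRUE`).
#' @export
category_free_nri <- function(old_risk, new_risk, event, level = 0.95) {
  event <- as.logical(event)
  stopifnot(length(old_risk) == length(new_risk),
            length(old_risk) == length(event), length(old_risk) > 0)
  d <- new_risk - old_risk
  up_e <- sum(d[event] > 0); down_e <- sum(d[event] < 0)
  up_n <- sum(d[!event] > 0); down_n <- sum(d[!event] < 0)
  e <- metric_result("NRIe(>0)", up_e, down_e, sum(event), level,
                     sign = +1, caveat = TRUE)
  ne <- metric_result("NRIne(>0)", up_n, down_n, sum(!event), level,
                      sign = -1, caveat = TRUE)
  ov <- if (e$not_available || ne$not_available) {
    tmp <- metric_result("NRI(>0)", 0, 0, length(event), level, caveat = TRUE)
    tmp$estimate <- e$estimate + ne$estimate
    tmp
  } else {
    metric_from_moments("NRI(>0)", e$estimate + ne$estimate,
                        sqrt(e$se^2 + ne$se^2), length(event), level,
                        caveat = TRUE)
  }
  structure(list(events = e, nonevents = ne, overall = ov),
            class = "sa_cfnri")
}

#' @export
print.sa_cfnri <- function(x, ...) {
  cat("Category-free NRI (any risk change counts as a move)\n")
  print(x$events); print(x$nonevents)
  cat("Overall: ")
  if (x$overall$not_available) cat("n.a.\n") else
    cat(sprintf("%.2f%%\n", 100 * x$overall$estimate))
  invisible(x)
}

#' Discrimination slope
#'
#' Mean predicted risk among subjects with the outcome minus the mean among
#' those without; the absolute separation a model achieves.
#'
#' @param risks Predicted probabilities.
#' @param events Logical outcome vector; both classes must be present.
#' @return A single number.
#' @export
discrimination_slope <- function(risks, events) {
  events <- as.logical(events)
  stopifnot(length(risks) == length(events))
  if (!any(events) || all(events))
    stop("discrimination slope undefined: only one outcome class present")
  mean(risks[events]) - mean(risks[!events])
}

#' Integrated discrimination improvement
#'
#' Change in discrimination slope from the established to the extended model:
#' \deqn{IDI = slope_{new} - slope_{old}
#'           = \overline{\Delta}_{events} - \overline{\Delta}_{nonevents}}
#' where \eqn{\Delta = new - old} per subject.  The standard error comes from
#' the two-sample formulation on the per-subject risk differences,
#' \eqn{\sqrt{SE_{events}^2 + SE_{nonevents}^2}}, with a Wald interval and
#' two-sided p-value.  Range -100% to 100%; positive values mean the new
#' predictor separates events from nonevents better.
#'
#' @param old_risk,new_risk Aligned probabilities from the two models.
#' @param event Logical outcome vector; both classes must be present.
#' @param level Confidence level.
#' @return An `sa_metric` object named `"IDI"`.
#' @export
idi <- function(old_risk, new_risk, event, level = 0.95) {
  event <- as.logical(event)
  stopifnot(length(old_risk) == length(new_risk),
            length(old_risk) == length(event))
  if (!any(event) || all(event))
    stop("IDI undefined: only one outcome class present")
  d <- new_risk - old_risk
  de <- d[event]; dn <- d[!event]
  est <- mean(de) - mean(dn)
  se_e <- if (length(de) > 1) sd(de) / sqrt(length(de)) else 0
  se_n <- if (length(dn) > 1) sd(dn) / sqrt(length(dn)) else 0
  se <- sqrt(se_e^2 + se_n^2)
  if (se == 0) {
    out <- metric_from_moments("IDI", est, 1, length(event), level)
    out$se <- 0; out$ci <- c(est, est)
    out$p_value <- if (est == 0) 1 else 0
    return(out)
  }
  metric_from_moments("IDI", est, se, length(event), level)
}

#' Count reclassified subjects
#'
#' Number (and cohort proportion) of subjects in any off-diagonal cell of a
#' reclassification table, events and nonevents combined.
#'
#' @param table A `reclass_table`.
#' @return List with `count` and `proportion`.
#' @export
count_reclassified <- function(table) {
  stopifnot(inherits(table, "reclass_table"))
  off <- function(m) m["low", "high"] + m["high", "low"]
  count <- unname(off(table$events) + off(table$nonevents))
  list(count = count,
       proportion = count / (table$n_events + table$n_nonevents))
}

#' Bootstrap percentile confidence interval for a reclassification metric
#'
#' Case--noncase stratified resampling: events and nonevents are resampled
#' separately with replacement, the chosen metric is recomputed per
#' replicate, and a percentile interval is taken.  Deterministic given
#' `seed`.  If the metric is unavailable (no movers) in more than half of
#' the replicates the result is flagged `not_available`.
#'
#' @param old_risk,new_risk,event As in [idi()].
#' @param metric One of `"nri_events"`, `"nri_nonevents"`, `"nri_overall"`,
#'   `"idi"`, `"cfnri_overall"`.
#' @param threshold Risk threshold (required for the categorical NRI
#'   metrics).
#' @param replicates Number of bootstrap replicates, at least 100.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return An `sa_metric` with the point estimate on the full data, the
#'   bootstrap standard error, and the percentile interval.
#' @export
bootstrap_ci <- function(old_risk, new_risk, event,
                         metric = c("nri_events", "nri_nonevents",
                                    "nri_overall", "idi", "cfnri_overall"),
                         threshold = NULL, replicates = 2000, level = 0.95,
                         seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(replicates >= 100)
  event <- as.logical(event)
  if (metric %in% c("nri_events", "nri_nonevents", "nri_overall") &&
      is.null(threshold))
    stop("categorical NRI metrics need a threshold")
  eval_metric <- function(o, nw, ev) {
    m <- switch(metric,
      nri_events = nri_events(build_reclass_table(o, nw, ev, threshold)),
      nri_nonevents = nri_nonevents(build_reclass_table(o, nw, ev, threshold)),
      nri_overall = nri_overall(build_reclass_table(o, nw, ev, threshold)),
      idi = idi(o, nw, ev),
      cfnri_overall = category_free_nri(o, nw, ev)$overall)
    if (isTRUE(m$not_available)) NA_real_ else m$estimate
  }
  point <- eval_metric(old_risk, new_risk, event)
  ie <- which(event); ine <- which(!event)
  est <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      i <- c(sample(ie, length(ie), replace = TRUE),
             sample(ine, length(ine), replace = TRUE))
      eval_metric(old_risk[i], new_risk[i], event[i])
    }, numeric(1))
  })
  n_na <- sum(is.na(est))
  out <- structure(list(name = paste0(metric, " (bootstrap)"),
                        estimate = if (is.na(point)) 0 else point,
                        se = NA_real_, ci = c(NA_real_, NA_real_),
                        p_value = NA_real_, level = level,
                        n = length(event),
                        movers_up = NA_integer_, movers_down = NA_integer_,
                        not_available = FALSE, caveat = FALSE,
                        replicates = replicates, failed_replicates = n_na),
                   class = "sa_metric")
  if (n_na > replicates / 2) {
    out$not_available <- TRUE
    attr(out, "diagnostic") <-
      sprintf("metric unavailable in %d/%d bootstrap replicates",
              n_na, replicates)
    return(out)
  }
  alpha <- (1 - level) / 2
  out$ci <- unname(quantile(est, c(alpha, 1 - alpha), na.rm = TRUE))
  out$se <- sd(est, na.rm = TRUE)
  out
}
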