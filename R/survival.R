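#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood variance and log-log 95% CIs
#' (via \pkg{survival}), returned as a tidy per-event-time table.
#'
#' @param times follow-up times (months, >= 0).
#' @param events 0/1 event flags (0 = censored).
#' @return list of class `km_curve`: data.frame `table` (`time`, `n_risk`,
#'   `n_event`, `survival`, `std_err`, `lower`, `upper`) and the underlying
#'   `survfit` object.
#' @export
km_estimate <- function(times, events) {
  stop_if_not(length(times) > 0, "empty input")
  stop_if_not(all(times >= 0), "times must be >= 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  s <- summary(fit, censored = FALSE)
  tab <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    survival = s$surv, std_err = s$std.err,
                    lower = s$lower, upper = s$upper)
  structure(list(table = tab, fit = fit), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, conf.int = TRUE, xlab = "months", ylab = "survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' one degree of freedom.
#'
#' @param times,events follow-up data.
#' @param group two-level grouping vector.
#' @return list with `chisq`, `p`, `df`.
#' @export
logrank_test <- function(times, events, group) {
  g <- as.factor(group)
  stop_if_not(nlevels(g) == 2 && all(table(g) > 0),
              "need two non-empty groups")
  if (sum(events) == 0) {
    warning("no events at all: log-rank statistic undefined")
    return(list(chisq = NA_real_, p = NA_real_, df = 1L))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chisq = sd$chisq, p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Cox proportional-hazards fit
#'
#' Efron-tie partial-likelihood maximization via \pkg{survival}, with Wald
#' 95% CIs and p-values per covariate.
#'
#' @param covariates data.frame or matrix of covariates (no constant
#'   columns).
#' @param times,events follow-up data.
#' @return object of class `cox_fit`: data.frame `table` (`covariate`,
#'   `coef`, `hr`, `lower`, `upper`, `p`) and the `coxph` object.
#' @export
cox_fit <- function(covariates, times, events) {
  x <- as.data.frame(covariates)
  stop_if_not(ncol(x) >= 1, "need at least one covariate")
  for (nm in names(x))
    stop_if_not(length(unique(x[[nm]])) > 1,
                sprintf("covariate '%s' is constant", nm))
  df <- cbind(data.frame(.time = times, .event = events), x)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  sm <- summary(fit)
  tab <- data.frame(covariate = names(x),
                    coef = unname(stats::coef(fit)),
                    hr = unname(exp(stats::coef(fit))),
                    lower = unname(sm$conf.int[, "lower .95"]),
                    upper = unname(sm$conf.int[, "upper .95"]),
                    p = unname(sm$coefficients[, "Pr(>|z|)"]))
  structure(list(table = tab, fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Univariable screen followed by a multivariable Cox model
#'
#' Fits each candidate covariate univariably; covariates with univariable
#' `p < p_enter` (default 0.20) enter the joint multivariable model.
#'
#' @param covariates data.frame of candidate covariates.
#' @param times,events follow-up data.
#' @param p_enter entry threshold (default 0.20).
#' @return list of class `cox_screen`: `univariable` (data.frame),
#'   `multivariable` (`cox_fit` or `NULL` if nothing entered), `entered`.
#' @export
multivariable_screen <- function(covariates, times, events, p_enter = 0.20) {
  x <- as.data.frame(covariates)
  stop_if_not(ncol(x) >= 1, "need at least one candidate covariate")
  uni <- do.call(rbind, lapply(names(x), function(nm)
    cox_fit(x[, nm, drop = FALSE], times, events)$table))
  entered <- uni$covariate[uni$p < p_enter]
  multi <- if (length(entered) > 0)
    cox_fit(x[, entered, drop = FALSE], times, events) else NULL
  structure(list(univariable = uni, multivariable = multi,
                 entered = entered, p_enter = p_enter),
            class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  cat("Univariable Cox fits:\n")
  print(x$univariable, row.names = FALSE, digits = 4)
  if (is.null(x$multivariable)) {
    cat(sprintf("No covariate reached p < %.2f; multivariable stage empty\n",
                x$p_enter))
  } else {
    cat(sprintf("Multivariable model (p < %.2f: %s):\n", x$p_enter,
                paste(x$entered, collapse = ", ")))
    print(x$multivariable)
  }
  invisible(x)
}

#' Survival stratification by classifier positivity
#'
#' Kaplan-Meier curves per group, the log-rank test, and a univariable Cox
#' fit of the positivity indicator, for one endpoint.
#'
#' @param times,events follow-up data; @param positive logical/0-1 MEL-RAD
#'   positivity per patient.
#' @return list with `km_positive`, `km_negative`, `logrank`, `cox`.
#' @export
stratified_survival <- function(times, events, positive) {
  pos <- as.integer(positive)
  res <- list(
    km_positive = km_estimate(times[pos == 1], events[pos == 1]),
    km_negative = km_estimate(times[pos == 0], events[pos == 0]),
    logrank = logrank_test(times, events, pos),
    cox = cox_fit(data.frame(melrad_positive = pos), times, events))
  res
}
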