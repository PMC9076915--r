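#' Kaplan-Meier product-limit estimate per group
#'
#' Wraps [survival::survfit()]: `S(t)` is the product over event times up
#' to `t` of `1 - d_i / n_i`, with censoring handled by risk-set
#' decrement. Curves are non-increasing, start at 1, and change only at
#' event times.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Optional group labels; a single curve when omitted.
#' @return Data frame `group`, `time`, `n_risk`, `n_event`, `surv`, with
#'   the underlying `survfit` object attached as attribute `fit`.
#' @export
km_fit <- function(time, event, group = NULL) {
  if (any(time < 0)) stop("km_fit: negative times")
  if (is.null(group)) group <- rep("all", length(time))
  g <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  if (length(levels(g)) == 1L) {
    grp <- rep(levels(g), length(fit$time))
  } else {
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  out <- data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each event time, observed minus expected events in
#' the first group with hypergeometric variance; the statistic
#' `(sum(O - E))^2 / sum(V)` is referred to chi-square with one degree of
#' freedom. Computed via [survival::survdiff()].
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Exactly two nonempty groups; at least one event overall.
#' @return List `chi2`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (length(levels(g)) != 2L)
    stop("logrank_test: exactly two groups required")
  if (any(table(g) == 0)) stop("logrank_test: empty group")
  if (sum(event) < 1) stop("logrank_test: no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Two-group Cox proportional-hazards estimate
#'
#' Maximizes the partial likelihood for a single binary covariate
#' (Breslow tie handling, Newton iteration via [survival::coxph()]); the
#' standard error comes from the observed information and the 95% CI and
#' p-value are Wald. The first factor level of `group` is the reference.
#' When every event falls in one group the partial likelihood is monotone
#' and no finite estimate exists; the fit is returned with `diverged =
#' TRUE` and the sign of the diverging log hazard ratio instead of a
#' number.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping; first level is the reference.
#' @return List of class `cox_fit`: `log_hr`, `se`, `hr`, `ci95`, `p`,
#'   `reference`, `diverged`, `divergence_sign`.
#' @export
cox_two_group <- function(time, event, group) {
  g <- factor(group)
  if (length(levels(g)) != 2L)
    stop("cox_two_group: exactly two groups required")
  if (sum(event) < 1) stop("cox_two_group: no events in pooled data")
  ref <- levels(g)[1]
  ev_by_group <- tapply(event, g, sum)
  if (any(ev_by_group == 0)) {
    sign <- if (ev_by_group[2] > 0) 1 else -1
    return(structure(list(log_hr = NA_real_, se = NA_real_, hr = NA_real_,
                          ci95 = c(NA_real_, NA_real_), p = NA_real_,
                          reference = ref, diverged = TRUE,
                          divergence_sign = sign),
                     class = "cox_fit"))
  }
  fit <- survival::coxph(
    survival::Surv(time, event) ~ g, ties = "breslow",
    control = survival::coxph.control(eps = 1e-10, iter.max = 50L))
  b <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  structure(list(
    log_hr = b, se = se, hr = exp(b),
    ci95 = exp(b + c(-1, 1) * 1.96 * se),
    p = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE),
    reference = ref, diverged = FALSE, divergence_sign = NA_real_
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$diverged) {
    cat(sprintf("Cox two-group fit: monotone likelihood (log HR -> %sInf)\n",
                ifelse(x$divergence_sign > 0, "+", "-")))
  } else {
    cat(sprintf(
      "Cox two-group fit vs %s: HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
      x$reference, x$hr, x$ci95[1], x$ci95[2], x$p))
  }
  invisible(x)
}
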