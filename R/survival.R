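# Kaplan-Meier estimation, G-rho (Fleming-Harrington) tests and
# univariate Cox screening of expression features, built on the survival
# package.

check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (!nrow(records)) stop("no survival records")
  if (any(records$time <= 0)) stop("survival times must be positive")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records `data.frame` with `time` (> 0) and `event`
#'   (1 = death, 0 = censored) columns.
#' @return `data.frame(time, n_risk, n_event, surv)`: the step function
#'   S(t) evaluated at the distinct observed times (right-continuous,
#'   non-increasing; S = 1 before the first event).
#' @export
km_estimate <- function(records) {
  check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' G-rho family (Fleming-Harrington) test of survival curves
#'
#' Weighted log-rank with weights `S(t-)^rho` from the pooled
#' Kaplan-Meier; `rho = 0` is the ordinary log-rank, `rho = 1` the
#' Peto-Wilcoxon variant.
#'
#' @param records Survival records (see [km_estimate()]).
#' @param groups Group label per record (>= 2 non-empty groups).
#' @param rho Weighting exponent.
#' @return List with `statistic` (chi-square), `df`, `p`, `rho`.
#' @export
grho_test <- function(records, groups, rho = 0) {
  check_records(records)
  groups <- as.character(groups)
  if (length(groups) != nrow(records))
    stop("one group label per record required")
  tab <- table(groups)
  if (length(tab) < 2L || any(tab == 0)) stop("need >= 2 non-empty groups")
  if (sum(records$event) < 1L) stop("need at least one event")
  d <- cbind(records, .grp = groups)
  fit <- survival::survdiff(survival::Surv(time, event) ~ .grp, data = d,
                            rho = rho)
  df <- length(fit$n) - 1L
  list(statistic = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE), rho = rho)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; reports the Wald test
#' of the single covariate. Non-convergence or an infinite coefficient
#' (monotone likelihood) is flagged rather than silently returned.
#'
#' @param records Survival records.
#' @param covariate Numeric value per record; must vary.
#' @return List with `beta`, `hr`, `se`, `z`, `p`, `flagged`.
#' @export
cox_univariate <- function(records, covariate) {
  check_records(records)
  if (length(covariate) != nrow(records))
    stop("one covariate value per record required")
  if (stats::sd(covariate) == 0) stop("covariate does not vary")
  if (sum(records$event) < 2L) stop("need >= 2 events")
  d <- cbind(records, .x = covariate)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ .x, data = d,
                    ties = "efron", control = survival::coxph.control(iter.max = 50)),
    warning = function(w) structure(suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ .x, data = d,
                      ties = "efron",
                      control = survival::coxph.control(iter.max = 50))),
      flagged = TRUE))
  flagged <- isTRUE(attr(fit, "flagged"))
  s <- summary(fit)
  beta <- unname(s$coefficients[1, "coef"])
  se <- unname(s$coefficients[1, "se(coef)"])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 20) flagged <- TRUE
  list(beta = beta, hr = exp(beta), se = se, z = beta / se,
       p = unname(s$coefficients[1, "Pr(>|z|)"]), flagged = flagged)
}

#' Screen expression features for prognostic association
#'
#' Per feature: a univariate Cox regression of survival on the
#' (transformed) expression values, plus a median-split log-rank p for
#' Kaplan-Meier display. A feature is called significant when the Cox
#' Wald p is below `alpha`; both p-values are reported.
#'
#' @param x Transformed `ExpressionMatrix`.
#' @param surv `data.frame(sample_id, time, event)`; samples must exist
#'   in `x` (extra expression samples are ignored).
#' @param alpha Significance cut on the Cox p.
#' @param rho G-rho exponent for the median-split test.
#' @return `data.frame(feature_id, beta, hr, p_cox, p_logrank,
#'   significant, flagged)`, one row per feature.
#' @export
prognostic_screen <- function(x, surv, alpha = 0.05, rho = 0) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            all(c("sample_id", "time", "event") %in% names(surv)))
  check_records(surv)
  miss <- setdiff(surv$sample_id, colnames(x$values))
  if (length(miss)) stop("survival sample absent from expression: ", miss[1])
  expr <- x$values[, surv$sample_id, drop = FALSE]
  n_feat <- nrow(expr)
  out <- data.frame(feature_id = rownames(expr), beta = NA_real_,
                    hr = NA_real_, p_cox = NA_real_, p_logrank = NA_real_,
                    significant = FALSE, flagged = FALSE)
  for (i in seq_len(n_feat)) {
    v <- expr[i, ]
    if (stats::sd(v) == 0) { out$flagged[i] <- TRUE; next }
    cx <- tryCatch(cox_univariate(surv, v), error = function(e) NULL)
    if (is.null(cx)) { out$flagged[i] <- TRUE; next }
    out$beta[i] <- cx$beta
    out$hr[i] <- cx$hr
    out$p_cox[i] <- cx$p
    out$flagged[i] <- cx$flagged
    grp <- ifelse(v > stats::median(v), "high", "low")
    if (length(unique(grp)) == 2L)
      out$p_logrank[i] <- tryCatch(grho_test(surv, grp, rho)$p,
                                   error = function(e) NA_real_)
  }
  out$significant <- !is.na(out$p_cox) & out$p_cox < alpha
  out
}
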