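#' Kaplan-Meier curves per group
#'
#' Product-limit estimator with Greenwood standard errors, one curve per
#' group.
#'
#' @param time positive survival times (months).
#' @param event event indicators (1 = event, 0 = censored).
#' @param groups per-subject group labels (a single group when omitted).
#' @return named list of `km_curve` data.frames (time, n_risk, n_event,
#'   surv, std_err).
#' @export
kaplan_meier <- function(time, event, groups = NULL) {
  if (any(time <= 0)) dsp_stop("survival times must be positive")
  if (is.null(groups)) groups <- rep("all", length(time))
  groups <- as.character(groups)
  if (any(table(factor(groups)) == 0)) dsp_stop("group with zero subjects")
  out <- lapply(split(seq_along(time), groups), function(ix) {
    fit <- survival::survfit(survival::Surv(time[ix], event[ix]) ~ 1,
                             conf.type = "log")
    structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                         n_event = fit$n.event, n_censor = fit$n.censor,
                         surv = fit$surv, std_err = fit$std.err),
              class = c("km_curve", "data.frame"))
  })
  out
}

#' Log-rank test
#'
#' Standard observed-minus-expected chi-square over event times with
#' `df = n_groups - 1`.
#'
#' @param time positive survival times.
#' @param event event indicators.
#' @param groups group labels (>= 2 groups; >= 1 event overall).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) dsp_stop("log-rank needs >= 2 groups")
  if (sum(event) < 1) dsp_stop("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson fit with Efron tie handling (Breslow by
#' flag); Wald 95% confidence interval `exp(beta +/- 1.96 se)`.
#'
#' @param time positive survival times.
#' @param event event indicators (>= 5 events).
#' @param covariates data.frame (or vector) of covariates; each must vary.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a `survival_fit` list: per-covariate `coef` (log HR), `hr`,
#'   `ci_lower`, `ci_upper`, `se`, `wald_p`; plus `n`, `n_events`,
#'   `converged`, and the underlying `coxph` fit.
#' @export
cox_ph <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(event) < 5) dsp_stop("need at least 5 events for a Cox fit")
  if (is.null(dim(covariates))) covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v)) < 2) {
      dsp_stop("non-identifiable: covariate '%s' is constant", nm)
    }
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ ., data = dat, ties = ties,
    control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  if (any(!is.finite(fit$coefficients)) ||
      any(sqrt(diag(fit$var)) > 1e3)) {
    dsp_stop("monotone likelihood (complete separation): Cox fit did not stabilize")
  }
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  structure(list(
    coef = beta, hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    se = se, wald_p = 2 * stats::pnorm(-abs(beta / se)),
    n = fit$n, n_events = sum(event),
    converged = fit$iter < 100, fit = fit), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d\n", x$n, x$n_events))
  for (i in seq_along(x$coef)) {
    cat(sprintf("  %s: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                names(x$coef)[i], x$hr[i], x$ci_lower[i], x$ci_upper[i],
                x$wald_p[i]))
  }
  invisible(x)
}

#' Proportional-hazards assumption check
#'
#' Score test on the correlation of scaled Schoenfeld residuals with
#' Kaplan-Meier-transformed time; advisory only.
#'
#' @param fit a `survival_fit` from [cox_ph()].
#' @return named vector of per-covariate p-values (plus `GLOBAL`).
#' @export
ph_assumption_check <- function(fit) {
  if (fit$n_events < 3) dsp_stop("need at least 3 events for the PH check")
  z <- survival::cox.zph(fit$fit, transform = "km")
  stats::setNames(z$table[, "p"], rownames(z$table))
}

#' Top-vs-bottom tertile survival comparison
#'
#' Cox fit of the extreme tertile groups (high vs low, low as reference) with
#' optional extra covariates, the log-rank test over the compared groups, and
#' per-group Kaplan-Meier curves — the standard read-out for a stratified
#' signature.
#'
#' @param strat a `stratification` from [tertile_stratify()].
#' @param survival_df data.frame with patient_id, time, event.
#' @param covariates optional data.frame of additional per-patient covariates
#'   (rows aligned to `survival_df`).
#' @return list with `cox` (a `survival_fit`; coefficient `grouphigh` is the
#'   high-vs-low log HR), `logrank`, `km` (all three tertiles) and `n`.
#' @export
tertile_survival <- function(strat, survival_df, covariates = NULL) {
  dat <- merge(strat, survival_df, by = "patient_id")
  km <- kaplan_meier(dat$time, dat$event, dat$group)
  ext <- dat[dat$group %in% c("low", "high"), , drop = FALSE]
  covs <- data.frame(group = factor(as.character(ext$group),
                                    levels = c("low", "high")))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cv$patient_id <- survival_df$patient_id
    ext_cv <- merge(ext["patient_id"], cv, by = "patient_id", sort = FALSE)
    covs <- cbind(covs, ext_cv[setdiff(names(ext_cv), "patient_id")])
  }
  cox <- cox_ph(ext$time, ext$event, covs)
  lr <- logrank_test(ext$time, ext$event, ext$group)
  list(cox = cox, logrank = lr, km = km, n = nrow(dat))
}
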