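#' Build an onset survival table from a cohort
#'
#' Extracts cases with an observed onset age into the `(time, event)` form
#' the onset analyses consume. Every case is an event (onset observed);
#' right-censored records can be added by hand for generality.
#'
#' @param cohort A `ps_cohort`.
#' @param groups Optional vector (or `ps_prs_groups`) assigning a group
#'   label per sample; matched by `sample_id` when a tibble is given.
#' @return Tibble: `sample_id`, `time` (onset age), `event` (1), `age`,
#'   `sex`, `family_history`, plus `group` when supplied.
#' @export
onset_data <- function(cohort, groups = NULL) {
  ph <- phenotypes(cohort)
  d <- ph[ph$status == 1 & !is.na(ph$onset_age), ]
  out <- tibble::tibble(sample_id = d$sample_id, time = d$onset_age,
                        event = 1L, age = d$age, sex = d$sex,
                        family_history = d$family_history)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      out$group <- groups$group[match(out$sample_id, groups$sample_id)]
    } else {
      out$group <- groups[match(out$sample_id, cohort$sample_id)]
    }
  }
  out
}

#' Kaplan-Meier curve of age of onset
#'
#' Product-limit estimator of the probability of remaining disease-free by
#' age; supports right-censoring (`event = 0`). The median onset is the
#' smallest time at which the survival estimate drops to 0.5 or below.
#'
#' @param data Data frame with `time` and optionally `event` (default all
#'   events).
#' @return Object of class `ps_km`: `curve` tibble (time, n_risk, n_event,
#'   survival), `median`, `n`.
#' @export
km_fit <- function(data) {
  d <- tibble::as_tibble(data)
  if (!"event" %in% names(d)) d$event <- 1L
  if (any(is.na(d$time)) || any(d$time <= 0)) abort("times must be positive")
  if (sum(d$event) < 1) abort("need at least one event")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  curve <- tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                          n_event = sf$n.event, survival = sf$surv)
  med <- unname(quantile(sf, probs = 0.5)$quantile)
  structure(list(curve = curve, median = med, n = nrow(d)), class = "ps_km")
}

#' @export
print.ps_km <- function(x, ...) {
  cat("<ps_km> n =", x$n, " median onset =", x$median, "\n")
  invisible(x)
}

#' Log-rank test across onset groups
#'
#' Mantel-Haenszel log-rank chi-square comparing the onset-time
#' distributions of k groups (k - 1 degrees of freedom).
#'
#' @param data Data frame with `time`, `group`, optional `event`.
#' @return One-row tibble: statistic, df, p.value, n.
#' @export
logrank_test <- function(data) {
  d <- tibble::as_tibble(data)
  if (!"event" %in% names(d)) d$event <- 1L
  d <- d[!is.na(d$group) & !is.na(d$time), ]
  k <- length(unique(d$group))
  if (k < 2) abort("log-rank needs at least two nonempty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  tibble::tibble(statistic = sd$chisq, df = k - 1,
                 p.value = pchisq(sd$chisq, k - 1, lower.tail = FALSE),
                 n = nrow(d))
}

#' Cox proportional-hazards model of onset age
#'
#' Newton-Raphson maximisation of the Efron-tie-corrected partial
#' likelihood (Breslow available by flag), as in `survival::coxph`. Onset
#' ages in whole years are heavily tied, hence the Efron default. Constant
#' covariates and monotone likelihoods (perfect ordering) raise explicit
#' errors.
#'
#' @param data Data frame with `time`, optional `event`, and covariates.
#' @param formula Right-hand side naming the covariate terms, e.g.
#'   `~ prs + age + sex`.
#' @param ties `"efron"` or `"breslow"`.
#' @return Object of class `ps_cox`: coefficient tibble (estimate, hazard
#'   ratio, std.error, statistic, p.value), partial log-likelihood, n.
#' @export
cox_fit <- function(data, formula, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  d <- tibble::as_tibble(data)
  if (!"event" %in% names(d)) d$event <- 1L
  terms_rhs <- attr(stats::terms(formula), "term.labels")
  for (v in intersect(all.vars(formula), names(d))) {
    vals <- d[[v]][!is.na(d[[v]])]
    if (length(unique(vals)) < 2) {
      abort(paste0("covariate ", v, " is constant"))
    }
  }
  full <- stats::update(formula, survival::Surv(time, event) ~ .)
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(full, data = d, ties = ties),
      warning = function(w) {
        if (grepl("infinite|did not converge|beta may be infinite",
                  conditionMessage(w))) {
          abort(paste0("monotone partial likelihood (coefficient diverges): ",
                       conditionMessage(w)))
        }
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) abort(paste0("Cox fit failed: ", conditionMessage(e)))
  )
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  structure(list(
    coefficients = tibble::tibble(
      term = names(cf), estimate = unname(cf), hazard_ratio = exp(unname(cf)),
      std.error = unname(se), statistic = unname(z),
      p.value = unname(2 * pnorm(-abs(z)))),
    loglik = fit$loglik[2], n = fit$n, ties = ties, coxph = fit),
    class = "ps_cox")
}

#' @export
coef.ps_cox <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
print.ps_cox <- function(x, ...) {
  cat("<ps_cox> n =", x$n, " ties =", x$ties, "\n")
  print(x$coefficients)
  invisible(x)
}

#' @method tidy ps_cox
#' @export
tidy.ps_cox <- function(x, ...) x$coefficients

#' @method glance ps_cox
#' @export
glance.ps_cox <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, df = nrow(x$coefficients), n = x$n)
}

#' One-way ANOVA of onset age across groups
#'
#' F test of equal mean onset age across risk groups.
#'
#' @param data Data frame with `time` (onset age) and `group`.
#' @return One-row tibble: statistic (F), df_between, df_within, p.value.
#' @export
onset_anova <- function(data) {
  d <- tibble::as_tibble(data)
  d <- d[!is.na(d$group) & !is.na(d$time), ]
  sizes <- table(d$group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("ANOVA needs >= 2 groups with >= 2 cases each")
  }
  a <- anova(lm(time ~ factor(group), data = d))
  tibble::tibble(statistic = a$`F value`[1],
                 df_between = a$Df[1], df_within = a$Df[2],
                 p.value = a$`Pr(>F)`[1])
}

#' Difference in Kaplan-Meier median onset between two groups
#'
#' `median(KM of group_b) - median(KM of group_a)`; with an onset hazard
#' increasing in PRS, higher-risk groups onset earlier, so
#' `median_onset_gap(data, high, low) < 0` and
#' `median_onset_gap(data, low, high) > 0`.
#'
#' @param data Data frame with `time`, `group`, optional `event`.
#' @param group_a,group_b The two group labels.
#' @return The gap in years (positive when `group_b` onsets later).
#' @export
median_onset_gap <- function(data, group_a, group_b) {
  d <- tibble::as_tibble(data)
  med <- function(g) {
    m <- km_fit(d[!is.na(d$group) & d$group == g, ])$median
    if (is.na(m)) abort(paste0("KM median undefined for group ", g,
                               " (survival never reaches 0.5)"))
    m
  }
  med(group_b) - med(group_a)
}
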