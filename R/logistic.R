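#' Fit a logistic regression risk model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, as in `stats::glm`), returning Wald standard errors, z and
#' p-values per term together with the fitted and null log-likelihoods.
#' Singular designs and complete separation (diverging coefficients) raise
#' explicit errors naming the offending term.
#'
#' @param data Data frame holding the response and model terms.
#' @param formula Model formula, e.g. `status ~ score + age + sex`.
#' @return Object of class `ps_logit`: coefficient tibble, covariance
#'   matrix, log-likelihoods, sample size, and the underlying `glm` fit.
#' @examples
#' d <- data.frame(y = rep(c(0, 1), c(20, 20)),
#'                 x = rep(c(0, 1, 0, 1), c(15, 5, 5, 15)))
#' exp(coef(fit_logistic(d, y ~ x))["x"])  # 2x2 odds ratio 9
#' @export
fit_logistic <- function(data, formula) {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2) abort("response is constant; cannot fit")
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    abort(paste0("singular design: term(s) ",
                 paste(dropped, collapse = ", "),
                 " aliased with earlier columns"))
  }
  fit <- suppressWarnings(glm(formula, data = data, family = binomial(),
                              control = stats::glm.control(epsilon = 1e-14,
                                                           maxit = 200)))
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("singular design: term(s) ",
                 paste(names(cf)[is.na(cf)], collapse = ", "),
                 " aliased with earlier columns"))
  }
  if (nrow(mf) <= length(cf)) abort("more terms than observations")
  big <- abs(cf) > 15 & names(cf) != "(Intercept)"
  eps <- 1e-8
  sep <- any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps)
  if (any(big) && sep) {
    abort(paste0("complete separation detected for term(s): ",
                 paste(names(cf)[big], collapse = ", ")))
  }
  vc <- vcov(fit)
  se <- sqrt(diag(vc))
  z <- cf / se
  coefs <- tibble::tibble(
    term = names(cf), estimate = unname(cf), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
  )
  ll1 <- as.numeric(logLik(fit))
  null_fit <- suppressWarnings(glm(stats::update(formula, . ~ 1),
                                   data = mf, family = binomial()))
  structure(list(coefficients = coefs, vcov = vc,
                 loglik = ll1, null_loglik = as.numeric(logLik(null_fit)),
                 n = nrow(mf), formula = formula, glm = fit,
                 converged = fit$converged),
            class = "ps_logit")
}

#' @export
coef.ps_logit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.ps_logit <- function(object, ...) object$vcov

#' @export
logLik.ps_logit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$coefficients), class = "logLik")
}

#' @export
print.ps_logit <- function(x, ...) {
  cat("<ps_logit> n =", x$n, " logLik =", format(x$loglik, digits = 6), "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `ps_logit`.
#' @param exponentiate Also report `or` (= exp(estimate)) with Wald 95% CI?
#' @param ... Unused.
#' @return Tibble with one row per term: estimate, std.error, statistic
#'   (Wald z), p.value, and optionally or/or_lo/or_hi.
#' @method tidy ps_logit
#' @export
tidy.ps_logit <- function(x, exponentiate = FALSE, ...) {
  out <- x$coefficients
  if (exponentiate) {
    out$or <- exp(out$estimate)
    out$or_lo <- exp(out$estimate - 1.96 * out$std.error)
    out$or_hi <- exp(out$estimate + 1.96 * out$std.error)
  }
  out
}

#' One-line summary of a logistic fit
#'
#' @param x A `ps_logit`.
#' @param ... Unused.
#' @return One-row tibble: logLik, null logLik, Nagelkerke pseudo-R2,
#'   number of terms, n, convergence flag.
#' @method glance ps_logit
#' @export
glance.ps_logit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, null_logLik = x$null_loglik,
    r2_nagelkerke = nagelkerke_r2(x),
    df = nrow(x$coefficients), n = x$n, converged = x$converged
  )
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `R2 = 1 - exp(2 (LL0 - LL1) / n)` rescaled by its maximum
#' attainable value `1 - exp(2 LL0 / n)`. Used as the "phenotypic variation
#' explained" of a logistic risk model.
#'
#' @param fit A `ps_logit` carrying null and fitted log-likelihoods.
#' @return Fraction in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  cs <- 1 - exp(2 * (fit$null_loglik - fit$loglik) / fit$n)
  cs_max <- 1 - exp(2 * fit$null_loglik / fit$n)
  cs / cs_max
}

#' Continuous-PRS logistic effect
#'
#' Fits case/control status on the continuous PRS plus covariates (age and
#' sex by default); the PRS coefficient is the per-unit log-odds (the
#' study-style "beta").
#'
#' @param prs A `ps_prs` from [compute_prs()].
#' @param covariate_data Data frame with `sample_id` and covariate columns
#'   (`NULL` for an unadjusted fit).
#' @param covariates Covariate column names.
#' @return A `ps_logit`; the PRS term is named `score`.
#' @export
continuous_prs_effect <- function(prs, covariate_data = NULL,
                                  covariates = c("age", "sex")) {
  df <- tibble::as_tibble(prs)
  rhs <- "score"
  if (!is.null(covariate_data)) {
    cd <- tibble::as_tibble(covariate_data)
    df <- dplyr::left_join(df, cd[, c("sample_id", covariates)], by = "sample_id")
    rhs <- paste(c("score", covariates), collapse = " + ")
    df <- df[stats::complete.cases(df[, c("status", "score", covariates)]), ]
  }
  fit_logistic(df, as.formula(paste("status ~", rhs)))
}

#' Likelihood-ratio interaction test between risk group and an exposure
#'
#' Fits status on group indicators, the binary exposure, covariates, and
#' all group-by-exposure product terms; the reported p-value is the
#' likelihood-ratio test of the product terms jointly. Empty cells in the
#' group-by-exposure cross-table are flagged but the test is still
#' attempted.
#'
#' @param groups A `ps_prs_groups` from [quartile_groups()].
#' @param covariate_data Data frame with `sample_id`, the exposure column
#'   and covariate columns.
#' @param exposure Name of the binary exposure column (default
#'   `ever_drinker`).
#' @param covariates Covariate column names.
#' @return List of class `ps_interaction`: `fit` (full model `ps_logit`),
#'   `lrt_stat`, `df`, `p`, `empty_cells` flag.
#' @export
interaction_test <- function(groups, covariate_data,
                             exposure = "ever_drinker",
                             covariates = c("age", "sex")) {
  cd <- tibble::as_tibble(covariate_data)
  df <- dplyr::left_join(tibble::as_tibble(groups),
                         cd[, c("sample_id", exposure, covariates)],
                         by = "sample_id")
  df <- df[stats::complete.cases(df[, c("status", "group", exposure, covariates)]), ]
  if (length(unique(df[[exposure]])) < 2) {
    abort(paste0("exposure ", exposure, " is constant"))
  }
  df$group <- factor(df$group, levels = sort(unique(df$group)))
  df$.exposure <- df[[exposure]]
  cross <- table(df$group, df$.exposure, df$status)
  empty <- any(cross == 0)
  if (empty) warn("empty cell(s) in group x exposure cross-table; LRT still attempted")
  rhs0 <- paste(c("group", ".exposure", covariates), collapse = " + ")
  full <- fit_logistic(df, as.formula(paste("status ~", rhs0, "+ group:.exposure")))
  base <- fit_logistic(df, as.formula(paste("status ~", rhs0)))
  lrt <- 2 * (full$loglik - base$loglik)
  df_lrt <- nrow(full$coefficients) - nrow(base$coefficients)
  structure(list(fit = full, lrt_stat = lrt, df = df_lrt,
                 p = pchisq(lrt, df_lrt, lower.tail = FALSE),
                 empty_cells = empty),
            class = "ps_interaction")
}

#' @export
print.ps_interaction <- function(x, ...) {
  cat("<ps_interaction> LRT chi2 =", format(x$lrt_stat, digits = 4),
      "df =", x$df, "p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Family-history association with PRS among cases
#'
#' Two complementary views of whether a positive family history tracks the
#' score: (a) a logistic fit of family history on the PRS among cases; (b)
#' a Welch two-sample t comparison of PRS means between family-history
#' positive and negative cases.
#'
#' @param prs A `ps_prs` restricted to (or containing) cases.
#' @param covariate_data Data frame with `sample_id` and `family_history`.
#' @return List of class `ps_family_history`: `fit` (`ps_logit`),
#'   `t_test` (tibble: group means, t, df, p), `n_pos`, `n_neg`.
#' @export
family_history_association <- function(prs, covariate_data) {
  cd <- tibble::as_tibble(covariate_data)
  df <- dplyr::left_join(tibble::as_tibble(prs),
                         cd[, c("sample_id", "family_history")],
                         by = "sample_id")
  df <- df[df$status == 1 & !is.na(df$family_history), ]
  if (length(unique(df$family_history)) < 2) {
    abort("family history has a single class among cases")
  }
  fit <- fit_logistic(df, family_history ~ score)
  tt <- stats::t.test(score ~ family_history, data = df)
  t_test <- tibble::tibble(
    mean_neg = unname(tt$estimate[1]), mean_pos = unname(tt$estimate[2]),
    t = -unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value
  )
  structure(list(fit = fit, t_test = t_test,
                 n_pos = sum(df$family_history == 1),
                 n_neg = sum(df$family_history == 0)),
            class = "ps_family_history")
}

#' @export
print.ps_family_history <- function(x, ...) {
  cat("<ps_family_history> n+ =", x$n_pos, " n- =", x$n_neg, "\n")
  print(x$t_test)
  print(tidy(x$fit))
  invisible(x)
}
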