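#' Table-1-style cohort summary
#'
#' Per-status counts and demographics: n, male count and percent, age
#' mean/sd/min/max, onset age mean/sd/min/max (cases), and positive family
#' history count and percent (cases). Single-observation groups report
#' `NA` standard deviations.
#'
#' @param cohort A `ps_cohort`.
#' @return Tibble with one row per status (`case`, `control`).
#' @export
cohort_summary <- function(cohort) {
  if (nrow(cohort) == 0) abort("empty cohort")
  ph <- phenotypes(cohort)
  ph$label <- ifelse(ph$status == 1, "case", "control")
  dplyr::summarise(
    dplyr::group_by(ph, .data$label),
    n = dplyr::n(),
    n_male = sum(.data$sex == 1, na.rm = TRUE),
    pct_male = 100 * mean(.data$sex == 1, na.rm = TRUE),
    age_mean = mean(.data$age, na.rm = TRUE),
    age_sd = sd(.data$age, na.rm = TRUE),
    age_min = suppressWarnings(min(.data$age, na.rm = TRUE)),
    age_max = suppressWarnings(max(.data$age, na.rm = TRUE)),
    onset_mean = mean(.data$onset_age, na.rm = TRUE),
    onset_sd = sd(.data$onset_age, na.rm = TRUE),
    onset_min = suppressWarnings(min(.data$onset_age, na.rm = TRUE)),
    onset_max = suppressWarnings(max(.data$onset_age, na.rm = TRUE)),
    n_family_history = sum(.data$family_history == 1, na.rm = TRUE),
    pct_family_history = 100 * mean(.data$family_history == 1, na.rm = TRUE),
    .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ ifelse(is.finite(.x) | is.na(.x), .x, NA)))
}

#' Run the full risk-score analysis pipeline
#'
#' Executes, in order: genotype QC; per-SNP allelic association; PRS under
#' the four score models (SNP, HLA, SNP-HLA, and SNP-HLA-Drink when the
#' cohort has drinking data and the panel an environment weight);
#' control-quartile risk grouping with the covariate-adjusted group OR
#' table; the continuous-PRS logistic effect with Nagelkerke pseudo-R2;
#' the group-by-drinking interaction test; per-model ROC/AUC with pairwise
#' DeLong comparisons and the Youden operating point of the full-panel
#' model; and the onset analyses (Cox PH of PRS with age/sex, ANOVA across
#' groups, log-rank and median-gap between extreme groups, family-history
#' association). Stages degrade gracefully: an analysis whose inputs are
#' absent (e.g. no onset ages) is reported as `NULL`. Deterministic given
#' its inputs.
#'
#' @param cohort A `ps_cohort`.
#' @param panel A [weight_panel()].
#' @param sample_cr,snp_cr,hwe_alpha QC thresholds (see [apply_qc()]).
#' @param missing_policy PRS missing-genotype policy (see [compute_prs()]).
#' @return Object of class `ps_report`: a named list of the stage outputs.
#' @export
run_full_analysis <- function(cohort, panel, sample_cr = 0.9, snp_cr = 0.9,
                              hwe_alpha = 1e-3,
                              missing_policy = c("drop", "expected_dosage")) {
  missing_policy <- match.arg(missing_policy)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  report <- list()
  report$summary <- stage("summary", cohort_summary(cohort))
  qc <- stage("qc", apply_qc(cohort, sample_cr, snp_cr, hwe_alpha))
  report$qc <- qc$report
  cohort <- qc$cohort
  report$assoc <- stage("assoc", assoc_table(cohort))

  has_drink <- any(!is.na(cohort$ever_drinker)) &&
    !is.na(environment_weight(panel))
  models <- c("SNP", "HLA", "SNP_HLA", if (has_drink) "SNP_HLA_DRINK")
  prs <- stage("prs", purrr::map(
    setNames(models, models),
    ~ compute_prs(cohort, panel, model = .x, missing_policy = missing_policy)))
  report$prs_summary <- purrr::imap_dfr(prs, function(p, m) tibble::tibble(
    model = m, n = nrow(p),
    mean_case = mean(p$score[p$status == 1]),
    mean_control = mean(p$score[p$status == 0]),
    n_missing_dropped = attr(p, "n_missing_dropped")))

  groups <- stage("risk_groups", quartile_groups(prs$SNP_HLA))
  report$cutpoints <- attr(groups, "cutpoints")
  report$risk_groups <- stage("risk_groups",
                              group_or_table(groups, phenotypes(cohort)))
  report$continuous_prs <- stage("continuous_prs",
    continuous_prs_effect(prs$SNP_HLA, phenotypes(cohort)))
  report$r2_nagelkerke <- nagelkerke_r2(report$continuous_prs)
  report$interaction <- if (has_drink) {
    stage("interaction", interaction_test(groups, phenotypes(cohort)))
  }

  roc_in <- tibble::as_tibble(groups)[, c("sample_id", "status")]
  for (m in models) {
    roc_in[[m]] <- prs[[m]]$score[match(roc_in$sample_id, prs[[m]]$sample_id)]
  }
  roc_in <- roc_in[stats::complete.cases(roc_in), ]
  report$roc <- stage("roc", purrr::map(
    setNames(models, models), ~ roc_auc(roc_in, score = .x)))
  report$auc <- purrr::imap_dfr(report$roc, function(r, m) tibble::tibble(
    model = m, auc = r$auc,
    auc_lo = r$auc - 1.96 * r$se, auc_hi = r$auc + 1.96 * r$se))
  pairs <- utils::combn(models, 2, simplify = FALSE)
  report$delong <- stage("delong", purrr::map_dfr(pairs, function(pr) {
    cmp <- delong_compare(roc_in, pr[2], pr[1])
    tibble::tibble(model_a = pr[2], model_b = pr[1], auc_a = cmp$auc_a,
                   auc_b = cmp$auc_b, z = cmp$z, p = cmp$p)
  }))
  report$operating_point <- stage("operating_point",
                                  sens_spec_at(report$roc$SNP_HLA))

  od <- onset_data(cohort, groups)
  if (nrow(od) >= 10) {
    od$prs <- prs$SNP_HLA$score[match(od$sample_id, prs$SNP_HLA$sample_id)]
    report$onset_cox <- stage("onset_cox", cox_fit(od, ~ prs + age + sex))
    report$onset_anova <- stage("onset_anova", onset_anova(od))
    extremes <- od[od$group %in% c(0, 3), ]
    report$onset_logrank <- stage("onset_logrank", logrank_test(extremes))
    report$median_gap_low_vs_high <- stage("median_gap",
      tryCatch(median_onset_gap(od, group_a = 3, group_b = 0),
               error = function(e) NA_real_))
    if (any(!is.na(od$family_history))) {
      report$family_history <- stage("family_history",
        family_history_association(prs$SNP_HLA, phenotypes(cohort)))
      report$onset_cox_fh <- stage("onset_cox_fh",
        cox_fit(od[!is.na(od$family_history), ], ~ family_history + age + sex))
    }
  }
  structure(report, class = "ps_report")
}

#' Serialise an analysis report to JSON
#'
#' Machine-readable form of [run_full_analysis()] output; identical inputs
#' give an identical JSON string.
#'
#' @param report A `ps_report`.
#' @return A JSON string (class `json`).
#' @export
report_json <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "ps_logit") || inherits(x, "ps_cox")) {
      list(coefficients = x$coefficients, loglik = x$loglik, n = x$n)
    } else if (inherits(x, "ps_roc")) {
      list(auc = x$auc, se = x$se, n_case = x$n_case, n_control = x$n_control)
    } else if (inherits(x, "ps_interaction")) {
      list(lrt_stat = x$lrt_stat, df = x$df, p = x$p)
    } else if (inherits(x, "ps_family_history")) {
      list(t_test = x$t_test, slope = x$fit$coefficients)
    } else if (inherits(x, "ps_qc_report")) {
      list(dropped_samples = x$dropped_samples, dropped_snps = x$dropped_snps,
           thresholds = as.list(x$thresholds))
    } else if (is.list(x) && !is.data.frame(x)) {
      purrr::map(x, simplify)
    } else x
  }
  jsonlite::toJSON(simplify(unclass(report)), digits = NA, auto_unbox = TRUE,
                   na = "null")
}

#' @export
print.ps_report <- function(x, ...) {
  cat("== Cohort ==\n"); print(x$summary)
  cat("\n== QC ==\n"); print(x$qc)
  cat("\n== Single-variant association ==\n"); print(x$assoc)
  cat("\n== PRS models ==\n"); print(x$prs_summary)
  cat("\n== Risk groups (control quartiles",
      paste(format(x$cutpoints, digits = 3), collapse = " / "), ") ==\n")
  print(x$risk_groups)
  cat("\n== Continuous PRS (per-unit log-odds) ==\n")
  print(tidy(x$continuous_prs))
  cat("Nagelkerke R2:", format(x$r2_nagelkerke, digits = 3), "\n")
  if (!is.null(x$interaction)) {
    cat("\n== Group x drinking interaction ==\n"); print(x$interaction)
  }
  cat("\n== Discrimination ==\n"); print(x$auc)
  print(x$delong)
  cat("Operating point (Youden, SNP-HLA):\n"); print(x$operating_point)
  if (!is.null(x$onset_cox)) {
    cat("\n== Onset ==\n")
    print(tidy(x$onset_cox))
    print(x$onset_anova)
    print(x$onset_logrank)
    cat("Median onset gap (group 0 minus group 3):",
        x$median_gap_low_vs_high, "years\n")
  }
  invisible(x)
}
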