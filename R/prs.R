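#' Compute per-sample polygenic risk scores
#'
#' The PRS of a sample is the weighted sum of its risk-allele counts,
#' `sum_i w_i * g_i` with `w_i = ln(OR_i)`, over the variants of the chosen
#' model: `SNP` (non-HLA variants), `HLA` (the HLA locus), `SNP_HLA` (all
#' variants) or `SNP_HLA_DRINK` (all variants plus the environmental
#' ever-drinking term `environment_weight * ever_drinker`). Samples missing
#' any model genotype are dropped under the default policy (mirroring the
#' usual complete-genotype filter); the `expected_dosage` policy instead
#' substitutes twice the control allele frequency for each missing dosage.
#'
#' @param cohort A `ps_cohort`.
#' @param panel A [weight_panel()] covering the cohort's variants.
#' @param model Score model tag.
#' @param missing_policy `"drop"` or `"expected_dosage"`.
#' @param control_freqs Control risk-allele frequencies used by the
#'   `expected_dosage` policy; defaults to frequencies estimated from the
#'   cohort's controls.
#' @return Tibble of class `ps_prs` with `sample_id`, `status`, `score`;
#'   attributes `model` and `n_missing_dropped`.
#' @examples
#' panel <- weight_panel(data.frame(
#'   snp_id = c("s1", "s2"), risk_allele = "A", other_allele = "G",
#'   odds_ratio = c(2, 3), is_hla = c(FALSE, TRUE)))
#' coh <- as_cohort(data.frame(sample_id = "x", status = 1),
#'                  matrix(c(1, 2), 1, dimnames = list(NULL, c("s1", "s2"))))
#' compute_prs(coh, panel, "SNP_HLA")$score  # log(2) + 2*log(3)
#' @export
compute_prs <- function(cohort, panel,
                        model = c("SNP_HLA", "SNP", "HLA", "SNP_HLA_DRINK"),
                        missing_policy = c("drop", "expected_dosage"),
                        control_freqs = NULL) {
  model <- match.arg(model)
  missing_policy <- match.arg(missing_policy)
  sub <- panel_subset(panel, model)
  missing_snps <- setdiff(sub$snp_id, variant_ids(cohort))
  if (length(missing_snps) > 0) {
    abort(paste0("cohort lacks model variant(s): ",
                 paste(missing_snps, collapse = ", ")))
  }
  dm <- dosage_matrix(cohort)[, sub$snp_id, drop = FALSE]

  keep <- rep(TRUE, nrow(dm))
  if (missing_policy == "drop") {
    keep <- stats::complete.cases(dm)
    dm <- dm[keep, , drop = FALSE]
  } else {
    if (is.null(control_freqs)) {
      ctrl <- cohort$status == 0
      if (!any(ctrl)) abort("expected_dosage policy needs controls or control_freqs")
      control_freqs <- colMeans(dm[ctrl, , drop = FALSE], na.rm = TRUE) / 2
    } else {
      if (length(control_freqs) == nrow(panel)) {
        names(control_freqs) <- panel$snp_id
        control_freqs <- control_freqs[sub$snp_id]
      }
      if (length(control_freqs) != ncol(dm)) {
        abort("control_freqs must match the model's variants")
      }
    }
    for (j in seq_len(ncol(dm))) {
      dm[is.na(dm[, j]), j] <- 2 * control_freqs[j]
    }
  }
  score <- as.numeric(dm %*% sub$weight)

  status <- cohort$status[keep]
  ids <- cohort$sample_id[keep]
  if (model == "SNP_HLA_DRINK") {
    ew <- environment_weight(panel)
    if (is.na(ew)) abort("SNP_HLA_DRINK model needs an environment weight in the panel")
    drink <- cohort$ever_drinker[keep]
    if (all(is.na(drink))) abort("SNP_HLA_DRINK model needs ever_drinker data")
    has_drink <- !is.na(drink)
    score <- score[has_drink] + ew * drink[has_drink]
    status <- status[has_drink]
    ids <- ids[has_drink]
    keep[keep] <- has_drink
  }
  structure(
    tibble::tibble(sample_id = ids, status = status, score = score),
    model = model, n_missing_dropped = sum(!keep),
    class = c("ps_prs", class(tibble::tibble())))
}

#' Assign control-quartile risk groups
#'
#' Cutpoints Q1/Q2/Q3 are the 25th/50th/75th percentiles of the scores of
#' healthy controls (linear interpolation between order statistics). Every
#' sample is binned into group 0 (`score <= Q1`), 1 (`Q1 < score <= Q2`),
#' 2 (`Q2 < score <= Q3`) or 3 (`score > Q3`).
#'
#' @param prs A `ps_prs` from [compute_prs()] (or any tibble with
#'   `sample_id`, `status`, `score`).
#' @return The input with a `group` integer column added; attributes
#'   `cutpoints` (named Q1/Q2/Q3).
#' @export
quartile_groups <- function(prs) {
  ctrl_scores <- prs$score[prs$status == 0]
  if (length(ctrl_scores) < 4) abort("need at least 4 controls for quartiles")
  q <- quantile(ctrl_scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (q[1] == q[3]) abort("degenerate control scores: all quartiles equal")
  group <- findInterval(prs$score, q, left.open = TRUE)
  out <- dplyr::mutate(tibble::as_tibble(prs), group = as.integer(group))
  structure(out, cutpoints = setNames(q, c("Q1", "Q2", "Q3")),
            model = attr(prs, "model"),
            class = c("ps_prs_groups", class(tibble::tibble())))
}

#' Risk-group odds-ratio table
#'
#' The Table-2-style summary: per-group case/control counts and the odds
#' ratio of each group versus the reference group 0, from a single logistic
#' regression with group indicator terms (plus optional covariates such as
#' age and sex), with Wald 95% confidence intervals and p-values. With
#' `covariate_data = NULL` the ORs are crude and equal the closed-form 2x2
#' cross-product ratios.
#'
#' @param groups A `ps_prs_groups` from [quartile_groups()].
#' @param covariate_data Optional data frame with `sample_id` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   age and sex).
#' @return Tibble of class `ps_risk_table`: group, cutpoint label, counts,
#'   OR with CI and p (`OR` = 1 for the reference row); attribute `fit`
#'   holds the underlying [fit_logistic()] object, `cutpoints` the
#'   quartiles. Groups with no samples are flagged `undefined`.
#' @export
group_or_table <- function(groups, covariate_data = NULL,
                           covariates = c("age", "sex")) {
  q <- attr(groups, "cutpoints")
  counts <- tidyr::complete(
    dplyr::count(tibble::as_tibble(groups), .data$group, .data$status),
    group = 0:3, status = c(0L, 1L), fill = list(n = 0L))
  counts <- tidyr::pivot_wider(counts, names_from = "status",
                               values_from = "n", names_prefix = "s")
  df <- tibble::as_tibble(groups)
  df$group <- factor(df$group, levels = 0:3)
  rhs <- "group"
  if (!is.null(covariate_data)) {
    cd <- tibble::as_tibble(covariate_data)
    df <- dplyr::left_join(df, cd[, c("sample_id", covariates)], by = "sample_id")
    rhs <- paste(c("group", covariates), collapse = " + ")
  }
  df <- df[, c("status", "group",
               if (!is.null(covariate_data)) covariates), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$group <- droplevels(df$group)
  fit <- fit_logistic(df, as.formula(paste("status ~", rhs)))
  est <- tidy(fit)
  lab <- c(sprintf("<= %.3g", q[1]),
           sprintf("%.3g-%.3g", q[1], q[2]),
           sprintf("%.3g-%.3g", q[2], q[3]),
           sprintf("> %.3g", q[3]))
  out <- tibble::tibble(
    group = 0:3, prs_range = lab,
    n_case = counts$s1[match(0:3, counts$group)],
    n_control = counts$s0[match(0:3, counts$group)],
    or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
    undefined = FALSE
  )
  out$or[1] <- 1
  for (g in 1:3) {
    term <- paste0("group", g)
    row <- est[est$term == term, ]
    if (nrow(row) == 1) {
      out$or[g + 1] <- exp(row$estimate)
      out$ci_lo[g + 1] <- exp(row$estimate - 1.96 * row$std.error)
      out$ci_hi[g + 1] <- exp(row$estimate + 1.96 * row$std.error)
      out$p[g + 1] <- row$p.value
    } else {
      out$undefined[g + 1] <- TRUE
    }
  }
  structure(out, fit = fit, cutpoints = q,
            class = c("ps_risk_table", class(tibble::tibble())))
}
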