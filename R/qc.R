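#' Hardy-Weinberg exact test p-value
#'
#' Exact conditional test for one biallelic SNP: given the observed allele
#' counts, the p-value is the sum of the conditional probabilities of every
#' heterozygote count (same parity, allele counts fixed) whose probability
#' does not exceed that of the observed count. This is the standard "no
#' more probable" two-sided definition, not the mid-p variant.
#'
#' @param n_rr Count of risk-allele homozygotes.
#' @param n_rh Count of heterozygotes.
#' @param n_oo Count of other-allele homozygotes.
#' @return The exact p-value in `[0, 1]`.
#' @examples
#' hwe_exact_p(3, 4, 3)
#' @export
hwe_exact_p <- function(n_rr, n_rh, n_oo) {
  if (any(c(n_rr, n_rh, n_oo) < 0)) abort("genotype counts must be nonnegative")
  n <- n_rr + n_rh + n_oo
  if (n == 0) abort("all genotype counts are zero")
  na <- 2 * n_rr + n_rh       # risk-allele count; parity fixes attainable hets
  nb <- 2 * n - na
  hets <- seq(na %% 2, min(na, nb), by = 2)
  # log conditional probability of each heterozygote count given allele counts
  logp <- vapply(hets, function(h) {
    rr <- (na - h) / 2
    oo <- (nb - h) / 2
    lgamma(n + 1) - lgamma(rr + 1) - lgamma(h + 1) - lgamma(oo + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_rh, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Allelic chi-square association test for one SNP
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' allele counts, with the allelic odds ratio and Woolf 95% confidence
#' interval `exp(ln OR +/- 1.96 * sqrt(sum of reciprocal cells))`. When any
#' cell is zero the OR and CI use the Haldane-Anscombe 0.5 correction and
#' the result is flagged.
#'
#' @param case_risk,case_other Risk/other allele counts in cases.
#' @param ctrl_risk,ctrl_other Risk/other allele counts in controls.
#' @param snp_id Optional variant label carried into the result.
#' @return One-row tibble: counts, `or`, `ci_lo`, `ci_hi`, `chi2`, `p`,
#'   `haldane` flag.
#' @examples
#' allelic_chi2(30, 70, 20, 80)
#' @export
allelic_chi2 <- function(case_risk, case_other, ctrl_risk, ctrl_other,
                         snp_id = NA_character_) {
  cells <- c(case_risk, case_other, ctrl_risk, ctrl_other)
  if (any(cells < 0)) abort("allele counts must be nonnegative")
  n <- sum(cells)
  r1 <- case_risk + case_other
  r2 <- ctrl_risk + ctrl_other
  c1 <- case_risk + ctrl_risk
  c2 <- case_other + ctrl_other
  if (any(c(r1, r2, c1, c2) == 0)) abort("every table margin must be positive")
  chi2 <- n * (case_risk * ctrl_other - case_other * ctrl_risk)^2 /
    (r1 * r2 * c1 * c2)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  haldane <- any(cells == 0)
  cc <- if (haldane) cells + 0.5 else cells
  lor <- log(cc[1] * cc[4] / (cc[2] * cc[3]))
  se <- sqrt(sum(1 / cc))
  tibble::tibble(
    snp_id = snp_id,
    case_risk = case_risk, case_other = case_other,
    ctrl_risk = ctrl_risk, ctrl_other = ctrl_other,
    or = exp(lor), ci_lo = exp(lor - 1.96 * se), ci_hi = exp(lor + 1.96 * se),
    chi2 = chi2, p = p, haldane = haldane
  )
}

count_alleles <- function(dm, status) {
  case <- status == 1
  risk_case <- colSums(dm[case, , drop = FALSE], na.rm = TRUE)
  n_case <- colSums(!is.na(dm[case, , drop = FALSE]))
  risk_ctrl <- colSums(dm[!case, , drop = FALSE], na.rm = TRUE)
  n_ctrl <- colSums(!is.na(dm[!case, , drop = FALSE]))
  tibble::tibble(
    snp_id = colnames(dm),
    case_risk = risk_case, case_other = 2 * n_case - risk_case,
    ctrl_risk = risk_ctrl, ctrl_other = 2 * n_ctrl - risk_ctrl
  )
}

#' Per-SNP allelic association table for a cohort
#'
#' Runs [allelic_chi2()] on every variant of a cohort.
#'
#' @param cohort A `ps_cohort` with case and control samples.
#' @return Tibble with one row per variant: allele counts, OR, Woolf 95% CI,
#'   chi-square statistic and p-value.
#' @export
assoc_table <- function(cohort) {
  counts <- count_alleles(dosage_matrix(cohort), cohort$status)
  purrr::pmap_dfr(counts, function(snp_id, case_risk, case_other,
                                   ctrl_risk, ctrl_other) {
    allelic_chi2(case_risk, case_other, ctrl_risk, ctrl_other, snp_id = snp_id)
  })
}

#' Power of the allelic chi-square test
#'
#' Analytic power of the 1-df allelic test, using the noncentral chi-square
#' approximation: the case allele frequency implied by `(freq_ctrl, or)`
#' under retrospective sampling gives the allele-frequency difference, and
#' the noncentrality parameter is that difference squared over the pooled
#' binomial variance of the difference at the design's allele counts.
#'
#' @param freq_ctrl Control risk-allele frequency.
#' @param or True per-allele odds ratio.
#' @param n_case,n_ctrl Numbers of cases and controls (individuals; each
#'   contributes two alleles).
#' @param alpha Significance level.
#' @return Power in `[0, 1]`.
#' @examples
#' allelic_test_power(0.2, 1.3, 712, 723, 0.05)
#' @export
allelic_test_power <- function(freq_ctrl, or, n_case, n_ctrl, alpha = 0.05) {
  if (freq_ctrl <= 0 || freq_ctrl >= 1) abort("freq_ctrl must be in (0,1)")
  if (or <= 0) abort("or must be positive")
  p1 <- case_allele_freq(freq_ctrl, or)
  p0 <- freq_ctrl
  m1 <- 2 * n_case
  m0 <- 2 * n_ctrl
  pbar <- (m1 * p1 + m0 * p0) / (m1 + m0)
  ncp <- (p1 - p0)^2 / (pbar * (1 - pbar) * (1 / m1 + 1 / m0))
  crit <- qchisq(1 - alpha, df = 1)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Apply genotype quality control to a cohort
#'
#' Filters in the fixed order: (1) samples with genotype call rate at or
#' below `sample_cr`; (2) SNPs with call rate at or below `snp_cr` among
#' the surviving samples; (3) SNPs whose Hardy-Weinberg exact p-value among
#' surviving controls is at or below `hwe_alpha`. Defaults are call rates
#' > 90% and HWE p > 1e-3 in controls. Every dropped sample or SNP is
#' recorded in the report with its single triggering reason.
#'
#' @param cohort A `ps_cohort` with at least one control.
#' @param sample_cr,snp_cr Minimum (exclusive) call-rate fractions.
#' @param hwe_alpha Minimum (exclusive) HWE p-value in controls.
#' @return List with `cohort` (filtered) and `report` (class `ps_qc_report`:
#'   tibbles `dropped_samples`, `dropped_snps`, plus the thresholds).
#' @export
apply_qc <- function(cohort, sample_cr = 0.9, snp_cr = 0.9, hwe_alpha = 1e-3) {
  if (!any(cohort$status == 0)) abort("QC needs at least one control (HWE filter)")
  dm <- dosage_matrix(cohort)

  s_cr <- rowMeans(!is.na(dm))
  drop_s <- s_cr <= sample_cr
  dropped_samples <- tibble::tibble(
    sample_id = cohort$sample_id[drop_s],
    reason = "sample_call_rate",
    value = s_cr[drop_s]
  )
  if (all(drop_s)) abort("QC removed every sample (empty cohort)")
  cohort <- keep_samples(cohort, !drop_s)
  dm <- dm[!drop_s, , drop = FALSE]

  v_cr <- colMeans(!is.na(dm))
  drop_v <- v_cr <= snp_cr
  dropped_snps <- tibble::tibble(
    snp_id = colnames(dm)[drop_v],
    reason = "snp_call_rate",
    value = v_cr[drop_v]
  )
  dm2 <- dm[, !drop_v, drop = FALSE]

  ctrl <- cohort$status == 0
  hwe_p <- vapply(seq_len(ncol(dm2)), function(j) {
    g <- dm2[ctrl, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_p(sum(g == 2), sum(g == 1), sum(g == 0))
  }, numeric(1))
  drop_h <- !is.na(hwe_p) & hwe_p <= hwe_alpha
  dropped_snps <- dplyr::bind_rows(dropped_snps, tibble::tibble(
    snp_id = colnames(dm2)[drop_h],
    reason = "hwe_controls",
    value = hwe_p[drop_h]
  ))
  cohort <- drop_variants(cohort, dropped_snps$snp_id)

  report <- structure(
    list(dropped_samples = dropped_samples, dropped_snps = dropped_snps,
         thresholds = c(sample_cr = sample_cr, snp_cr = snp_cr,
                        hwe_alpha = hwe_alpha)),
    class = "ps_qc_report")
  list(cohort = cohort, report = report)
}

#' @export
print.ps_qc_report <- function(x, ...) {
  cat("<ps_qc_report> thresholds: sample call rate >", x$thresholds["sample_cr"],
      "| SNP call rate >", x$thresholds["snp_cr"],
      "| HWE p >", x$thresholds["hwe_alpha"], "\n")
  cat("dropped samples:", nrow(x$dropped_samples),
      "| dropped SNPs:", nrow(x$dropped_snps), "\n")
  if (nrow(x$dropped_samples)) print(x$dropped_samples)
  if (nrow(x$dropped_snps)) print(x$dropped_snps)
  invisible(x)
}
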