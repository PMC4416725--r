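#' A synthetic 14-variant psoriasis-like weight panel
#'
#' The published panel behind the motivating study lives in a supplementary
#' table that names only two of its variants in the main text (rs1265181 in
#' the MHC and rs7007032), so the package ships this synthetic stand-in: 14
#' biallelic SNPs, one large-effect HLA-like locus (OR 8, the magnitude the
#' MHC locus carries in Han Chinese psoriasis cohorts) and 13 small-effect
#' loci with odds ratios between 1.1 and 1.6, plus an ever-drinking exposure
#' OR of 2.49 from the meta-analytic estimate the study used. All values
#' other than the two rs ids are synthetic placeholders, not published
#' estimates.
#'
#' @return A [weight_panel()] of 14 variants with an environment weight.
#' @export
synthetic_panel <- function() {
  alle <- c("A", "C", "G", "T")
  ids <- c("rs1265181", "rs7007032", sprintf("rsSIM%02d", 3:14))
  ors <- c(8.00, 1.32, 1.58, 1.49, 1.43, 1.38, 1.35, 1.30,
           1.27, 1.24, 1.21, 1.18, 1.14, 1.11)
  weight_panel(tibble::tibble(
    snp_id = ids,
    risk_allele = alle[1 + (seq_along(ids) %% 4)],
    other_allele = alle[1 + ((seq_along(ids) + 1) %% 4)],
    odds_ratio = ors,
    is_hla = c(TRUE, rep(FALSE, 13))
  ), environment_or = 2.49)
}

default_control_freqs <- function(n_snps = 14, hla_index = 1) {
  f <- seq(0.12, 0.48, length.out = n_snps)
  f[hla_index] <- 0.15
  f
}

#' Simulation configuration for a synthetic case-control cohort
#'
#' Collects every parameter of the generator. The defaults reproduce the
#' statistical structure of the motivating psoriasis study's initial stage:
#' 3621 cases / 3350 controls; 14 independent biallelic SNPs in
#' Hardy-Weinberg equilibrium among controls with one OR ~ 8 HLA-like locus
#' and 13 small additive effects; an ever-drinking exposure with OR 2.49;
#' age ~ 30 +/- 11.5 years truncated to 3-81 with ~58% males; an onset
#' hazard ratio of 1.08 per PRS unit on an exponential baseline scaled so
#' the median onset is near 21 years; and a positive-family-history rate
#' near 31% among cases, increasing with PRS.
#'
#' @param panel A [weight_panel()]; its odds ratios are the true per-allele
#'   effects unless `snp_ors` overrides them.
#' @param n_cases,n_controls Sample sizes.
#' @param control_freqs Per-SNP risk-allele frequency among controls.
#' @param snp_ors Per-SNP true additive per-allele odds ratio.
#' @param hla_index Index of the large-effect locus (defaults to the
#'   panel's HLA flag).
#' @param drink_or Odds ratio of ever-drinking for case status.
#' @param drink_prevalence_controls Ever-drinking probability in controls.
#' @param onset_hr_per_prs_unit Hazard ratio on onset age per PRS unit.
#' @param baseline_onset_scale Exponential baseline scale (years) of the
#'   onset model at PRS = 0.
#' @param family_history_slope Log-odds of positive family history per PRS
#'   unit, among cases.
#' @param family_history_rate Target marginal family-history rate among
#'   cases (fixes the intercept at the mean case PRS).
#' @param age_mean,age_sd Age distribution (years), truncated to 3-81.
#' @param male_fraction Probability of male sex.
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Integer seed governing all randomness.
#' @return A list of class `ps_sim_config`.
#' @export
sim_config <- function(panel = synthetic_panel(),
                       n_cases = 3621, n_controls = 3350,
                       control_freqs = default_control_freqs(
                         nrow(panel), which(panel$is_hla)[1]),
                       snp_ors = panel$odds_ratio,
                       hla_index = which(panel$is_hla)[1],
                       drink_or = 2.49,
                       drink_prevalence_controls = 0.25,
                       onset_hr_per_prs_unit = 1.08,
                       baseline_onset_scale = 43,
                       family_history_slope = 0.35,
                       family_history_rate = 0.3134,
                       age_mean = 30, age_sd = 11.5,
                       male_fraction = 0.58,
                       missing_rate = 0.004,
                       seed = 1L) {
  cfg <- list(panel = panel, n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              control_freqs = as.numeric(control_freqs),
              snp_ors = as.numeric(snp_ors),
              hla_index = as.integer(hla_index),
              drink_or = drink_or,
              drink_prevalence_controls = drink_prevalence_controls,
              onset_hr_per_prs_unit = onset_hr_per_prs_unit,
              baseline_onset_scale = baseline_onset_scale,
              family_history_slope = family_history_slope,
              family_history_rate = family_history_rate,
              age_mean = age_mean, age_sd = age_sd,
              male_fraction = male_fraction,
              missing_rate = missing_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "ps_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cases < 1 || cfg$n_controls < 1) {
    abort("n_cases and n_controls must each be >= 1")
  }
  k <- nrow(cfg$panel)
  if (length(cfg$control_freqs) != k || length(cfg$snp_ors) != k) {
    abort("control_freqs and snp_ors must have one entry per panel variant")
  }
  if (any(cfg$control_freqs <= 0 | cfg$control_freqs >= 1)) {
    abort("control_freqs must lie strictly in (0, 1)")
  }
  probs <- c(cfg$drink_prevalence_controls, cfg$male_fraction,
             cfg$family_history_rate)
  if (any(probs <= 0 | probs >= 1)) {
    abort("probabilities must lie strictly in (0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  ors <- c(cfg$snp_ors, cfg$drink_or, cfg$onset_hr_per_prs_unit)
  if (any(!is.finite(ors)) || any(ors <= 0)) {
    abort("every odds/hazard ratio must be a finite positive number")
  }
  if (cfg$baseline_onset_scale <= 0 || cfg$age_sd <= 0) {
    abort("baseline_onset_scale and age_sd must be positive")
  }
  if (cfg$hla_index < 1 || cfg$hla_index > k) abort("hla_index out of range")
  invisible(cfg)
}

# genotype distribution for one SNP: HWE in controls; cases tilted by OR^g
# (retrospective sampling under the additive logistic model)
genotype_probs <- function(freq, or = 1) {
  p0 <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  p1 <- p0 * or^(0:2)
  list(control = p0, case = p1 / sum(p1))
}

#' Expected case risk-allele frequency under retrospective sampling
#'
#' For a SNP with control frequency `p` and per-allele odds ratio `OR`, the
#' case allele frequency implied by the additive logistic disease model is
#' `p * OR / (1 - p + p * OR)`.
#'
#' @param freq_ctrl Control risk-allele frequency.
#' @param or Per-allele odds ratio.
#' @return Case risk-allele frequency.
#' @export
case_allele_freq <- function(freq_ctrl, or) {
  freq_ctrl * or / (1 - freq_ctrl + freq_ctrl * or)
}

#' Simulate genotypes for a case-control cohort
#'
#' Controls are drawn per SNP from Hardy-Weinberg genotype frequencies at
#' the configured control allele frequencies. Cases are drawn from the
#' genotype distribution implied by retrospective sampling under the
#' additive logistic model, `P(g | case) \%\propto\% P(g | control) * OR^g`
#' renormalised over g in \{0, 1, 2\}. SNPs are independent (linkage
#' equilibrium). Uniform missingness is applied at `missing_rate`.
#'
#' Controls come first (rows `ctrl_...`), then cases (`case_...`). The
#' random stream order is: per SNP control genotypes, per SNP case
#' genotypes, then the missingness mask. `set.seed(config$seed)` is applied
#' here unless `use_seed = FALSE` (as when called inside a larger
#' simulation that already seeded the stream).
#'
#' @param config A [sim_config()].
#' @param use_seed Seed the RNG from `config$seed` first?
#' @return A `ps_cohort` with dosages and `status` set.
#' @export
simulate_genotypes <- function(config, use_seed = TRUE) {
  validate_sim_config(config)
  if (use_seed) set.seed(config$seed)
  n0 <- config$n_controls
  n1 <- config$n_cases
  k <- length(config$control_freqs)
  dos <- matrix(NA_real_, n0 + n1, k,
                dimnames = list(NULL, config$panel$snp_id))
  for (j in seq_len(k)) {
    pr <- genotype_probs(config$control_freqs[j], config$snp_ors[j])
    dos[seq_len(n0), j] <- sample(0:2, n0, replace = TRUE, prob = pr$control)
  }
  for (j in seq_len(k)) {
    pr <- genotype_probs(config$control_freqs[j], config$snp_ors[j])
    dos[n0 + seq_len(n1), j] <- sample(0:2, n1, replace = TRUE, prob = pr$case)
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(dos)) < config$missing_rate, nrow(dos))
    dos[miss] <- NA_real_
  }
  as_cohort(
    tibble::tibble(
      sample_id = c(sprintf("ctrl_%05d", seq_len(n0)),
                    sprintf("case_%05d", seq_len(n1))),
      status = rep(c(0L, 1L), c(n0, n1))
    ),
    dos
  )
}

#' Simulate phenotypes on top of simulated genotypes
#'
#' Fills in sex, ever-drinking (control prevalence as configured; case
#' prevalence tilted by the drink odds ratio), positive family history
#' among cases (logistic in the full-panel PRS, intercept calibrated to
#' the target marginal rate), and age of onset among cases from an
#' exponential proportional-hazards model with rate
#' `onset_hr_per_prs_unit^PRS / baseline_onset_scale`, floored at 1 year.
#' Controls draw their age from a truncated normal on 3-81 years; cases
#' are ascertained after onset, so a case's age is its onset age plus an
#' exponential recruitment delay (mean 9 years, matching the typical gap
#' between onset and enrolment), capped at 81. This keeps the marginal
#' hazard structure of onset intact while preserving `onset_age <= age`.
#' The PRS driving family history and onset is the full-panel (SNP-HLA)
#' score with expected-dosage fill-in for missing genotypes.
#'
#' Random stream order: age, sex, ever-drinking, family history, onset,
#' recruitment delay.
#'
#' @param cohort A `ps_cohort` from [simulate_genotypes()].
#' @param panel The [weight_panel()] used for scoring (defaults to the
#'   config's panel).
#' @param config The [sim_config()].
#' @return The cohort with all phenotype columns populated.
#' @export
simulate_phenotypes <- function(cohort, panel = config$panel, config) {
  validate_sim_config(config)
  if (!identical(variant_ids(cohort), panel$snp_id)) {
    abort("cohort variants do not match the weight panel")
  }
  n <- nrow(cohort)
  case <- cohort$status == 1
  prs <- compute_prs(cohort, panel, model = "SNP_HLA",
                     missing_policy = "expected_dosage",
                     control_freqs = config$control_freqs)$score

  lo <- pnorm(3, config$age_mean, config$age_sd)
  hi <- pnorm(81, config$age_mean, config$age_sd)
  age <- round(qnorm(runif(n, lo, hi), config$age_mean, config$age_sd), 1)
  sex <- as.integer(runif(n) < config$male_fraction)

  p0 <- config$drink_prevalence_controls
  p1 <- p0 * config$drink_or / (1 - p0 + p0 * config$drink_or)
  drink <- as.integer(runif(n) < ifelse(case, p1, p0))

  fh <- rep(NA_integer_, n)
  icept <- qlogis(config$family_history_rate) -
    config$family_history_slope * mean(prs[case])
  fh[case] <- as.integer(
    runif(sum(case)) < plogis(icept + config$family_history_slope * prs[case]))

  onset <- rep(NA_real_, n)
  lambda <- config$onset_hr_per_prs_unit^prs[case] / config$baseline_onset_scale
  onset[case] <- round(-log(1 - runif(sum(case))) / lambda, 1)
  onset[case] <- pmin(pmax(onset[case], 1), 80)
  delay <- -log(1 - runif(sum(case))) * 9
  age[case] <- pmin(round(onset[case] + delay, 1), 81)

  tbl <- tibble::as_tibble(cohort)
  tbl$age <- age
  tbl$sex <- sex
  tbl$ever_drinker <- drink
  tbl$family_history <- fh
  tbl$onset_age <- onset
  new_cohort(tbl, variant_ids(cohort))
}

#' Simulate a complete synthetic cohort
#'
#' Seeds the RNG from `config$seed`, draws genotypes, then phenotypes.
#'
#' @param config A [sim_config()].
#' @return A fully populated `ps_cohort`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  cohort <- simulate_genotypes(config, use_seed = FALSE)
  simulate_phenotypes(cohort, config$panel, config)
}

#' Write a reproducible synthetic fixture bundle
#'
#' Simulates a cohort and writes `genotypes.ped` / `genotypes.map`,
#' `weights.tsv` and `phenotypes.tsv` to a directory. The same config (and
#' seed) always produces byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  cohort <- simulate_cohort(config)
  paths <- c(ped = file.path(out_dir, "genotypes.ped"),
             map = file.path(out_dir, "genotypes.map"),
             weights = file.path(out_dir, "weights.tsv"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"))
  write_ped_map(cohort, config$panel, paths["ped"], paths["map"])
  write_weights(config$panel, paths["weights"])
  write_phenotypes(cohort, paths["phenotypes"])
  invisible(paths)
}
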