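test_that("PRS is the weighted dosage sum over the model's variants", {
  panel <- tiny_panel(environment_or = 2.49)
  dos <- matrix(c(1, 2,
                  0, 0,
                  2, 1), 3, 2, byrow = TRUE,
                dimnames = list(NULL, c("snpA", "snpB")))
  coh <- tiny_cohort(dos, c(1L, 0L, 1L), ever_drinker = c(1L, 1L, 0L))
  prs <- compute_prs(coh, panel, "SNP_HLA")
  expect_equal(prs$score[1], log(2) + 2 * log(3), tolerance = 1e-12)
  expect_equal(prs$score[1], 2.8904, tolerance = 1e-4)
  expect_equal(prs$score[2], 0)

  # the panel partition: SNP + HLA = SNP_HLA for every sample
  s_snp <- compute_prs(coh, panel, "SNP")$score
  s_hla <- compute_prs(coh, panel, "HLA")$score
  s_all <- compute_prs(coh, panel, "SNP_HLA")$score
  expect_equal(s_snp + s_hla, s_all, tolerance = 1e-12)

  # drink model adds the environment weight for drinkers only
  s_drink <- compute_prs(coh, panel, "SNP_HLA_DRINK")$score
  expect_equal(s_drink, s_all + log(2.49) * c(1, 1, 0), tolerance = 1e-12)
  # all-zero dosages + drinker -> environment weight alone
  expect_equal(s_drink[2], log(2.49), tolerance = 1e-12)
})

test_that("an OR = 1 variant never changes a score", {
  panel3 <- weight_panel(data.frame(
    snp_id = c("snpA", "snpB", "snpC"),
    risk_allele = c("C", "G", "A"), other_allele = c("T", "A", "G"),
    odds_ratio = c(2, 3, 1), is_hla = c(FALSE, TRUE, FALSE)))
  set.seed(8)
  dos <- matrix(rbinom(60, 2, 0.5), 20, 3,
                dimnames = list(NULL, c("snpA", "snpB", "snpC")))
  coh <- tiny_cohort(dos, rep(c(0L, 1L), 10))
  with3 <- compute_prs(coh, panel3, "SNP_HLA")$score
  without <- as.numeric(dos[, 1:2] %*% log(c(2, 3)))
  expect_equal(with3, without, tolerance = 1e-12)
})

test_that("missing-genotype policies drop or impute as documented", {
  panel <- tiny_panel()
  dos <- matrix(c(1, NA,
                  2, 1,
                  0, 2,
                  1, 0), 4, 2, byrow = TRUE,
                dimnames = list(NULL, c("snpA", "snpB")))
  coh <- tiny_cohort(dos, c(1L, 0L, 0L, 1L))
  dropped <- compute_prs(coh, panel, "SNP_HLA", missing_policy = "drop")
  expect_equal(nrow(dropped), 3)
  expect_equal(attr(dropped, "n_missing_dropped"), 1)
  expect_false("s01" %in% dropped$sample_id)

  imputed <- compute_prs(coh, panel, "SNP_HLA",
                         missing_policy = "expected_dosage",
                         control_freqs = c(0.4, 0.25))
  expect_equal(nrow(imputed), 4)
  expect_equal(imputed$score[1], 1 * log(2) + 2 * 0.25 * log(3),
               tolerance = 1e-12)
})

test_that("control quartiles follow the interpolated percentile definition", {
  prs <- structure(
    tibble::tibble(sample_id = as.character(1:10),
                   status = c(rep(0L, 8), 1L, 1L),
                   score = c(1:8, 2.75, 2.76)),
    class = c("ps_prs", class(tibble::tibble())))
  g <- quartile_groups(prs)
  q <- attr(g, "cutpoints")
  expect_equal(unname(q), c(2.75, 4.5, 6.25))
  expect_equal(g$group[g$score == 2.75 & g$status == 1], 0L)  # boundary in
  expect_equal(g$group[g$score == 2.76], 1L)                  # just above
  # controls split 25/25/25/25 without cutpoint ties
  expect_equal(as.integer(table(g$group[g$status == 0])), rep(2L, 4))
})

test_that("degenerate control scores are rejected", {
  prs <- structure(
    tibble::tibble(sample_id = as.character(1:6),
                   status = c(0L, 0L, 0L, 0L, 1L, 1L),
                   score = c(2, 2, 2, 2, 1, 3)),
    class = c("ps_prs", class(tibble::tibble())))
  expect_error(quartile_groups(prs), "degenerate")
})

test_that("logistic fit matches the closed-form 2x2 log-OR and Woolf SE", {
  set.seed(31)
  for (i in 1:200) {
    a <- sample(5:60, 4)  # exposed-case, unexposed-case, exposed-ctrl, unexposed-ctrl
    d <- data.frame(
      y = rep(c(1, 1, 0, 0), a),
      x = rep(c(1, 0, 1, 0), a))
    fit <- fit_logistic(d, y ~ x)
    est <- tidy(fit)
    lor <- log(a[1] * a[4] / (a[2] * a[3]))
    se <- sqrt(sum(1 / a))
    expect_equal(est$estimate[est$term == "x"], lor, tolerance = 1e-6)
    expect_equal(est$std.error[est$term == "x"], se, tolerance = 1e-6)
  }
})

test_that("logistic fit flags singular designs and separation", {
  d <- data.frame(y = rep(c(0, 1), 20), x = rnorm(40))
  d$x2 <- d$x
  expect_error(fit_logistic(d, y ~ x + x2), "singular")
  sep <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  expect_error(fit_logistic(sep, y ~ x), "separation")
  expect_error(fit_logistic(data.frame(y = rep(1, 10), x = rnorm(10)), y ~ x),
               "constant")
})

test_that("null predictors give uniform Wald p-values", {
  set.seed(77)
  pvals <- replicate(300, {
    d <- data.frame(y = rbinom(200, 1, 0.5), x = rnorm(200))
    tidy(fit_logistic(d, y ~ x))$p.value[2]
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})

test_that("group OR table reproduces closed-form crude ORs and counts", {
  set.seed(12)
  n <- 400
  score <- rnorm(n)
  status <- rbinom(n, 1, plogis(-0.5 + score))
  prs <- structure(
    tibble::tibble(sample_id = as.character(1:n), status = as.integer(status),
                   score = score),
    class = c("ps_prs", class(tibble::tibble())))
  g <- quartile_groups(prs)
  tab <- group_or_table(g)
  cnt <- table(g$group, g$status)
  for (k in 2:4) {
    crude <- (cnt[k, "1"] * cnt[1, "0"]) / (cnt[k, "0"] * cnt[1, "1"])
    expect_equal(tab$or[k], unname(crude), tolerance = 1e-6)
    expect_equal(tab$n_case[k], unname(cnt[k, "1"]))
    expect_equal(tab$n_control[k], unname(cnt[k, "0"]))
  }
  expect_equal(tab$or[1], 1)
})

test_that("group ORs rise monotonically under a paper-like simulation", {
  ok <- 0L
  for (seed in 1:5) {
    cfg <- small_config(seed, n_cases = 900, n_controls = 900)
    coh <- simulate_cohort(cfg)
    prs <- compute_prs(coh, cfg$panel, "SNP_HLA",
                       missing_policy = "expected_dosage")
    tab <- group_or_table(quartile_groups(prs), phenotypes(coh))
    if (!any(tab$undefined) && all(diff(tab$or) > 0)) ok <- ok + 1L
    # the strong HLA-like locus concentrates cases in the top quartile
    expect_gt(tab$n_case[4] / sum(tab$n_case), 0.5)
  }
  expect_gte(ok, 4L)
})

test_that("null simulations leave all group OR CIs covering 1", {
  cfg <- small_config(21, n_cases = 800, n_controls = 800,
                      snp_ors = rep(1, 14), missing_rate = 0)
  coh <- simulate_cohort(cfg)
  prs <- compute_prs(coh, cfg$panel, "SNP_HLA")
  tab <- group_or_table(quartile_groups(prs), phenotypes(coh))
  expect_true(all(tab$ci_lo[2:4] < 1 & tab$ci_hi[2:4] > 1))
})

test_that("continuous PRS effect is affine-invariant and recoverable", {
  cfg <- small_config(13, n_cases = 600, n_controls = 600)
  coh <- simulate_cohort(cfg)
  prs <- compute_prs(coh, cfg$panel, "SNP_HLA", missing_policy = "expected_dosage")
  fit <- continuous_prs_effect(prs, phenotypes(coh))
  shifted <- prs
  shifted$score <- shifted$score + 5
  fit2 <- continuous_prs_effect(shifted, phenotypes(coh))
  est1 <- tidy(fit)
  est2 <- tidy(fit2)
  expect_equal(est1$estimate[est1$term == "score"],
               est2$estimate[est2$term == "score"], tolerance = 1e-6)
  expect_equal(est2$estimate[est2$term == "(Intercept)"],
               est1$estimate[est1$term == "(Intercept)"] -
                 5 * est1$estimate[est1$term == "score"], tolerance = 1e-5)
})

test_that("a true per-unit log-odds of 1 is recovered at n = 7000", {
  set.seed(55)
  n <- 7000
  x <- rnorm(n, 0, 1)
  y <- rbinom(n, 1, plogis(-0.5 + 1.0 * x))
  d <- data.frame(sample_id = as.character(1:n), status = y, score = x)
  prs <- structure(tibble::as_tibble(d),
                   class = c("ps_prs", class(tibble::tibble())))
  fit <- continuous_prs_effect(prs)
  est <- tidy(fit)
  expect_lt(abs(est$estimate[est$term == "score"] - 1.0), 0.15)
})

test_that("Nagelkerke R2 matches direct formula evaluation", {
  d <- data.frame(y = rep(c(1, 1, 0, 0), c(8, 2, 2, 8)),
                  x = rep(c(1, 0, 1, 0), c(8, 2, 2, 8)))
  fit <- fit_logistic(d, y ~ x)
  n <- 20
  ll1 <- fit$loglik; ll0 <- fit$null_loglik
  direct <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(nagelkerke_r2(fit), direct, tolerance = 1e-12)
  expect_gt(nagelkerke_r2(fit), 0)
  # exactly balanced 2x2 (OR = 1): R2 = 0
  dnull <- data.frame(y = rep(c(0, 1, 0, 1), each = 12),
                      x = rep(c(0, 0, 1, 1), each = 12))
  fit0 <- fit_logistic(dnull, y ~ x)
  expect_equal(nagelkerke_r2(fit0), 0, tolerance = 1e-8)
})

test_that("interaction LRT detects a product effect and stays calibrated", {
  # power: strong group x exposure product term
  make_sim <- function(seed, gamma) {
    set.seed(seed)
    n <- 3000
    group <- sample(0:3, n, replace = TRUE)
    expo <- rbinom(n, 1, 0.4)
    age <- rnorm(n, 30, 10); sex <- rbinom(n, 1, 0.5)
    eta <- -1 + 0.3 * group + 0.4 * expo + gamma * (group == 3) * expo
    y <- rbinom(n, 1, plogis(eta))
    prs <- structure(
      tibble::tibble(sample_id = as.character(1:n), status = y,
                     score = rnorm(n), group = as.integer(group)),
      cutpoints = c(Q1 = -1, Q2 = 0, Q3 = 1),
      class = c("ps_prs_groups", class(tibble::tibble())))
    cd <- tibble::tibble(sample_id = as.character(1:n), ever_drinker = expo,
                         age = age, sex = sex)
    suppressWarnings(interaction_test(prs, cd))
  }
  hits <- sum(vapply(1:10, function(s) make_sim(s, 1.0)$p < 0.05, logical(1)))
  expect_gte(hits, 9L)
  nulls <- vapply(11:30, function(s) make_sim(s, 0)$p, numeric(1))
  expect_gt(min(nulls), 0.001)
  expect_lt(mean(nulls < 0.25), 0.6)  # roughly uniform under the null

  # constant exposure is rejected
  cfg <- small_config(3, n_cases = 100, n_controls = 100)
  coh <- simulate_cohort(cfg)
  prs <- compute_prs(coh, cfg$panel, "SNP_HLA", missing_policy = "expected_dosage")
  g <- quartile_groups(prs)
  cd <- phenotypes(coh)
  cd$ever_drinker <- 1L
  expect_error(interaction_test(g, cd), "constant")
})

test_that("family-history association recovers the simulated slope", {
  cfg <- small_config(41, n_cases = 2500, n_controls = 100,
                      family_history_slope = 0.35, missing_rate = 0)
  coh <- simulate_cohort(cfg)
  prs <- compute_prs(coh, cfg$panel, "SNP_HLA")
  fh <- family_history_association(prs, phenotypes(coh))
  est <- tidy(fh$fit)
  slope <- est$estimate[est$term == "score"]
  se <- est$std.error[est$term == "score"]
  expect_gt(slope, 0)
  expect_lt(abs(slope - 0.35), 3 * se)
  # t comparison agrees in direction: FH-positive cases have higher PRS
  expect_gt(fh$t_test$mean_pos, fh$t_test$mean_neg)
  expect_gt(fh$t_test$t, 0)

  # identical groups -> t = 0
  prs0 <- structure(
    tibble::tibble(sample_id = as.character(1:40), status = 1L,
                   score = rep(c(1, 2, 3, 4), 10)),
    class = c("ps_prs", class(tibble::tibble())))
  # same score distribution {1,2,3,4} in each family-history class
  cd0 <- tibble::tibble(sample_id = as.character(1:40),
                        family_history = rep(rep(c(0L, 1L), each = 4), 5))
  fh0 <- family_history_association(prs0, cd0)
  expect_equal(fh0$t_test$t, 0, tolerance = 1e-12)
})

test_that("null family-history slope CIs cover zero at the nominal rate", {
  covered <- 0L
  n_seeds <- 60L
  for (seed in seq_len(n_seeds)) {
    cfg <- small_config(seed + 100, n_cases = 700, n_controls = 50,
                        family_history_slope = 0, missing_rate = 0)
    coh <- simulate_cohort(cfg)
    prs <- compute_prs(coh, cfg$panel, "SNP_HLA")
    fh <- family_history_association(prs, phenotypes(coh))
    est <- tidy(fh$fit)
    s <- est$estimate[est$term == "score"]
    se <- est$std.error[est$term == "score"]
    if (abs(s) < 1.96 * se) covered <- covered + 1L
  }
  # nominal 95%; >= 4-sigma binomial slack below 0.95 * 60 = 57, since a
  # Wald interval is only asymptotically exact
  expect_gte(covered, 48L)
})
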