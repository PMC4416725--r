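# brute-force AUC over all case-control pairs
auc_bruteforce <- function(scores, status) {
  case <- scores[status == 1]; ctrl <- scores[status == 0]
  mean(outer(case, ctrl, function(a, b) (a > b) + 0.5 * (a == b)))
}

# trapezoidal area under the (fpr, tpr) polygon
auc_trapezoid <- function(curve) {
  pts <- curve$points[order(curve$points$fpr, curve$points$tpr), ]
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  expect_equal(roc_auc(data.frame(score = c(2, 3, 0, 1),
                                  status = c(1, 1, 0, 0)))$auc, 1.0)
  expect_equal(roc_auc(data.frame(score = c(1, 3, 0, 2),
                                  status = c(1, 1, 0, 0)))$auc, 0.75)
  set.seed(14)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    status <- c(0, 1, rbinom(n - 2, 1, 0.5))
    r <- roc_auc(data.frame(score = scores, status = status))
    expect_equal(r$auc, auc_bruteforce(scores, status), tolerance = 1e-12)
    # label swap reverses the AUC
    r2 <- roc_auc(data.frame(score = scores, status = 1 - status))
    expect_equal(r2$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("trapezoidal curve area equals the Mann-Whitney AUC exactly", {
  set.seed(15)
  for (i in 1:30) {
    n <- sample(10:80, 1)
    scores <- c(rnorm(n %/% 2), sample(1:4, n - n %/% 2, replace = TRUE))
    status <- c(0, 1, rbinom(n - 2, 1, 0.5))
    r <- roc_auc(data.frame(score = scores, status = status))
    expect_equal(auc_trapezoid(r), r$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(16)
  scores <- rnorm(100)
  status <- rbinom(100, 1, plogis(scores))
  a0 <- roc_auc(data.frame(score = scores, status = status))$auc
  for (f in list(function(x) 3 * x + 7, exp, function(x) x^3)) {
    expect_equal(roc_auc(data.frame(score = f(scores), status = status))$auc,
                 a0, tolerance = 1e-12)
  }
})

test_that("constant scores give a flagged AUC of one half", {
  r <- roc_auc(data.frame(score = rep(1, 20),
                          status = rep(c(0, 1), 10)))
  expect_equal(r$auc, 0.5)
  expect_true(r$degenerate)
})

test_that("AUC and DeLong variance match pROC", {
  skip_if_not_installed("pROC")
  set.seed(18)
  n <- 150
  score <- rnorm(n)
  status <- rbinom(n, 1, plogis(score))
  r <- roc_auc(data.frame(score = score, status = status))
  ref <- pROC::roc(status, score, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(r$se^2, as.numeric(pROC::var(ref)), tolerance = 1e-10)
})

test_that("self-comparison yields z = 0 and p = 1", {
  d <- data.frame(score = rnorm(30), status = rep(c(0, 1), 15))
  d$score2 <- d$score
  cmp <- delong_compare(d, "score", "score2")
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$var_diff, 0)
})

test_that("DeLong comparison matches pROC's paired test", {
  skip_if_not_installed("pROC")
  set.seed(19)
  n <- 200
  latent <- rnorm(n)
  status <- rbinom(n, 1, plogis(latent))
  d <- data.frame(status = status,
                  a = latent + rnorm(n, 0, 1.0),
                  b = latent + rnorm(n, 0, 1.5))
  cmp <- delong_compare(d, "a", "b")
  ra <- pROC::roc(d$status, d$a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(d$status, d$b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(cmp$z, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong p agrees with a paired bootstrap on a simulated cohort", {
  set.seed(20)
  n <- 200
  latent <- rnorm(n)
  status <- c(rep(0, 3), rep(1, 3), rbinom(n - 6, 1, plogis(latent[-(1:6)])))
  d <- data.frame(status = status,
                  a = latent + rnorm(n, 0, 1.1),
                  b = latent + rnorm(n, 0, 1.4))
  cmp <- delong_compare(d, "a", "b")
  boots <- replicate(2000, {
    idx <- sample(n, replace = TRUE)
    while (length(unique(d$status[idx])) < 2) idx <- sample(n, replace = TRUE)
    db <- d[idx, ]
    roc_auc(db, "a")$auc - roc_auc(db, "b")$auc
  })
  p_boot <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  expect_lt(abs(cmp$p - p_boot), 0.02)
})

test_that("the variance of an AUC difference is nonnegative on random data", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    d <- data.frame(status = c(0, 1, rbinom(n - 2, 1, 0.5)),
                    a = sample(1:6, n, replace = TRUE),
                    b = rnorm(n))
    cmp <- delong_compare(d, "a", "b")
    expect_gte(cmp$var_diff, 0)
    # single-curve variances bound: var(diff) <= (se_a + se_b)^2
    se_a <- roc_auc(d, "a")$se
    se_b <- roc_auc(d, "b")$se
    expect_lte(cmp$var_diff, (se_a + se_b)^2 + 1e-12)
  }
})

test_that("Youden operating point is found by exhaustive search", {
  # cases {1,3}, controls {0,2}: enumerate all thresholds by brute force
  d <- data.frame(score = c(1, 3, 0, 2), status = c(1, 1, 0, 0))
  r <- roc_auc(d)
  op <- sens_spec_at(r)
  cand <- sort(unique(c(-Inf, d$score)))
  youdens <- vapply(cand, function(t) {
    mean(d$score[d$status == 1] > t) + mean(d$score[d$status == 0] <= t) - 1
  }, numeric(1))
  expect_equal(op$youden, max(youdens), tolerance = 1e-12)
  # perfect separation: sens = spec = 1
  perf <- sens_spec_at(roc_auc(data.frame(score = c(5, 6, 1, 2),
                                          status = c(1, 1, 0, 0))))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  # fixed threshold path
  fx <- sens_spec_at(r, criterion = 1.5)
  expect_equal(fx$sensitivity, 0.5)
  expect_equal(fx$specificity, 0.5)
})

test_that("model AUCs are ordered SNP < HLA < SNP-HLA < SNP-HLA-Drink", {
  for (seed in 1:3) {
    cfg <- small_config(seed + 200, n_cases = 1500, n_controls = 1500)
    coh <- simulate_cohort(cfg)
    ph <- tibble::as_tibble(coh)[, c("sample_id", "status")]
    aucs <- vapply(c("SNP", "HLA", "SNP_HLA", "SNP_HLA_DRINK"), function(m) {
      prs <- compute_prs(coh, cfg$panel, m, missing_policy = "expected_dosage")
      roc_auc(prs)$auc
    }, numeric(1))
    expect_true(all(diff(aucs) > 0),
                label = paste("AUC ordering, seed", seed))
    # operating point of the full genetic model in the qualitative band
    prs <- compute_prs(coh, cfg$panel, "SNP_HLA", missing_policy = "expected_dosage")
    op <- sens_spec_at(roc_auc(prs))
    expect_gt(op$sensitivity, 0.70); expect_lt(op$sensitivity, 0.95)
    expect_gt(op$specificity, 0.70); expect_lt(op$specificity, 0.95)
  }
})

test_that("weights scored against unrelated phenotypes discriminate nothing", {
  # mirrors the negative-control check on an unrelated disease cohort:
  # scores built from the panel's weights on genotypes simulated with all
  # true ORs = 1 (phenotype independent of genotype)
  cfg <- small_config(31, n_cases = 1200, n_controls = 1200,
                      snp_ors = rep(1, 14), missing_rate = 0)
  coh <- simulate_genotypes(cfg)
  prs <- compute_prs(coh, cfg$panel, "SNP_HLA")
  r <- roc_auc(prs)
  expect_lt(abs(r$auc - 0.5), 3 * r$se)
})
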