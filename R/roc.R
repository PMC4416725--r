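psi_mw <- function(case, ctrl) {
  # Mann-Whitney kernel with midrank tie handling
  outer(case, ctrl, function(a, b) (a > b) + 0.5 * (a == b))
}

# DeLong placement values via midranks (equals row/col means of psi_mw)
placements <- function(case, ctrl) {
  m <- length(case)
  n <- length(ctrl)
  r_all <- rank(c(case, ctrl))
  r_case <- rank(case)
  r_ctrl <- rank(ctrl)
  v10 <- (r_all[seq_len(m)] - r_case) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrl) / m
  list(v10 = v10, v01 = v01)
}

#' ROC curve and AUC for a score
#'
#' Builds the ROC curve over all distinct score thresholds (classifying
#' `score > t` as case) and computes the AUC as the Mann-Whitney statistic
#' with midrank tie handling: the mean over case-control pairs of
#' `[score_case > score_control] + 1/2 [tie]`. The trapezoidal area under
#' the curve equals this estimate exactly.
#'
#' @param data Data frame with a score and a 0/1 status column (e.g. a
#'   `ps_prs`).
#' @param score,status Column names.
#' @return Object of class `ps_roc`: `points` tibble (threshold, fpr =
#'   1 - specificity, tpr = sensitivity), `auc`, `se` (DeLong), `n_case`,
#'   `n_control`, `degenerate` flag for constant scores.
#' @examples
#' roc_auc(data.frame(score = c(1, 3, 0, 2), status = c(1, 1, 0, 0)))$auc
#' @export
roc_auc <- function(data, score = "score", status = "status") {
  d <- tibble::as_tibble(data)
  x <- d[[score]]
  y <- d[[status]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  case <- x[y == 1]
  ctrl <- x[y == 0]
  if (length(case) == 0 || length(ctrl) == 0) {
    abort("need at least one case and one control")
  }
  # midrank AUC via ranks (O(n log n)); pairwise kernel kept for DeLong
  r <- rank(c(case, ctrl))
  auc <- (sum(r[seq_along(case)]) - length(case) * (length(case) + 1) / 2) /
    (length(case) * length(ctrl))
  thr <- c(-Inf, sort(unique(x)))
  points <- tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(ctrl > t), numeric(1)),
    tpr = vapply(thr, function(t) mean(case > t), numeric(1))
  )
  degenerate <- length(unique(x)) == 1
  pl <- placements(case, ctrl)
  se <- sqrt(var(pl$v10) / length(case) + var(pl$v01) / length(ctrl))
  if (is.na(se)) se <- 0
  structure(list(points = points, auc = auc, se = se,
                 n_case = length(case), n_control = length(ctrl),
                 degenerate = degenerate),
            class = "ps_roc")
}

#' @export
print.ps_roc <- function(x, ...) {
  ci <- x$auc + c(-1.96, 1.96) * x$se
  cat("<ps_roc> AUC =", format(x$auc, digits = 4),
      sprintf("(DeLong 95%% CI %.4f-%.4f)", ci[1], ci[2]),
      "on", x$n_case, "cases /", x$n_control, "controls\n")
  if (x$degenerate) cat("note: constant scores (degenerate curve)\n")
  invisible(x)
}

#' DeLong test comparing two paired AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors measured on
#' the same samples, using DeLong's structural components: per-case and
#' per-control placement values of each marker give an estimate of the
#' covariance of the paired AUCs; `z = (AUC_a - AUC_b) / sqrt(var)` with a
#' two-sided normal p-value. Comparing a marker with itself yields z = 0,
#' p = 1.
#'
#' @param data Data frame with two score columns and a 0/1 status column.
#' @param score_a,score_b Names of the two score columns.
#' @param status Name of the status column.
#' @return Object of class `ps_roc_comparison`: `auc_a`, `auc_b`,
#'   `var_diff`, `z`, `p`, sample sizes.
#' @export
delong_compare <- function(data, score_a, score_b, status = "status") {
  d <- tibble::as_tibble(data)
  keep <- !is.na(d[[score_a]]) & !is.na(d[[score_b]]) & !is.na(d[[status]])
  d <- d[keep, ]
  y <- d[[status]]
  case <- y == 1
  m <- sum(case); n <- sum(!case)
  if (m == 0 || n == 0) abort("need at least one case and one control")
  pa <- placements(d[[score_a]][case], d[[score_a]][!case])
  pb <- placements(d[[score_b]][case], d[[score_b]][!case])
  V10 <- cbind(pa$v10, pb$v10)
  V01 <- cbind(pa$v01, pb$v01)
  aucs <- colMeans(V10)
  S10 <- stats::cov(V10)
  S01 <- stats::cov(V01)
  var_diff <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  var_diff <- max(var_diff, 0)
  diff <- aucs[1] - aucs[2]
  z <- if (var_diff == 0) 0 else diff / sqrt(var_diff)
  structure(list(auc_a = aucs[1], auc_b = aucs[2], var_diff = var_diff,
                 z = z, p = 2 * pnorm(-abs(z)), n_case = m, n_control = n),
            class = "ps_roc_comparison")
}

#' @export
print.ps_roc_comparison <- function(x, ...) {
  cat("<ps_roc_comparison> AUC_a =", format(x$auc_a, digits = 4),
      "AUC_b =", format(x$auc_b, digits = 4),
      "z =", format(x$z, digits = 4), "p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' @method tidy ps_roc_comparison
#' @export
tidy.ps_roc_comparison <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b,
                 var_diff = x$var_diff, statistic = x$z, p.value = x$p)
}

#' Operating point of a ROC curve
#'
#' Either the Youden-optimal threshold (maximising sensitivity +
#' specificity - 1, ties broken toward higher specificity) or the
#' sensitivity/specificity at a fixed threshold.
#'
#' @param curve A `ps_roc` from [roc_auc()].
#' @param criterion `"youden"` or a numeric threshold.
#' @return One-row tibble: threshold, sensitivity, specificity, youden.
#' @export
sens_spec_at <- function(curve, criterion = "youden") {
  pts <- curve$points
  if (identical(criterion, "youden")) {
    j <- pts$tpr - pts$fpr
    best <- which(j == max(j))
    # ties toward higher specificity = smaller fpr = larger threshold
    best <- best[which.min(pts$fpr[best])]
    tibble::tibble(threshold = pts$threshold[best],
                   sensitivity = pts$tpr[best],
                   specificity = 1 - pts$fpr[best],
                   youden = j[best])
  } else {
    t <- as.numeric(criterion)
    i <- findInterval(t, pts$threshold)  # largest tabulated threshold <= t
    sens <- pts$tpr[i]
    spec <- 1 - pts$fpr[i]
    tibble::tibble(threshold = t, sensitivity = sens,
                   specificity = spec, youden = sens + spec - 1)
  }
}
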