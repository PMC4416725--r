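#' Plot a ROC curve
#'
#' @param object A `ps_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ps_roc
#' @export
autoplot.ps_roc <- function(object, ...) {
  pts <- dplyr::arrange(object$points, .data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.4f)", object$auc))
}

#' Plot PRS distributions by case/control status
#'
#' @param object A `ps_prs` from [compute_prs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ps_prs
#' @export
autoplot.ps_prs <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- ifelse(d$status == 1, "case", "control")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "Polygenic risk score", y = "Density", fill = NULL,
                  title = paste0("PRS distribution (", attr(object, "model"), ")"))
}

#' Forest plot of risk-group odds ratios
#'
#' @param object A `ps_risk_table` from [group_or_table()].
#' @param ... Unused.
#' @return A ggplot (log-scaled OR axis).
#' @method autoplot ps_risk_table
#' @export
autoplot.ps_risk_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$group_label <- paste0("Group ", d$group, "\n", d$prs_range)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group_label, y = .data$or)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Control-quartile PRS group", y = "Odds ratio (95% CI)")
}

#' Plot a Kaplan-Meier onset curve as cumulative risk
#'
#' Displays `1 - S(t)`, the cumulative probability of onset by age.
#'
#' @param object A `ps_km` from [km_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ps_km
#' @export
autoplot.ps_km <- function(object, ...) {
  d <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1), object$curve)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = 1 - .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Age of onset (years)", y = "Cumulative onset risk")
}
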