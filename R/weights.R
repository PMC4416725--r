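#' Construct a variant weight panel
#'
#' A weight panel holds, for each variant in the score, its risk allele, the
#' published per-allele odds ratio, and the PRS weight `w = ln(OR)`. One
#' variant may be flagged as the large-effect HLA locus; the panel then
#' partitions into the nested score models `SNP` (non-HLA), `HLA` and
#' `SNP_HLA` (all variants). An optional environmental log-odds weight (for
#' ever-drinking) extends `SNP_HLA` to `SNP_HLA_DRINK`.
#'
#' @param x A data frame with columns `snp_id`, `risk_allele`, `other_allele`,
#'   `odds_ratio` (or `or`) and logical/0-1 `is_hla`.
#' @param environment_or Optional positive odds ratio for the binary
#'   environmental exposure (ever-drinking); stored as `ln(environment_or)`.
#' @return A tibble of class `ps_weights` with a `weight = ln(odds_ratio)`
#'   column and an `environment_weight` attribute (`NA` when unset).
#' @examples
#' panel <- weight_panel(data.frame(
#'   snp_id = c("rs1", "rs2"), risk_allele = c("A", "C"),
#'   other_allele = c("G", "T"), odds_ratio = c(1.3, 8.0),
#'   is_hla = c(FALSE, TRUE)
#' ), environment_or = 2.49)
#' panel$weight
#' @export
weight_panel <- function(x, environment_or = NULL) {
  x <- tibble::as_tibble(x)
  if ("or" %in% names(x) && !"odds_ratio" %in% names(x)) {
    x <- dplyr::rename(x, odds_ratio = "or")
  }
  need <- c("snp_id", "risk_allele", "other_allele", "odds_ratio", "is_hla")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("weight panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$snp_id <- as.character(x$snp_id)
  x$risk_allele <- toupper(as.character(x$risk_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  x$odds_ratio <- as.numeric(x$odds_ratio)
  x$is_hla <- as.logical(x$is_hla)
  if (anyDuplicated(x$snp_id)) {
    abort(paste0("duplicate snp_id in weight panel: ",
                 paste(unique(x$snp_id[duplicated(x$snp_id)]), collapse = ", ")))
  }
  if (any(!is.finite(x$odds_ratio)) || any(x$odds_ratio <= 0)) {
    abort("every odds_ratio must be a finite positive number")
  }
  if (any(x$risk_allele == x$other_allele)) {
    abort("risk_allele must differ from other_allele")
  }
  ok <- c("A", "C", "G", "T")
  if (!all(c(x$risk_allele, x$other_allele) %in% ok)) {
    abort("alleles must be single bases A/C/G/T")
  }
  if (any(is.na(x$is_hla))) abort("is_hla must be TRUE/FALSE for every variant")
  x$weight <- log(x$odds_ratio)
  x <- x[, c("snp_id", "risk_allele", "other_allele", "odds_ratio",
             "weight", "is_hla")]
  env_w <- NA_real_
  if (!is.null(environment_or) && !is.na(environment_or)) {
    if (environment_or <= 0) abort("environment_or must be positive")
    env_w <- log(environment_or)
  }
  structure(x, environment_weight = env_w,
            class = c("ps_weights", class(tibble::tibble())))
}

#' Read a variant weight panel from TSV
#'
#' The file is tab-delimited with header columns `snp_id`, `risk_allele`,
#' `other_allele`, `or`, `is_hla`. An optional footer row whose
#' `risk_allele` and `other_allele` are both `"-"` carries the odds ratio of
#' the binary environmental exposure (ever-drinking) instead of a variant;
#' its `ln(or)` becomes the panel's `environment_weight`.
#'
#' @param path Path to the TSV file.
#' @return A [weight_panel()] tibble.
#' @export
read_weights <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    risk_allele = readr::col_character(),
    other_allele = readr::col_character(),
    or = readr::col_double(),
    is_hla = readr::col_integer()
  ), progress = FALSE)
  is_env <- raw$risk_allele == "-" & raw$other_allele == "-"
  env_or <- NULL
  if (any(is_env)) {
    if (sum(is_env) > 1) abort("at most one environment-exposure row allowed")
    env_or <- raw$or[is_env]
    if (is.na(env_or) || env_or <= 0) abort("environment row must have or > 0")
  }
  weight_panel(raw[!is_env, ], environment_or = env_or)
}

#' Write a weight panel to TSV
#'
#' Inverse of [read_weights()]: variant rows in panel order, then the
#' environment-exposure footer row (alleles `"-"`) if the panel carries one.
#'
#' @param panel A [weight_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(panel, path) {
  out <- tibble::tibble(
    snp_id = panel$snp_id,
    risk_allele = panel$risk_allele,
    other_allele = panel$other_allele,
    or = panel$odds_ratio,
    is_hla = as.integer(panel$is_hla)
  )
  env_w <- attr(panel, "environment_weight")
  if (!is.na(env_w)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      snp_id = "ever_drinking", risk_allele = "-", other_allele = "-",
      or = exp(env_w), is_hla = 0L
    ))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Environmental exposure weight of a panel
#'
#' @param panel A [weight_panel()].
#' @return The stored `ln(OR)` for ever-drinking, or `NA` if unset.
#' @export
environment_weight <- function(panel) attr(panel, "environment_weight")

#' Restrict a weight panel to a score model
#'
#' `SNP` keeps non-HLA variants, `HLA` the HLA-flagged variant(s), and
#' `SNP_HLA` / `SNP_HLA_DRINK` keep all variants (the drink model adds the
#' environmental term at scoring time, not here).
#'
#' @param panel A [weight_panel()].
#' @param model One of `"SNP"`, `"HLA"`, `"SNP_HLA"`, `"SNP_HLA_DRINK"`.
#' @return The sub-panel as a `ps_weights` tibble (environment weight kept).
#' @export
panel_subset <- function(panel, model = c("SNP_HLA", "SNP", "HLA", "SNP_HLA_DRINK")) {
  model <- match.arg(model)
  keep <- switch(model,
    SNP = !panel$is_hla,
    HLA = panel$is_hla,
    SNP_HLA = rep(TRUE, nrow(panel)),
    SNP_HLA_DRINK = rep(TRUE, nrow(panel))
  )
  if (!any(keep)) abort(paste0("model ", model, " selects no variants"))
  structure(panel[keep, ], environment_weight = attr(panel, "environment_weight"),
            class = class(panel))
}
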