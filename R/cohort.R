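#' Build a cohort table from phenotypes and genotype dosages
#'
#' A cohort is a tibble with one row per sample: the phenotype columns
#' `sample_id`, `status` (1 = case, 0 = control), `age` (years), `sex`
#' (1 = male, 0 = female), `family_history`, `ever_drinker`, `onset_age`
#' (cases only), followed by one integer dosage column per variant holding
#' the risk-allele count (0/1/2, `NA` = missing genotype). The variant
#' column order is recorded in the `variant_ids` attribute.
#'
#' @param phenotypes Data frame with at least `sample_id` and `status`;
#'   optional `age`, `sex`, `family_history`, `ever_drinker`, `onset_age`.
#' @param dosage Numeric matrix (samples x variants) of risk-allele counts
#'   in \{0, 1, 2, NA\}, columns named by variant id.
#' @return A tibble of class `ps_cohort`.
#' @export
as_cohort <- function(phenotypes, dosage) {
  ph <- tibble::as_tibble(phenotypes)
  if (!all(c("sample_id", "status") %in% names(ph))) {
    abort("phenotypes must have sample_id and status columns")
  }
  ph$sample_id <- as.character(ph$sample_id)
  for (col in c("age", "sex", "family_history", "ever_drinker", "onset_age")) {
    if (!col %in% names(ph)) ph[[col]] <- NA_real_
  }
  ph <- ph[, c("sample_id", "status", "age", "sex", "family_history",
               "ever_drinker", "onset_age")]
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) abort("dosage columns must be named by variant id")
  if (nrow(dosage) != nrow(ph)) {
    abort("dosage rows must match phenotype rows")
  }
  validate_phenotypes(ph)
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) abort("every non-missing dosage must be 0, 1 or 2")
  out <- dplyr::bind_cols(ph, tibble::as_tibble(dosage))
  new_cohort(out, colnames(dosage))
}

new_cohort <- function(tbl, variant_ids) {
  structure(tibble::as_tibble(tbl), variant_ids = as.character(variant_ids),
            class = c("ps_cohort", class(tibble::tibble())))
}

validate_phenotypes <- function(ph) {
  if (any(is.na(ph$status))) abort("status must be 0/1 with no missing values")
  if (!all(ph$status %in% c(0, 1))) {
    abort(paste0("unknown status code(s): ",
                 paste(unique(ph$status[!ph$status %in% c(0, 1)]), collapse = ", ")))
  }
  if (anyDuplicated(ph$sample_id)) abort("duplicate sample_id in phenotypes")
  onset <- ph$onset_age
  has_onset <- !is.na(onset)
  if (any(has_onset & ph$status == 0)) {
    abort("onset_age is defined only for cases (controls were screened negative)")
  }
  late <- has_onset & !is.na(ph$age) & onset > ph$age
  if (any(late)) {
    abort(paste0("onset_age exceeds age for sample(s): ",
                 paste(ph$sample_id[late], collapse = ", ")))
  }
  if (any(has_onset & onset <= 0)) abort("onset_age must be positive")
  invisible(ph)
}

#' Variant ids of a cohort
#' @param cohort A `ps_cohort`.
#' @return Character vector of variant ids in dosage-column order.
#' @export
variant_ids <- function(cohort) attr(cohort, "variant_ids")

#' Extract the dosage matrix of a cohort
#' @param cohort A `ps_cohort`.
#' @return Integer matrix (samples x variants) of risk-allele counts,
#'   rownames = sample ids.
#' @export
dosage_matrix <- function(cohort) {
  m <- as.matrix(as.data.frame(cohort)[, variant_ids(cohort), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$sample_id
  m
}

#' Phenotype columns of a cohort
#' @param cohort A `ps_cohort`.
#' @return Tibble of the per-sample phenotype record columns.
#' @export
phenotypes <- function(cohort) {
  tibble::as_tibble(cohort)[, c("sample_id", "status", "age", "sex",
                                "family_history", "ever_drinker", "onset_age")]
}

keep_samples <- function(cohort, keep) {
  new_cohort(tibble::as_tibble(cohort)[keep, , drop = FALSE], variant_ids(cohort))
}

drop_variants <- function(cohort, drop_ids) {
  kept <- setdiff(variant_ids(cohort), drop_ids)
  tbl <- tibble::as_tibble(cohort)
  tbl <- tbl[, !(names(tbl) %in% drop_ids), drop = FALSE]
  new_cohort(tbl, kept)
}

#' Read PLINK text genotypes into a cohort
#'
#' Parses a whitespace-delimited `.ped`/`.map` pair. Each `.ped` row has six
#' leading columns (FID, IID, PAT, MAT, SEX, PHENO) followed by two allele
#' calls per variant; `0 0` codes a missing genotype. Alleles are matched
#' against the panel's risk/other alleles and converted to risk-allele
#' dosages, irrespective of the within-genotype allele order. The PLINK
#' phenotype column (1 = control, 2 = case) becomes `status` 0/1; samples
#' with phenotype `0` or `-9` have no usable status and are dropped with a
#' warning. PLINK sex 1/2 is recoded to `sex` 1 = male / 0 = female.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @param panel A [weight_panel()] covering the `.map` variants used.
#' @return A `ps_cohort` with dosages and `status`/`sex` filled in (other
#'   phenotype fields `NA`; merge a phenotype table for the rest).
#' @export
read_ped_map <- function(ped_path, map_path, panel) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) abort("malformed .map: expected 4 columns (chr, id, cm, bp)")
  snp_ids <- as.character(map[[2]])
  unknown <- setdiff(snp_ids, panel$snp_id)
  if (length(unknown) > 0) {
    abort(paste0(".map lists variant(s) absent from the weight panel: ",
                 paste(unknown, collapse = ", ")))
  }
  idx <- match(snp_ids, panel$snp_id)
  risk <- panel$risk_allele[idx]
  other <- panel$other_allele[idx]

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  want <- 6 + 2 * length(snp_ids)
  n <- length(lines)
  dosage <- matrix(NA_real_, n, length(snp_ids),
                   dimnames = list(NULL, snp_ids))
  sample_id <- character(n)
  status <- integer(n)
  sex <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != want) {
      abort(paste0("malformed .ped line ", i, ": expected ", want,
                   " fields, found ", length(f)))
    }
    sample_id[i] <- f[2]
    sex[i] <- ifelse(f[5] == "1", 1L, ifelse(f[5] == "2", 0L, NA_integer_))
    status[i] <- switch(f[6], "2" = 1L, "1" = 0L, NA_integer_)
    a1 <- f[seq(7, want, by = 2)]
    a2 <- f[seq(8, want, by = 2)]
    for (j in seq_along(snp_ids)) {
      pair <- c(a1[j], a2[j])
      if (all(pair == "0")) next
      legal <- pair %in% c(risk[j], other[j])
      if (!all(legal)) {
        abort(paste0("allele '", pair[!legal][1], "' at ", snp_ids[j],
                     " for sample ", sample_id[i],
                     " matches neither risk nor other allele (strand/allele error)"))
      }
      dosage[i, j] <- sum(pair == risk[j])
    }
  }
  drop <- is.na(status)
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop),
                " sample(s) with missing phenotype code (-9/0): ",
                paste(sample_id[drop], collapse = ", ")))
  }
  as_cohort(
    tibble::tibble(sample_id = sample_id[!drop], status = status[!drop],
                   sex = sex[!drop]),
    dosage[!drop, , drop = FALSE]
  )
}

#' Read a phenotype table from TSV
#'
#' Tab-delimited with header; expected columns `sample_id`, `status` (0/1),
#' and optionally `age`, `sex` (1 = male), `family_history`, `ever_drinker`,
#' `onset_age`; `NA` for missing. Records are validated: status must be 0/1,
#' onset_age only for cases and never exceeding current age.
#'
#' @param path Path to the TSV file.
#' @return A tibble of per-sample phenotype records.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, na = c("NA", ""))
  for (col in c("age", "sex", "family_history", "ever_drinker", "onset_age")) {
    if (!col %in% names(ph)) ph[[col]] <- NA_real_
  }
  for (col in c("status", "sex", "family_history", "ever_drinker")) {
    ph[[col]] <- as.integer(ph[[col]])
  }
  ph <- ph[, c("sample_id", "status", "age", "sex", "family_history",
               "ever_drinker", "onset_age")]
  validate_phenotypes(ph)
  ph
}

#' Attach phenotype records to a genotyped cohort
#'
#' Joins a phenotype table (e.g. from [read_phenotypes()]) onto a cohort by
#' `sample_id`, overriding the placeholder phenotype columns. `status` must
#' agree where both sources define it.
#'
#' @param cohort A `ps_cohort`.
#' @param pheno A phenotype tibble with `sample_id`.
#' @return The cohort with phenotype columns filled in.
#' @export
attach_phenotypes <- function(cohort, pheno) {
  pheno <- tibble::as_tibble(pheno)
  m <- match(cohort$sample_id, pheno$sample_id)
  if (any(is.na(m))) {
    abort(paste0("phenotype table is missing sample(s): ",
                 paste(cohort$sample_id[is.na(m)], collapse = ", ")))
  }
  both <- !is.na(cohort$status) & !is.na(pheno$status[m])
  if (any(cohort$status[both] != pheno$status[m][both])) {
    abort("status disagrees between genotype file and phenotype table")
  }
  tbl <- tibble::as_tibble(cohort)
  for (col in c("status", "age", "sex", "family_history", "ever_drinker",
                "onset_age")) {
    if (col %in% names(pheno)) tbl[[col]] <- pheno[[col]][m]
  }
  validate_phenotypes(tbl[, c("sample_id", "status", "age", "sex",
                              "family_history", "ever_drinker", "onset_age")])
  new_cohort(tbl, variant_ids(cohort))
}

#' Write a cohort's genotypes as PLINK text
#'
#' Inverse of [read_ped_map()]: dosages become allele pairs using the
#' panel's risk/other alleles (`0 0` for missing), status becomes the PLINK
#' 1/2 phenotype, sex becomes PLINK 1/2 (0 when unknown).
#'
#' @param cohort A `ps_cohort`.
#' @param panel The [weight_panel()] providing allele symbols.
#' @param ped_path,map_path Output paths.
#' @return `ped_path`, invisibly.
#' @export
write_ped_map <- function(cohort, panel, ped_path, map_path) {
  ids <- variant_ids(cohort)
  idx <- match(ids, panel$snp_id)
  if (any(is.na(idx))) abort("panel does not cover every cohort variant")
  map <- data.frame(chr = 0L, id = ids, cm = 0, bp = seq_along(ids))
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  dm <- dosage_matrix(cohort)
  risk <- panel$risk_allele[idx]
  other <- panel$other_allele[idx]
  ped_rows <- vapply(seq_len(nrow(dm)), function(i) {
    g <- dm[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, risk, other))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, risk, other))
    sex <- cohort$sex[i]
    paste(c(cohort$sample_id[i], cohort$sample_id[i], "0", "0",
            ifelse(is.na(sex), "0", ifelse(sex == 1, "1", "2")),
            ifelse(cohort$status[i] == 1, "2", "1"),
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(ped_rows, ped_path)
  invisible(ped_path)
}

#' Write a cohort's phenotype records to TSV
#' @param cohort A `ps_cohort` (or a phenotype tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  ph <- if (inherits(cohort, "ps_cohort")) phenotypes(cohort) else
    tibble::as_tibble(cohort)
  readr::write_tsv(ph, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @export
print.ps_cohort <- function(x, ...) {
  cat("<ps_cohort> ", nrow(x), " samples (",
      sum(x$status == 1, na.rm = TRUE), " cases / ",
      sum(x$status == 0, na.rm = TRUE), " controls), ",
      length(variant_ids(x)), " variants\n", sep = "")
  NextMethod()
}
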