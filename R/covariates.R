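#' Read the per-subject covariate table
#'
#' The covariate CSV has one row per subject with columns `subject_id`,
#' `genotype` (APOE2/APOE3/APOE4), `sex` (F/M), `age_months` (positive),
#' `diet` (CTRL/HFD) and `immunity` (HN/mNos2). Missing values are a hard
#' error: the test battery needs complete factor labels.
#'
#' @param path CSV path.
#' @return A covariate tibble in canonical (lexicographic subject) order.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("covariate file not found: ", path))
  }
  cov <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    genotype = readr::col_character(),
    sex = readr::col_character(),
    age_months = readr::col_double(),
    diet = readr::col_character(),
    immunity = readr::col_character()
  ))
  validate_covariates(cov)
}

#' Validate a covariate table
#'
#' @param cov Data frame of per-subject covariates.
#' @return Validated tibble in canonical subject order.
#' @export
validate_covariates <- function(cov) {
  required <- c("subject_id", "genotype", "sex", "age_months", "diet", "immunity")
  missing <- setdiff(required, names(cov))
  if (length(missing) > 0) {
    abort(paste0("covariates missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(cov$subject_id)) {
    abort("duplicated subject_id in covariates")
  }
  if (anyNA(cov[required])) {
    bad <- cov$subject_id[rowSums(is.na(cov[required])) > 0][1]
    abort(paste0("missing covariate value for subject ", bad,
                 " (no imputation is performed)"))
  }
  lv <- scn_factor_levels()
  for (f in c("genotype", "sex", "diet", "immunity")) {
    bad <- setdiff(unique(cov[[f]]), lv[[f]])
    if (length(bad) > 0) {
      abort(paste0("unknown ", f, " level(s): ", paste(bad, collapse = ", ")))
    }
  }
  if (any(cov$age_months <= 0)) {
    abort("age_months must be positive")
  }
  tbl <- tibble::as_tibble(cov)[c(required, setdiff(names(cov), required))]
  tbl[order(tbl$subject_id), ]
}

#' Write a covariate table to CSV
#'
#' @param cov Covariate tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  readr::write_csv(cov, path)
  invisible(path)
}

#' Binarize age within genotype
#'
#' Age is a continuous covariate but enters the test battery as a two-level
#' factor: each subject is labelled `young` or `old` relative to the median
#' age of its own genotype group. Ties go to `young` (age equal to the
#' median counts as young), which keeps the split deterministic.
#'
#' @param cov Covariate tibble (see [read_covariates()]).
#' @return The tibble with an added/overwritten `age_bin` column.
#' @export
binarize_age <- function(cov) {
  cov <- validate_covariates(cov)
  if (nrow(cov) == 0) {
    abort("cannot binarize age on an empty covariate table")
  }
  dplyr::mutate(
    dplyr::group_by(cov, .data$genotype),
    age_bin = ifelse(.data$age_months <= median(.data$age_months), "young", "old"),
    .after = "age_months"
  ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id)
}

#' Select an analysis cohort by factor-level constraints
#'
#' Returns the subjects satisfying every constraint, in canonical
#' (lexicographic) order. Constraints are named factor = level pairs, e.g.
#' `filter_cohort(cov, diet = "CTRL")` for the control-diet analysis or
#' `filter_cohort(cov, immunity = "HN")` for the humanized-immunity
#' analysis. With no constraints, all subjects are returned.
#'
#' @param cov Covariate tibble.
#' @param ... Named constraints; names among `genotype`, `sex`, `age`
#'   (the binarized `age_bin`), `diet`, `immunity`; values must be valid
#'   levels (a vector of levels selects their union).
#' @return Character vector of subject IDs.
#' @export
filter_cohort <- function(cov, ...) {
  cov <- tibble::as_tibble(cov)
  constraints <- list(...)
  lv <- scn_factor_levels()
  keep <- rep(TRUE, nrow(cov))
  for (f in names(constraints)) {
    if (!f %in% names(lv)) {
      abort(paste0("unknown factor in cohort predicate: ", f))
    }
    levels_ok <- lv[[f]]
    wanted <- constraints[[f]]
    bad <- setdiff(wanted, levels_ok)
    if (length(bad) > 0) {
      abort(paste0("unknown level(s) for ", f, ": ", paste(bad, collapse = ", ")))
    }
    col <- if (f == "age") "age_bin" else f
    if (!col %in% names(cov)) {
      abort(paste0("covariates lack column '", col,
                   "'; run binarize_age() before filtering on age"))
    }
    keep <- keep & cov[[col]] %in% wanted
  }
  sort(cov$subject_id[keep])
}

#' Expand printed per-genotype cohort marginals into a covariate table
#'
#' Cohort descriptions are often published only as per-genotype marginal
#' counts: total N, number of females, number on high-fat diet, number with
#' humanized immunity, and the age mean/sd. This helper deterministically
#' expands such a counts table into one covariate row per subject whose
#' marginals reproduce the printed numbers exactly. The joint assignment of
#' sex x diet x immunity is a synthetic reconstruction (the published
#' marginals do not determine it): high-fat diet is assigned within the
#' mouse-Nos2 (non-HN) animals first, consistent with designs in which the
#' HFD x humanized-immunity cell is unsupported, and ages are deterministic
#' normal quantiles at the printed mean/sd.
#'
#' @param counts Data frame with columns `genotype`, `n`, `n_female`,
#'   `age_mean`, `age_sd`, `n_hfd`, `n_hn` (one row per genotype).
#' @return A covariate tibble (one row per subject) passing
#'   [validate_covariates()].
#' @export
expand_cohort_counts <- function(counts) {
  required <- c("genotype", "n", "n_female", "age_mean", "age_sd", "n_hfd", "n_hn")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort(paste0("counts table missing column(s): ", paste(missing, collapse = ", ")))
  }
  rows <- purrr::pmap(counts[required], function(genotype, n, n_female, age_mean,
                                                 age_sd, n_hfd, n_hn) {
    if (n_hfd > n - n_hn) {
      abort(paste0("cannot place all HFD mice outside the HN group for ", genotype))
    }
    # non-HN mice first so HFD (assigned from the front) never lands on HN
    immunity <- rep(c("mNos2", "HN"), c(n - n_hn, n_hn))
    diet <- rep(c("HFD", "CTRL"), c(n_hfd, n - n_hfd))
    # alternate sexes along the sequence so every diet/immunity stratum is mixed
    sex <- character(n)
    sex[seq_len(n) %% 2 == 1] <- rep_len("F", sum(seq_len(n) %% 2 == 1))
    sex[seq_len(n) %% 2 == 0] <- rep_len("M", sum(seq_len(n) %% 2 == 0))
    n_f <- sum(sex == "F")
    if (n_f != n_female) {
      flip_to <- if (n_f < n_female) "F" else "M"
      idx <- which(sex != flip_to)
      sex[utils::tail(idx, abs(n_f - n_female))] <- flip_to
    }
    ages <- stats::qnorm(stats::ppoints(n), mean = age_mean, sd = age_sd)
    tibble::tibble(
      subject_id = sprintf("%s_%03d", genotype, seq_len(n)),
      genotype = genotype,
      sex = sex,
      age_months = round(ages, 2),
      diet = diet,
      immunity = immunity
    )
  })
  validate_covariates(dplyr::bind_rows(rows))
}
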