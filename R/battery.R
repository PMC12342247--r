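#' One-hot encode subjects into multi-way group cells
#'
#' Reduces a multi-way K-sample comparison to an independence test: the
#' selected factors' levels are crossed, each subject is assigned to its
#' observed cell, empty cells are dropped, and membership is returned as a
#' one-hot matrix. Euclidean distances between one-hot rows (0 within a
#' group, sqrt(2) between groups) then feed the distance-correlation test.
#'
#' Genotype can be recoded one-vs-rest (e.g. `"APOE2_vs_rest"`) to contrast
#' one allele against the other two.
#'
#' @param cov Covariate tibble for the analysis cohort (with `age_bin` if
#'   `"age"` is among the factors; see [binarize_age()]).
#' @param factors Non-empty subset of
#'   `c("genotype", "sex", "age", "immunity", "diet")`.
#' @param genotype_coding `"three_level"` (default) or one of
#'   `"APOE2_vs_rest"`, `"APOE3_vs_rest"`, `"APOE4_vs_rest"`.
#' @return `s x K` one-hot numeric matrix, columns named by cell; rows in
#'   `cov` order.
#' @export
encode_groups <- function(cov, factors,
                          genotype_coding = c("three_level", "APOE2_vs_rest",
                                              "APOE3_vs_rest", "APOE4_vs_rest")) {
  genotype_coding <- match.arg(genotype_coding)
  known <- c("genotype", "sex", "age", "immunity", "diet")
  if (length(factors) == 0 || !all(factors %in% known)) {
    abort(paste0("factors must be a non-empty subset of: ",
                 paste(known, collapse = ", ")))
  }
  cols <- lapply(factors, function(f) {
    col <- if (f == "age") "age_bin" else f
    if (!col %in% names(cov)) {
      abort(paste0("covariates lack column '", col, "'"))
    }
    v <- cov[[col]]
    if (f == "genotype" && genotype_coding != "three_level") {
      target <- sub("_vs_rest$", "", genotype_coding)
      v <- ifelse(v == target, target, "rest")
    }
    v
  })
  cell <- do.call(paste, c(cols, sep = "."))
  cell <- factor(cell)  # observed cells only: empty cells never materialize
  counts <- table(cell)
  if (any(counts < 2)) {
    abort(paste0("degenerate test: group cell(s) with < 2 subjects: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  onehot <- stats::model.matrix(~ 0 + cell)
  colnames(onehot) <- levels(cell)
  rownames(onehot) <- cov$subject_id
  onehot
}

#' Test one region's latent features against a factor combination
#'
#' Computes Euclidean distance matrices over the region's per-subject
#' multimodal latent feature vectors and over the one-hot group encoding,
#' then the unbiased distance correlation and its fast chi-squared p-value.
#' Rejection means the region's latent-position distribution differs across
#' the groups, i.e. the region is vulnerable to that factor combination.
#'
#' @param features `s x q` matrix: one row per cohort subject (in `cov`
#'   order), the region's concatenated latent coordinates.
#' @param cov Cohort covariate tibble, rows aligned with `features`.
#' @inheritParams encode_groups
#' @return One-row tibble: `stat` (raw unbiased dcorr), `dcorr` (effect
#'   size, floored at 0), `p`, `n_subjects`, `n_groups`, `degenerate`.
#' @export
region_test <- function(features, cov, factors, genotype_coding = "three_level") {
  if (nrow(features) != nrow(cov)) {
    abort("features rows must match the cohort covariates")
  }
  labels <- encode_groups(cov, factors, genotype_coding)
  dx <- as.matrix(dist(features))
  dy <- as.matrix(dist(labels))
  stat <- dcorr_unbiased(dx, dy)
  degenerate <- isTRUE(attr(stat, "degenerate"))
  p <- if (degenerate) 1 else chi2_pvalue(as.numeric(stat), nrow(features))
  tibble::tibble(
    stat = as.numeric(stat),
    dcorr = max(as.numeric(stat), 0),
    p = p,
    n_subjects = nrow(features),
    n_groups = ncol(labels),
    degenerate = degenerate
  )
}

#' Enumerate the factor-combination test specs of an analysis
#'
#' Analysis `"A"` (control-diet cohort) crosses genotype, sex, age and
#' immunity; analysis `"B"` (humanized-immunity cohort) crosses genotype,
#' sex, age and diet. Diet and immunity never co-occur in one spec because
#' the design has no joint support. All `2^4 - 1 = 15` non-empty factor
#' subsets are emitted; subsets containing genotype are additionally
#' repeated for each requested one-vs-rest genotype coding (codings other
#' than `three_level` are meaningless without genotype and are not emitted
#' for genotype-free subsets).
#'
#' @param analysis `"A"` or `"B"`.
#' @param codings Genotype codings to include.
#' @return Tibble with columns `spec_id`, `analysis`, `factors`
#'   (list-column), `genotype_coding`.
#' @export
enumerate_specs <- function(analysis = c("A", "B"),
                            codings = "three_level") {
  analysis <- match.arg(analysis)
  all_codings <- c("three_level", "APOE2_vs_rest", "APOE3_vs_rest", "APOE4_vs_rest")
  bad <- setdiff(codings, all_codings)
  if (length(bad) > 0) {
    abort(paste0("unknown genotype coding(s): ", paste(bad, collapse = ", ")))
  }
  factors <- if (analysis == "A") {
    c("genotype", "sex", "age", "immunity")
  } else {
    c("genotype", "sex", "age", "diet")
  }
  subsets <- unlist(
    lapply(seq_along(factors), function(k) combn(factors, k, simplify = FALSE)),
    recursive = FALSE
  )
  rows <- purrr::map(subsets, function(fs) {
    cods <- if ("genotype" %in% fs) codings else "three_level"
    tibble::tibble(
      analysis = analysis,
      factors = list(fs),
      genotype_coding = cods
    )
  })
  out <- dplyr::bind_rows(rows)
  out$spec_id <- sprintf(
    "%s:%s:%s", out$analysis,
    vapply(out$factors, paste, character(1), collapse = "+"),
    out$genotype_coding
  )
  out[c("spec_id", "analysis", "factors", "genotype_coding")]
}

#' Run the full multi-way test battery
#'
#' For every atlas region and every enumerated factor-combination spec,
#' tests whether the region's multimodal latent features differ across the
#' group cells, then applies Holm-Bonferroni familywise correction. The
#' cohort is restricted per analysis: `"A"` keeps control-diet subjects,
#' `"B"` keeps humanized-immunity subjects.
#'
#' Specs whose group cells are degenerate (< 2 subjects in a cell) are
#' skipped with a warning and recorded in the `skipped_specs` attribute —
#' they are neither significant nor insignificant, just untestable on this
#' cohort.
#'
#' @param concat Named list of per-subject `n x q` concatenated latent
#'   feature matrices (from [concat_modalities()]), canonical subject
#'   order.
#' @param cov Covariate tibble covering (at least) those subjects, with
#'   `age_bin` present (see [binarize_age()]).
#' @param analysis `"A"` (diet = CTRL cohort) or `"B"` (immunity = HN
#'   cohort).
#' @param alpha Familywise significance level (default 0.05).
#' @param codings Genotype codings passed to [enumerate_specs()].
#' @param atlas Optional atlas tibble; supplies the `hemisphere` column.
#' @param family Correction family: `"per_spec"` (default; all regions
#'   within one analysis x spec battery, matching per-panel reporting) or
#'   `"global"` (all regions x specs of the analysis at once).
#' @return A `scn_battery` tibble: one row per region x spec with columns
#'   `region_id`, `hemisphere`, `spec_id`, `analysis`, `factors`,
#'   `genotype_coding`, `n_subjects`, `n_groups`, `stat`, `dcorr`, `p`,
#'   `p_adj`, `reject`.
#' @export
run_battery <- function(concat, cov, analysis = c("A", "B"), alpha = 0.05,
                        codings = "three_level", atlas = NULL,
                        family = c("per_spec", "global")) {
  analysis <- match.arg(analysis)
  family <- match.arg(family)
  if (!"age_bin" %in% names(cov)) {
    cov <- binarize_age(cov)
  }
  cohort <- if (analysis == "A") {
    filter_cohort(cov, diet = "CTRL")
  } else {
    filter_cohort(cov, immunity = "HN")
  }
  cohort <- intersect(cohort, names(concat))
  if (length(cohort) < 4) {
    abort("analysis cohort has fewer than 4 subjects with features")
  }
  cov_c <- cov[match(cohort, cov$subject_id), ]
  feats <- concat[cohort]

  n <- nrow(feats[[1]])
  region_ids <- rownames(feats[[1]]) %||% sprintf("r%03d", seq_len(n))
  # per-region s x q feature stacks and distance matrices, shared across specs
  region_dx <- lapply(seq_len(n), function(r) {
    as.matrix(dist(t(vapply(feats, function(x) x[r, ], numeric(ncol(feats[[1]]))))))
  })

  specs <- enumerate_specs(analysis, codings = codings)
  skipped <- character(0)
  res <- purrr::pmap(specs, function(spec_id, analysis, factors, genotype_coding) {
    labels <- tryCatch(
      encode_groups(cov_c, factors, genotype_coding),
      error = function(e) e
    )
    if (inherits(labels, "error")) {
      skipped <<- c(skipped, spec_id)
      warn(paste0("skipping spec ", spec_id, ": ", conditionMessage(labels)))
      return(NULL)
    }
    dy <- as.matrix(dist(labels))
    stats_ <- purrr::map(region_dx, function(dx) {
      st <- dcorr_unbiased(dx, dy)
      deg <- isTRUE(attr(st, "degenerate"))
      c(stat = as.numeric(st),
        p = if (deg) 1 else chi2_pvalue(as.numeric(st), length(cohort)))
    })
    st <- vapply(stats_, `[[`, numeric(1), "stat")
    tibble::tibble(
      region_id = region_ids,
      spec_id = spec_id,
      analysis = analysis,
      factors = paste(factors, collapse = "+"),
      genotype_coding = genotype_coding,
      n_subjects = length(cohort),
      n_groups = ncol(labels),
      stat = st,
      dcorr = pmax(st, 0),
      p = vapply(stats_, `[[`, numeric(1), "p")
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    abort("all specs were degenerate on this cohort")
  }

  group_var <- if (family == "per_spec") "spec_id" else "analysis"
  out <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(group_var))),
    p_adj = holm_bonferroni(.data$p, alpha = alpha)$p_adj,
    reject = .data$p_adj <= alpha
  ))

  if (!is.null(atlas)) {
    out <- dplyr::left_join(out, atlas[c("region_id", "hemisphere")], by = "region_id")
  } else {
    out$hemisphere <- NA_character_
  }
  out <- out[c("region_id", "hemisphere", "spec_id", "analysis", "factors",
               "genotype_coding", "n_subjects", "n_groups", "stat", "dcorr",
               "p", "p_adj", "reject")]
  structure(out,
            class = c("scn_battery", class(tibble::tibble()))) |>
    set_battery_attrs(alpha = alpha, analysis = analysis, family = family,
                      skipped_specs = skipped)
}

set_battery_attrs <- function(x, alpha, analysis, family, skipped_specs) {
  attr(x, "alpha") <- alpha
  attr(x, "analysis") <- analysis
  attr(x, "family") <- family
  attr(x, "skipped_specs") <- skipped_specs
  x
}

#' Write battery results to TSV
#'
#' One row per region x spec, regions grouped by hemisphere (left first)
#' to match per-hemisphere reporting panels.
#'
#' @param results `scn_battery` tibble from [run_battery()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_battery <- function(results, path) {
  ord <- order(match(results$hemisphere, c("left", "right")),
               results$region_id, results$spec_id)
  readr::write_tsv(tibble::as_tibble(results)[ord, ], path)
  invisible(path)
}
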