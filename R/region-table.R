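#' Read a subjects-by-regions feature table
#'
#' Reads one modality's regional measurements (volume in mm^3 or regional
#' mean fractional anisotropy) from CSV. The file must have a `subject_id`
#' column plus one numeric column per atlas region. Subjects are
#' canonicalized to lexicographic `subject_id` order and regions to atlas
#' order, so that all downstream matrices share one indexing convention.
#'
#' @param path CSV path (UTF-8, comma-separated, header row).
#' @param atlas Atlas tibble from [read_atlas()] or [synthetic_atlas()].
#' @param modality `"volume"` or `"fa"`.
#' @return A tibble with `subject_id` plus one column per region, carrying a
#'   `modality` attribute.
#' @export
read_region_table <- function(path, atlas, modality = c("volume", "fa")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) {
    abort(paste0("feature table not found: ", path))
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_region_table(tbl, atlas, modality)
}

#' Validate and canonicalize a regional feature table
#'
#' @param tbl Data frame with `subject_id` plus region columns.
#' @inheritParams read_region_table
#' @return Validated tibble in canonical subject and region order.
#' @export
validate_region_table <- function(tbl, atlas, modality = c("volume", "fa")) {
  modality <- match.arg(modality)
  atlas <- validate_atlas(atlas)
  if (!"subject_id" %in% names(tbl)) {
    abort("feature table must have a 'subject_id' column")
  }
  if (anyDuplicated(tbl$subject_id)) {
    abort("duplicated subject_id in feature table")
  }
  regions <- setdiff(names(tbl), "subject_id")
  unknown <- setdiff(regions, atlas$region_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown region column(s) not in atlas: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  absent <- setdiff(atlas$region_id, regions)
  if (length(absent) > 0) {
    abort(paste0("feature table is missing atlas region(s): ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  tbl <- tbl[order(tbl$subject_id), c("subject_id", atlas$region_id)]
  vals <- as.matrix(tbl[atlas$region_id])
  if (anyNA(vals) || any(!is.finite(vals))) {
    idx <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)[1, ]
    abort(paste0("missing/non-finite value at subject ", tbl$subject_id[idx[1]],
                 ", region ", atlas$region_id[idx[2]]))
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(paste0("negative value at subject ", tbl$subject_id[idx[1]],
                 ", region ", atlas$region_id[idx[2]]))
  }
  out <- tibble::as_tibble(tbl)
  attr(out, "modality") <- modality
  out
}

#' Write a regional feature table to CSV
#'
#' Inverse of [read_region_table()]: writing a table read by the loader and
#' re-reading it reproduces the same tibble, and re-writing reproduces the
#' same bytes.
#'
#' @param tbl Feature tibble (canonical order).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

# Numeric matrix view (subjects x regions) of a feature tibble.
region_matrix <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "subject_id")])
  rownames(m) <- tbl$subject_id
  m
}
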