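#' Read a brain atlas region list
#'
#' The atlas is a three-column tab-separated file with header
#' `region_id`, `name`, `hemisphere`. The default mouse atlas used in this
#' line of work has 332 regions, 166 per hemisphere, but any
#' hemisphere-labelled region list is accepted.
#'
#' @param path Path to a TSV file with columns `region_id`, `name`,
#'   `hemisphere` (`left` or `right`).
#' @return A tibble with columns `region_id`, `name`, `hemisphere`.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("atlas file not found: ", path))
  }
  atlas <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_atlas(atlas)
}

#' Validate an atlas region table
#'
#' Checks the invariants every atlas must satisfy: the three required
#' columns, unique region identifiers, and hemisphere labels restricted to
#' `left`/`right`.
#'
#' @param atlas A data frame with columns `region_id`, `name`, `hemisphere`.
#' @return The atlas as a tibble, invisibly validated.
#' @export
validate_atlas <- function(atlas) {
  required <- c("region_id", "name", "hemisphere")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0) {
    abort(paste0("atlas is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(atlas$region_id)) {
    dup <- unique(atlas$region_id[duplicated(atlas$region_id)])
    abort(paste0("duplicated region_id in atlas: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad <- setdiff(unique(atlas$hemisphere), c("left", "right"))
  if (length(bad) > 0) {
    abort(paste0("hemisphere must be 'left' or 'right'; found: ", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(atlas[required])
}

#' Construct a synthetic hemisphere-balanced atlas
#'
#' Builds a region list with `n_regions / 2` regions per hemisphere, named
#' `L_001 ... / R_001 ...`. Used by the cohort simulator and anywhere a
#' stand-in for the real segmentation atlas is needed.
#'
#' @param n_regions Even number of regions (default 332, as in the
#'   symmetrized mouse brain atlas).
#' @return A tibble with columns `region_id`, `name`, `hemisphere`.
#' @export
synthetic_atlas <- function(n_regions = 332) {
  if (n_regions < 2 || n_regions %% 2 != 0) {
    abort("n_regions must be a positive even number (hemisphere-balanced)")
  }
  half <- n_regions / 2
  ids <- sprintf("%s_%03d", rep(c("L", "R"), each = half), rep(seq_len(half), 2))
  tibble::tibble(
    region_id = ids,
    name = sprintf("region %03d (%s)", rep(seq_len(half), 2),
                   rep(c("left", "right"), each = half)),
    hemisphere = rep(c("left", "right"), each = half)
  )
}

#' Write an atlas region list to TSV
#'
#' @param atlas Atlas tibble (see [read_atlas()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  atlas <- validate_atlas(atlas)
  readr::write_tsv(atlas, path)
  invisible(path)
}
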