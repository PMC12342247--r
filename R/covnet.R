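#' Normalize regional features to the unit interval
#'
#' Regional volumes are divided by each subject's total brain volume (the
#' sum of its atlas regional volumes), so each subject's row sums to 1;
#' regional FA is divided by each subject's maximum regional FA, so each
#' row's maximum is 1. Either way every value lands in [0, 1] and each
#' subject's network becomes invariant to its own global scale.
#'
#' @param tbl Feature tibble from [read_region_table()] (or any tibble with
#'   `subject_id` plus numeric region columns carrying a `modality`
#'   attribute).
#' @param modality `"volume"` or `"fa"`; defaults to the tibble's attribute.
#' @return Normalized feature tibble of the same shape.
#' @export
normalize_features <- function(tbl, modality = NULL) {
  modality <- modality %||% attr(tbl, "modality")
  if (is.null(modality) || !modality %in% c("volume", "fa")) {
    abort("modality must be 'volume' or 'fa'")
  }
  vals <- region_matrix(tbl)
  denom <- if (modality == "volume") rowSums(vals) else apply(vals, 1, max)
  if (any(denom <= 0)) {
    abort(paste0("zero ", if (modality == "volume") "total volume" else "maximum FA",
                 " for subject ", tbl$subject_id[which(denom <= 0)[1]]))
  }
  out <- tbl
  out[setdiff(names(tbl), "subject_id")] <- vals / denom
  attr(out, "modality") <- modality
  out
}

#' Build one subject's distance network
#'
#' The individualized structural covariance network: entry (i, j) is the
#' absolute difference |x_i - x_j| between the subject's normalized features
#' at regions i and j. The result is symmetric, hollow (zero diagonal) and
#' [0, 1]-valued, i.e. an undirected weighted loopless network on the atlas
#' regions.
#'
#' @param x Numeric vector of one subject's normalized features, values in
#'   [0, 1]; names (region ids) are propagated to the dimnames.
#' @return An n x n numeric matrix.
#' @export
distance_network <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("features must be finite and in [0, 1]; normalize first")
  }
  m <- abs(outer(x, x, "-"))
  diag(m) <- 0
  dimnames(m) <- list(names(x), names(x))
  m
}

#' Build the distance networks for every subject
#'
#' @param tbl Normalized feature tibble (see [normalize_features()]).
#' @return Named list of n x n matrices, one per subject, in canonical
#'   subject order.
#' @export
build_networks <- function(tbl) {
  vals <- region_matrix(tbl)
  nets <- lapply(seq_len(nrow(vals)), function(i) distance_network(vals[i, ]))
  names(nets) <- tbl$subject_id
  nets
}

#' Average network over a group of subjects
#'
#' Element-wise mean of the selected subjects' distance networks, e.g. the
#' per-genotype mean matrices shown when visualizing group structure.
#'
#' @param nets Named list of networks from [build_networks()].
#' @param subjects Subject IDs to average over; default all.
#' @return An n x n matrix (still symmetric, hollow, [0, 1]).
#' @export
group_mean_network <- function(nets, subjects = names(nets)) {
  if (length(subjects) == 0) {
    abort("empty subject set")
  }
  absent <- setdiff(subjects, names(nets))
  if (length(absent) > 0) {
    abort(paste0("no network for subject(s): ", paste(head(absent, 5), collapse = ", ")))
  }
  Reduce(`+`, nets[subjects]) / length(subjects)
}

#' Contrast two group-mean networks
#'
#' Element-wise difference `mean_a - mean_b`, e.g. between genotype means;
#' antisymmetric under swapping the groups.
#'
#' @param mean_a,mean_b Same-shape matrices from [group_mean_network()].
#' @return Matrix of element-wise differences.
#' @export
network_contrast <- function(mean_a, mean_b) {
  if (!identical(dim(mean_a), dim(mean_b))) {
    abort("network shapes differ")
  }
  mean_a - mean_b
}

#' Write a network matrix to TSV
#'
#' Square matrix with region ids as header row and first column; numbers
#' are written with full double precision so a read round-trips exactly.
#'
#' @param m Square matrix with region-id dimnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(region_id = rownames(m)), df)
  df <- dplyr::mutate(df, dplyr::across(-1, \(x) sprintf("%.17g", x)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a network matrix from TSV
#'
#' @param path TSV written by [write_network()].
#' @return Square numeric matrix with region-id dimnames.
#' @export
read_network <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  # base strtod parsing is correctly rounded, preserving exact doubles
  m <- apply(as.matrix(df[-1]), 2, as.numeric)
  rownames(m) <- df$region_id
  m
}
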