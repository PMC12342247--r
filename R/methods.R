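#' @export
print.scn_battery <- function(x, ...) {
  # subsetting via dplyr verbs can drop the battery columns; fall back then
  if (!all(c("region_id", "spec_id", "reject") %in% names(x))) {
    return(NextMethod())
  }
  cat(sprintf("# Vulnerable-region test battery (analysis %s, alpha = %g, %s family)\n",
              attr(x, "analysis") %||% "?", attr(x, "alpha") %||% NA,
              attr(x, "family") %||% "per_spec"))
  cat(sprintf("# %d regions x %d specs; %d rejections\n",
              dplyr::n_distinct(x$region_id), dplyr::n_distinct(x$spec_id),
              sum(x$reject)))
  skipped <- attr(x, "skipped_specs")
  if (length(skipped) > 0) {
    cat(sprintf("# skipped (degenerate) specs: %s\n", paste(skipped, collapse = ", ")))
  }
  NextMethod()
}

#' Tidy a test-battery result
#'
#' Returns the battery as a plain tibble, one row per region x factor
#' combination, with the distance-correlation effect size, raw and
#' Holm-adjusted p-values and the rejection flag.
#'
#' @param x `scn_battery` from [run_battery()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.scn_battery <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a test-battery result
#'
#' @param x `scn_battery` from [run_battery()].
#' @param ... Unused.
#' @return Tibble with one row: analysis, counts of regions, specs and
#'   tests, rejections, vulnerable regions (regions with at least one
#'   rejection), and the alpha level.
#' @export
glance.scn_battery <- function(x, ...) {
  tibble::tibble(
    analysis = attr(x, "analysis") %||% NA_character_,
    n_regions = dplyr::n_distinct(x$region_id),
    n_specs = dplyr::n_distinct(x$spec_id),
    n_tests = nrow(x),
    n_reject = sum(x$reject),
    n_vulnerable_regions = dplyr::n_distinct(x$region_id[x$reject]),
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' Plot a test battery as a region-by-factor significance map
#'
#' Mirrors the per-hemisphere panels used to report these batteries: tiles
#' are regions (rows) by factor combinations (columns), filled by
#' -log10 adjusted p, with an X marking Holm-significant cells. Regions
#' with no significant test can be dropped for readability.
#'
#' @param object `scn_battery` from [run_battery()].
#' @param drop_null_regions Drop regions with no rejection (default
#'   `TRUE`, as in the reporting figures).
#' @param ... Unused.
#' @return A ggplot object (faceted by hemisphere when available).
#' @export
autoplot.scn_battery <- function(object, drop_null_regions = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (drop_null_regions && any(df$reject)) {
    keep <- unique(df$region_id[df$reject])
    df <- df[df$region_id %in% keep, ]
  }
  df$label <- sprintf("%s\n[%s]", df$factors, df$genotype_coding)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$region_id,
                                        fill = -log10(pmax(.data$p_adj, 1e-16)))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$reject, , drop = FALSE],
                        shape = 4, size = 2, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p[adj])) +
    ggplot2::labs(x = "factor combination", y = "region",
                  title = sprintf("Analysis %s: vulnerable regions (X = Holm-significant)",
                                  attr(object, "analysis") %||% "")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!all(is.na(df$hemisphere))) {
    p <- p + ggplot2::facet_wrap(~hemisphere, scales = "free_y")
  }
  p
}

#' Heatmap of a network or contrast matrix
#'
#' Quick visualization of a per-subject network, a group-mean network or a
#' genotype contrast (diverging palette centred at zero for contrasts).
#'
#' @param m Square matrix with region dimnames.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_network_heatmap <- function(m, title = NULL) {
  df <- tidyr::expand_grid(row = rownames(m) %||% as.character(seq_len(nrow(m))),
                           col = colnames(m) %||% as.character(seq_len(ncol(m))))
  df$value <- as.vector(t(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
  if (min(m) < 0) {
    p + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b")
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}
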