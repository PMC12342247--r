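#' Holm-Bonferroni familywise error control
#'
#' Step-down Holm adjustment: p-values are sorted ascending, the k-th is
#' multiplied by (m - k + 1), the running maximum is taken and capped at 1,
#' and hypotheses are rejected while the adjusted value stays at or below
#' `alpha`. The adjusted values are returned in the original input order.
#' The adjustment itself is delegated to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param alpha Familywise significance level (default 0.05).
#' @return Tibble with columns `p`, `p_adj`, `reject`, aligned with the
#'   input.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0) {
    return(tibble::tibble(p = numeric(0), p_adj = numeric(0), reject = logical(0)))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be in [0, 1] with no missing values")
  }
  p_adj <- p.adjust(p, method = "holm")
  tibble::tibble(p = p, p_adj = p_adj, reject = p_adj <= alpha)
}
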