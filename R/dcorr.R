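# U-centering of a distance matrix (unbiased/"U-statistic" centering):
# off-diagonal (i,j) entry becomes
#   D_ij - R_i/(s-2) - C_j/(s-2) + T/((s-1)(s-2)),
# diagonal forced to zero. The resulting inner products give unbiased
# estimates of distance covariance.
u_center <- function(d) {
  s <- nrow(d)
  r <- rowSums(d)
  c_ <- colSums(d)
  t_ <- sum(d)
  u <- d - outer(r, rep(1, s)) / (s - 2) - outer(rep(1, s), c_) / (s - 2) +
    t_ / ((s - 1) * (s - 2))
  diag(u) <- 0
  u
}

# Unbiased inner product of two U-centered matrices.
u_inner <- function(a, b) {
  s <- nrow(a)
  sum(a * b) / (s * (s - 3))
}

#' Unbiased distance correlation between two distance matrices
#'
#' Computes the unbiased (U-centered) sample distance correlation from two
#' precomputed pairwise distance matrices. The statistic equals 1 when the
#' two matrices are identical with distinct points, may be slightly
#' negative under independence, and is bounded by 1 in absolute value. It
#' serves both as the test statistic and as the reported effect size.
#'
#' If either sample has zero distance variance (all points coincident) the
#' statistic is degenerate: 0 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param dx,dy Symmetric, hollow, non-negative `s x s` distance matrices
#'   over the same s >= 4 observations.
#' @return The unbiased distance correlation (scalar), possibly with a
#'   `degenerate` attribute.
#' @export
dcorr_unbiased <- function(dx, dy) {
  s <- nrow(dx)
  if (!is.matrix(dx) || !is.matrix(dy) || nrow(dy) != s || ncol(dx) != s ||
      ncol(dy) != s) {
    abort("dx and dy must be square matrices of the same size")
  }
  if (s < 4) {
    abort("unbiased distance correlation needs at least 4 observations")
  }
  ux <- u_center(dx)
  uy <- u_center(dy)
  vx <- u_inner(ux, ux)
  vy <- u_inner(uy, uy)
  if (vx <= 0 || vy <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  u_inner(ux, uy) / sqrt(vx * vy)
}

#' Fast chi-squared p-value for the unbiased distance correlation
#'
#' The null distribution of `s * dcorr` is approximated by a centered
#' chi-squared: `s * dcorr + 1` is referred to the upper tail of a
#' chi-squared distribution with 1 degree of freedom. This replaces the
#' permutation null at a tiny fraction of the cost and is
#' conservative-to-nominal, which matters when hundreds of region x factor
#' tests are run. The result is clipped to [0, 1] and is monotonically
#' decreasing in the statistic.
#'
#' @param stat Unbiased distance correlation.
#' @param s Number of observations the statistic was computed from (>= 4).
#' @return p-value in [0, 1].
#' @export
chi2_pvalue <- function(stat, s) {
  if (any(s < 4)) {
    abort("s must be >= 4")
  }
  p <- pchisq(s * stat + 1, df = 1, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Permutation p-value for the distance-correlation group test
#'
#' The permutation oracle: group labels are permuted uniformly at random
#' and the unbiased distance correlation recomputed for each permutation;
#' the p-value is `(1 + #{permuted stat >= observed}) / (1 + n_perm)`.
#' Exact exchangeability makes this the reference against which the fast
#' chi-squared approximation is validated.
#'
#' Because U-centering commutes with simultaneous row/column permutation,
#' each permuted statistic is an inner product of the fixed U-centered
#' feature matrix with a permuted U-centered label matrix, so the loop
#' costs O(s^2) per permutation.
#'
#' @param features `s x q` numeric matrix of per-observation features.
#' @param labels One-hot `s x K` group membership matrix (see
#'   [encode_groups()]).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return p-value in (0, 1], with attribute `stat` (the observed
#'   statistic).
#' @export
permutation_pvalue <- function(features, labels, n_perm = 1000, seed = 1) {
  if (n_perm < 99) {
    abort("n_perm must be at least 99")
  }
  s <- nrow(features)
  dx <- as.matrix(dist(features))
  dy <- as.matrix(dist(labels))
  ux <- u_center(dx)
  uy <- u_center(dy)
  vx <- u_inner(ux, ux)
  vy <- u_inner(uy, uy)
  if (vx <= 0 || vy <= 0) {
    return(structure(1, stat = 0, degenerate = TRUE))
  }
  denom <- sqrt(vx * vy)
  observed <- u_inner(ux, uy) / denom
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(s)
    perm_stat <- u_inner(ux, uy[p, p]) / denom
    if (perm_stat >= observed) {
      count <- count + 1L
    }
  }
  structure((1 + count) / (1 + n_perm), stat = observed)
}
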