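#' Adjacency spectral embedding
#'
#' Embeds a symmetric matrix as `U |S|^{1/2}`, where `S` holds the top-d
#' eigenvalues by magnitude (in decreasing order of |eigenvalue|) and `U`
#' the corresponding orthonormal eigenvectors. Negative eigenvalues are kept
#' and enter through their absolute value. For reproducibility each
#' eigenvector's sign is fixed so that its largest-magnitude entry is
#' positive; every downstream statistic is invariant to this choice.
#'
#' @param m Symmetric numeric matrix.
#' @param d Embedding dimension, `1 <= d <= nrow(m)`.
#' @return An `n x d` matrix of estimated latent positions, with attribute
#'   `eigenvalues` (the signed eigenvalues used, in |value|-descending
#'   order).
#' @export
ase <- function(m, d) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-10)) {
    abort("ase() needs a symmetric square matrix")
  }
  if (d < 1 || d > nrow(m)) {
    abort("d must satisfy 1 <= d <= nrow(m)")
  }
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(d)]
  vecs <- fix_eigenvector_signs(e$vectors[, ord, drop = FALSE])
  vals <- e$values[ord]
  x <- vecs %*% diag(sqrt(abs(vals)), d)
  dimnames(x) <- list(rownames(m), paste0("dim_", seq_len(d)))
  attr(x, "eigenvalues") <- vals
  x
}

# Flip eigenvector columns so the largest-magnitude entry of each is positive.
fix_eigenvector_signs <- function(v) {
  sgn <- apply(v, 2, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  sweep(v, 2, sgn, `*`)
}

#' Construct the omnibus matrix of a network collection
#'
#' For m networks on the same n vertices, the omnibus matrix is the
#' `mn x mn` symmetric matrix whose (l, l) diagonal block is network l and
#' whose (l, k) off-diagonal block is the average `(A(l) + A(k)) / 2`.
#' Spectral embedding of this single matrix yields per-network latent
#' positions that live in one common coordinate system, so they can be
#' compared directly across subjects.
#'
#' `mode = "dense"` materializes the matrix; `mode = "implicit"` returns an
#' operator exposing matrix-vector products (see [omnibus_matvec()]) without
#' ever forming the `mn x mn` matrix, which is essential at full-cohort
#' scale (hundreds of subjects, several hundred regions).
#'
#' @param nets Named list of same-dimension symmetric matrices.
#' @param mode `"dense"` or `"implicit"`.
#' @return Dense: an `mn x mn` matrix. Implicit: an object of class
#'   `omnibus_operator`.
#' @export
build_omnibus <- function(nets, mode = c("dense", "implicit")) {
  mode <- match.arg(mode)
  m <- length(nets)
  if (m < 1) {
    abort("need at least one network")
  }
  n <- nrow(nets[[1]])
  ok <- vapply(nets, function(a) is.matrix(a) && all(dim(a) == n), logical(1))
  if (!all(ok)) {
    abort("all networks must be square matrices of the same dimension")
  }
  if (mode == "dense") {
    o <- matrix(0, m * n, m * n)
    for (l in seq_len(m)) {
      for (k in seq_len(m)) {
        o[(l - 1) * n + seq_len(n), (k - 1) * n + seq_len(n)] <-
          (nets[[l]] + nets[[k]]) / 2
      }
    }
    return(o)
  }
  # Block l of O v collapses to (A_l S + T) / 2 with S = sum_k v_k and
  # T = sum_k A_k v_k, so one horizontal and one vertical stack of the
  # networks give the whole product in two BLAS calls.
  structure(
    list(
      m = m, n = n,
      hstack = do.call(cbind, nets),   # n x (n m): [A_1 | ... | A_m]
      vstack = do.call(rbind, nets)    # (n m) x n: [A_1; ...; A_m]
    ),
    class = "omnibus_operator"
  )
}

#' Omnibus operator matrix-vector product
#'
#' Computes `O v` for the implicit omnibus operator, identical (to
#' floating-point roundoff) to multiplying by the dense omnibus matrix.
#'
#' @param op An `omnibus_operator` from [build_omnibus()].
#' @param v Numeric vector of length `m * n`.
#' @return Numeric vector `O v`.
#' @export
omnibus_matvec <- function(op, v) {
  if (!inherits(op, "omnibus_operator")) {
    abort("op must be an omnibus_operator")
  }
  if (length(v) != op$m * op$n) {
    abort("v has the wrong length")
  }
  vmat <- matrix(v, nrow = op$n, ncol = op$m)
  s <- rowSums(vmat)
  t_sum <- as.vector(op$hstack %*% v)           # sum_k A_k v_k
  blocks <- matrix(as.vector(op$vstack %*% s), nrow = op$n) # stacked A_l S
  as.vector((blocks + t_sum) / 2)
}

#' @export
print.omnibus_operator <- function(x, ...) {
  cat(sprintf("<omnibus operator: %d networks x %d regions (%d x %d implicit)>\n",
              x$m, x$n, x$m * x$n, x$m * x$n))
  invisible(x)
}

#' Select embedding dimension by profile log-likelihood elbows
#'
#' Implements the profile log-likelihood change-point criterion of
#' Zhu and Ghodsi on a scree of eigenvalue magnitudes: every split point q
#' divides the (descending) spectrum into two groups modelled as Gaussians
#' with a common variance, and the q maximizing the profile log-likelihood
#' is an elbow. Successive elbows are found by recursing on the tail beyond
#' the previous elbow. For omnibus spectra the second elbow is the default
#' choice of latent dimension: the first elbow routinely isolates only the
#' dominant (Perron-type) eigenvalue.
#'
#' @param spectrum Non-negative eigenvalue magnitudes, sorted descending.
#' @param n_elbows Which elbow to return (default 2).
#' @return The selected dimension (1-based count into the spectrum).
#' @export
select_dimension <- function(spectrum, n_elbows = 2) {
  if (length(spectrum) == 0) {
    abort("empty spectrum")
  }
  if (any(spectrum < 0) || is.unsorted(rev(spectrum))) {
    abort("spectrum must be non-negative and sorted in decreasing order")
  }
  if (n_elbows < 1) {
    abort("n_elbows must be >= 1")
  }
  offset <- 0L
  x <- spectrum
  elbow <- NULL
  for (i in seq_len(n_elbows)) {
    if (length(x) == 0) {
      warn(sprintf("only %d elbow(s) available; returning the last one", i - 1L))
      break
    }
    q <- zhu_ghodsi_elbow(x)
    elbow <- offset + q
    offset <- elbow
    x <- if (q < length(x)) x[(q + 1):length(x)] else numeric(0)
  }
  elbow
}

# Single Zhu-Ghodsi elbow: argmax over split points of the two-group
# common-variance Gaussian profile log-likelihood.
zhu_ghodsi_elbow <- function(x) {
  p <- length(x)
  if (p == 1) {
    return(1L)
  }
  lik <- vapply(seq_len(p), function(q) {
    head_x <- x[seq_len(q)]
    tail_x <- if (q < p) x[(q + 1):p] else numeric(0)
    ss <- sum((head_x - mean(head_x))^2)
    if (length(tail_x) > 0) {
      ss <- ss + sum((tail_x - mean(tail_x))^2)
    }
    sigma2 <- max(ss / p, .Machine$double.xmin)
    -p / 2 * log(2 * pi * sigma2) - ss / (2 * sigma2)
  }, numeric(1))
  which.max(lik)
}

#' Jointly embed one modality's networks with the omnibus embedding
#'
#' Builds the omnibus matrix of all subjects' networks, selects the latent
#' dimension from its scree (second profile-log-likelihood elbow by
#' default) unless `d` is given, embeds with [ase()] semantics, and slices
#' the `mn x d` result into m consecutive `n x d` per-subject blocks in
#' subject order. Because all blocks come from one joint decomposition they
#' share a coordinate system and are directly comparable.
#'
#' @param nets Named list of at least two same-dimension networks (one per
#'   subject, canonical order).
#' @param d Latent dimension; `NULL` (default) selects it automatically.
#' @param n_elbows Elbow used for automatic selection (default 2).
#' @param mode `"auto"` (dense when `m * n <= dense_limit`, implicit
#'   otherwise), `"dense"`, or `"implicit"`.
#' @param dense_limit Largest `m * n` for which the dense path is used under
#'   `mode = "auto"`.
#' @param n_spectrum Number of leading eigenvalue magnitudes fed to elbow
#'   selection; default `min(n, 100)` (elbows are local features of the
#'   leading spectrum and the deep tail is noise).
#' @return Named list of `n x d` latent position matrices, one per subject,
#'   with attributes `d` and `spectrum` (leading eigenvalue magnitudes).
#' @export
omni_embed <- function(nets, d = NULL, n_elbows = 2,
                       mode = c("auto", "dense", "implicit"),
                       dense_limit = 2000, n_spectrum = NULL) {
  mode <- match.arg(mode)
  m <- length(nets)
  if (m < 2) {
    abort("omnibus embedding needs at least two networks")
  }
  n <- nrow(nets[[1]])
  mn <- m * n
  if (mode == "auto") {
    mode <- if (mn <= dense_limit) "dense" else "implicit"
  }
  n_spectrum <- n_spectrum %||% min(n, 100)
  k <- min(max(n_spectrum, d %||% 1L), mn)

  if (mode == "dense") {
    o <- build_omnibus(nets, mode = "dense")
    e <- eigen(o, symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)
    vals <- e$values[ord[seq_len(k)]]
    vecs <- e$vectors[, ord[seq_len(k)], drop = FALSE]
  } else {
    op <- build_omnibus(nets, mode = "implicit")
    k <- min(k, mn - 2)  # ARPACK needs nev < n - 1
    res <- igraph::arpack(
      function(x, extra) omnibus_matvec(op, x),
      sym = TRUE,
      options = list(n = mn, nev = k, ncv = min(mn, max(2 * k + 1, 20)),
                     which = "LM", maxiter = 5000)
    )
    ord <- order(abs(res$values), decreasing = TRUE)
    vals <- res$values[ord]
    vecs <- res$vectors[, ord, drop = FALSE]
  }
  spectrum <- abs(vals)

  if (is.null(d)) {
    d <- select_dimension(head(spectrum, n_spectrum), n_elbows = n_elbows)
  }
  if (d > k) {
    abort("requested dimension exceeds the computed spectrum")
  }
  vecs <- fix_eigenvector_signs(vecs[, seq_len(d), drop = FALSE])
  z <- vecs %*% diag(sqrt(spectrum[seq_len(d)]), d)

  region_ids <- rownames(nets[[1]]) %||% sprintf("r%03d", seq_len(n))
  out <- lapply(seq_len(m), function(l) {
    b <- z[(l - 1) * n + seq_len(n), , drop = FALSE]
    dimnames(b) <- list(region_ids, paste0("dim_", seq_len(d)))
    b
  })
  names(out) <- names(nets)
  attr(out, "d") <- d
  attr(out, "spectrum") <- head(spectrum, n_spectrum)
  out
}

#' Concatenate per-modality latent positions
#'
#' Horizontally concatenates each subject's volume-network latent positions
#' with its FA-network latent positions, giving one `n x (d_vol + d_fa)`
#' feature matrix per subject (6 columns when both modalities embed in 3
#' dimensions). Region r's row is the multimodal latent feature vector used
#' by the test battery.
#'
#' @param vol,fa Named lists of per-subject latent position matrices from
#'   [omni_embed()], same subjects in the same order, same regions.
#' @return Named list of `n x (d_vol + d_fa)` matrices with columns
#'   labelled `vol_*` then `fa_*`.
#' @export
concat_modalities <- function(vol, fa) {
  if (!identical(names(vol), names(fa))) {
    abort("volume and FA embeddings must cover the same subjects in the same order")
  }
  out <- purrr::map2(vol, fa, function(v, f) {
    if (nrow(v) != nrow(f)) {
      abort("region counts differ between modalities")
    }
    colnames(v) <- if (ncol(v)) paste0("vol_", seq_len(ncol(v))) else character(0)
    colnames(f) <- if (ncol(f)) paste0("fa_", seq_len(ncol(f))) else character(0)
    cbind(v, f)
  })
  attr(out, "d_vol") <- ncol(vol[[1]])
  attr(out, "d_fa") <- ncol(fa[[1]])
  out
}

#' Write latent positions to long-format TSV
#'
#' One row per subject x region with columns `subject_id`, `region_id`,
#' `dim_1..dim_k`, `modality`. Values use full double precision, so
#' [read_embeddings()] reproduces the matrices exactly.
#'
#' @param embeds Named list of per-subject position matrices.
#' @param modality Label stored in the `modality` column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeds, modality, path) {
  rows <- purrr::imap(embeds, function(x, sid) {
    df <- tibble::as_tibble(x, .name_repair = "minimal")
    names(df) <- paste0("dim_", seq_len(ncol(x)))
    dplyr::bind_cols(
      tibble::tibble(subject_id = sid, region_id = rownames(x)),
      dplyr::mutate(df, dplyr::across(dplyr::everything(), \(v) sprintf("%.17g", v)))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$modality <- modality
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read latent positions written by [write_embeddings()]
#'
#' @param path TSV path.
#' @return Named list of per-subject position matrices (column names
#'   restored as `dim_*`).
#' @export
read_embeddings <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  dims <- grep("^dim_", names(df), value = TRUE)
  # base strtod parsing is correctly rounded, preserving exact doubles
  df[dims] <- lapply(df[dims], as.numeric)
  split_df <- split(df, factor(df$subject_id, levels = unique(df$subject_id)))
  out <- lapply(split_df, function(s) {
    m <- as.matrix(s[dims])
    rownames(m) <- s$region_id
    m
  })
  out
}
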