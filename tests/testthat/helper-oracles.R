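# Independent brute-force oracles used to validate the fast implementations.
# These are written as literal loops over the defining formulas and share no
# code with the package internals.

# U-centering by explicit double loop.
oracle_u_center <- function(d) {
  s <- nrow(d)
  u <- matrix(0, s, s)
  total <- sum(d)
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      if (i != j) {
        u[i, j] <- d[i, j] - sum(d[i, ]) / (s - 2) - sum(d[, j]) / (s - 2) +
          total / ((s - 1) * (s - 2))
      }
    }
  }
  u
}

oracle_dcorr <- function(dx, dy) {
  s <- nrow(dx)
  ux <- oracle_u_center(dx)
  uy <- oracle_u_center(dy)
  inner <- function(a, b) {
    acc <- 0
    for (i in seq_len(s)) for (j in seq_len(s)) acc <- acc + a[i, j] * b[i, j]
    acc / (s * (s - 3))
  }
  inner(ux, uy) / sqrt(inner(ux, ux) * inner(uy, uy))
}

# Holm step-down by the textbook definition: sort ascending, multiply the
# k-th by (m - k + 1), running max, cap at 1, restore input order.
oracle_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    running <- max(running, min(1, (m - k + 1) * p[o[k]]))
    adj_sorted[k] <- running
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  list(p_adj = adj, reject = adj <= alpha)
}

# Exhaustive profile log-likelihood evaluation for a single scree elbow.
oracle_profile_elbow <- function(x) {
  p <- length(x)
  if (p == 1) return(1L)
  best_q <- 1L
  best <- -Inf
  for (q in seq_len(p)) {
    g1 <- x[1:q]
    g2 <- if (q < p) x[(q + 1):p] else numeric(0)
    ss <- sum((g1 - mean(g1))^2)
    if (length(g2) > 0) ss <- ss + sum((g2 - mean(g2))^2)
    s2 <- max(ss / p, 1e-300)
    ll <- sum(dnorm(g1, mean(g1), sqrt(s2), log = TRUE))
    if (length(g2) > 0) ll <- ll + sum(dnorm(g2, mean(g2), sqrt(s2), log = TRUE))
    if (ll > best) {
      best <- ll
      best_q <- q
    }
  }
  best_q
}

# Orthogonal Procrustes residual: min over orthogonal W of ||A W - B||_F.
procrustes_resid <- function(a, b) {
  sv <- svd(crossprod(a, b))
  w <- sv$u %*% t(sv$v)
  sqrt(sum((a %*% w - b)^2))
}

# Small fixture builders -----------------------------------------------------

tiny_atlas <- function(n = 4) {
  synthetic_atlas(n)
}

tiny_cov <- function(n = 8) {
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    genotype = rep(c("APOE2", "APOE3"), length.out = n),
    sex = rep(c("F", "M"), each = ceiling(n / 2))[seq_len(n)],
    age_months = seq(12, 18, length.out = n),
    diet = "CTRL",
    immunity = rep(c("HN", "mNos2"), length.out = n)
  )
}

random_network <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n)
  names(x) <- sprintf("r%03d", seq_len(n))
  distance_network(x)
}
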