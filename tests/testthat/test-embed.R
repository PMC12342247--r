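test_that("adjacency spectral embedding matches hand and Procrustes oracles", {
  # rank-1 matrix with eigenvalue 0.5 and eigenvector (1, 1)/sqrt(2)
  x <- ase(matrix(0.25, 2, 2), d = 1)
  expect_equal(abs(as.vector(x)), c(0.5, 0.5), tolerance = 1e-12)

  expect_equal(unname(ase(matrix(0, 3, 3), d = 2)), matrix(0, 3, 2),
               ignore_attr = TRUE)

  set.seed(21)
  lat <- matrix(runif(30 * 3, 0.1, 0.55), 30, 3)
  p <- tcrossprod(lat)
  xh <- ase(p, d = 3)
  expect_lt(procrustes_resid(xh, lat), 1e-8 * sqrt(sum(lat^2)))

  expect_error(ase(matrix(1:6, 2, 3), 1), "symmetric")
  asym <- matrix(runif(9), 3, 3)
  expect_error(ase(asym, 1), "symmetric")
  expect_error(ase(p, 31), "1 <= d")
})

test_that("ase recovery improves monotonically as network noise vanishes", {
  sigmas <- c(0.2, 0.1, 0.05, 0)
  set.seed(31)
  lat <- matrix(runif(30 * 3, 0.1, 0.55), 30, 3)
  p <- tcrossprod(lat)
  mean_resid <- sapply(sigmas, function(s) {
    mean(sapply(1:50, function(i) {
      e <- matrix(rnorm(900, sd = s), 30, 30)
      procrustes_resid(ase(p + (e + t(e)) / 2, d = 3), lat)
    }))
  })
  expect_true(all(diff(mean_resid) < 0))
  expect_lt(mean_resid[4], 1e-8)
})

test_that("the omnibus matrix satisfies its block structure", {
  a <- random_network(5, seed = 1)
  b <- random_network(5, seed = 2)
  expect_equal(build_omnibus(list(s1 = a), "dense"), a, ignore_attr = TRUE)

  o2 <- build_omnibus(list(s1 = a, s2 = a), "dense")
  expect_equal(o2, rbind(cbind(a, a), cbind(a, a)), ignore_attr = TRUE)

  o <- build_omnibus(list(s1 = a, s2 = b), "dense")
  expect_equal(o[1:5, 6:10], (a + b) / 2, ignore_attr = TRUE)
  expect_equal(o[6:10, 1:5], (a + b) / 2, ignore_attr = TRUE)
  expect_equal(o[1:5, 1:5], a, ignore_attr = TRUE)
  expect_identical(max(abs(o - t(o))), 0)

  expect_error(build_omnibus(list(a, matrix(0, 3, 3))), "same dimension")
})

test_that("implicit operator products equal dense omnibus products", {
  nets <- lapply(1:6, function(i) random_network(12, seed = 40 + i))
  names(nets) <- sprintf("S%02d", 1:6)
  o <- build_omnibus(nets, "dense")
  op <- build_omnibus(nets, "implicit")
  set.seed(3)
  for (i in 1:5) {
    v <- rnorm(72)
    expect_lt(max(abs(o %*% v - omnibus_matvec(op, v))), 1e-12)
  }
})

test_that("profile log-likelihood elbow selection matches the exhaustive oracle", {
  spectrum <- c(10, 9.8, 9.5, 1.2, 1.1, 1.0, 0.9)
  expect_equal(select_dimension(spectrum, n_elbows = 1), 3)
  expect_equal(oracle_profile_elbow(spectrum), 3)

  expect_equal(select_dimension(5, n_elbows = 1), 1)
  expect_error(select_dimension(numeric(0)), "empty")
  expect_warning(d <- select_dimension(c(3, 1), n_elbows = 5), "elbow")

  set.seed(17)
  for (i in 1:25) {
    sp <- sort(rexp(sample(3:30, 1), rate = 0.3), decreasing = TRUE)
    expect_equal(select_dimension(sp, n_elbows = 1), oracle_profile_elbow(sp))
  }
  # successive elbows recurse beyond the previous one
  e1 <- select_dimension(spectrum, 1)
  e2 <- select_dimension(spectrum, 2)
  expect_gt(e2, e1)
  expect_equal(e2, e1 + oracle_profile_elbow(spectrum[(e1 + 1):length(spectrum)]))
})

test_that("omnibus embedding of identical networks yields identical blocks recovering X", {
  set.seed(51)
  lat <- matrix(runif(25 * 3, 0.1, 0.55), 25, 3)
  p <- tcrossprod(lat)
  dimnames(p) <- list(sprintf("r%02d", 1:25), sprintf("r%02d", 1:25))
  nets <- list(s1 = p, s2 = p, s3 = p, s4 = p)
  emb <- omni_embed(nets, d = 3, mode = "dense")
  for (l in 2:4) {
    expect_lt(sqrt(sum((emb[[1]] - emb[[l]])^2)), 1e-8)
  }
  expect_lt(procrustes_resid(emb[[1]], lat), 1e-6 * sqrt(sum(lat^2)))
})

test_that("planted between-group differences separate embedded blocks", {
  set.seed(61)
  lat_a <- matrix(runif(20 * 2, 0.1, 0.6), 20, 2)
  lat_b <- lat_a
  lat_b[1:6, ] <- lat_b[1:6, ] + 0.25
  pa <- pmin(tcrossprod(lat_a), 1)
  pb <- pmin(tcrossprod(lat_b), 1)
  nets <- c(lapply(1:4, function(i) pa), lapply(1:4, function(i) pb))
  names(nets) <- sprintf("S%02d", 1:8)
  emb <- omni_embed(nets, d = 2, mode = "dense")
  dmat <- as.matrix(dist(t(sapply(emb, as.vector))))
  within <- c(dmat[1:4, 1:4][upper.tri(diag(4))], dmat[5:8, 5:8][upper.tri(diag(4))])
  between <- as.vector(dmat[1:4, 5:8])
  expect_gt(min(between), max(within))
})

test_that("permuting subject order permutes embedding blocks identically", {
  nets <- lapply(1:5, function(i) random_network(10, seed = 70 + i))
  names(nets) <- sprintf("S%02d", 1:5)
  emb <- omni_embed(nets, d = 3, mode = "dense")
  perm <- c(4, 1, 5, 2, 3)
  emb_p <- omni_embed(nets[perm], d = 3, mode = "dense")
  for (s in names(nets)) {
    expect_lt(max(abs(emb[[s]] - emb_p[[s]])), 1e-8)
  }
})

test_that("implicit and dense embeddings agree after sign alignment", {
  for (seed in 1:3) {
    m <- sample(4:8, 1)
    nets <- lapply(seq_len(m), function(i) random_network(30, seed = 90 * seed + i))
    names(nets) <- sprintf("S%02d", seq_len(m))
    ed <- omni_embed(nets, d = 3, mode = "dense")
    ei <- omni_embed(nets, d = 3, mode = "implicit")
    err <- max(mapply(function(a, b) {
      # per-column sign alignment: the fixed-sign convention should already
      # match, but alignment keeps the check about the subspace
      sgn <- sign(colSums(a * b))
      max(abs(sweep(a, 2, sgn, `*`) - b))
    }, ed, ei))
    expect_lt(err, 1e-8)
  }
})

test_that("modal concatenation lays volume before FA and handles empty blocks", {
  v <- list(S1 = matrix(1:6, 3, 2), S2 = matrix(7:12, 3, 2))
  f <- list(S1 = matrix(13:21, 3, 3), S2 = matrix(22:30, 3, 3))
  cc <- concat_modalities(v, f)
  expect_equal(ncol(cc$S1), 5)
  expect_equal(unname(cc$S1[, 1:2]), unname(v$S1))
  expect_equal(unname(cc$S1[, 3:5]), unname(f$S1))

  f0 <- list(S1 = matrix(numeric(0), 3, 0), S2 = matrix(numeric(0), 3, 0))
  cc0 <- concat_modalities(v, f0)
  expect_equal(unname(cc0$S1), unname(v$S1))

  expect_error(concat_modalities(v, f[c(2, 1)]), "same subjects")
})

test_that("embedding TSV export round-trips exactly", {
  nets <- lapply(1:4, function(i) random_network(8, seed = 200 + i))
  names(nets) <- sprintf("S%02d", 1:4)
  emb <- omni_embed(nets, d = 2, mode = "dense")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(emb, "volume", f)
  back <- read_embeddings(f)
  expect_identical(lapply(emb, unclass)[names(back)],
                   lapply(back, function(m) m))
})
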