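test_that("group encoding crosses factors, drops empty cells, recodes genotype", {
  cov <- tibble::tibble(
    subject_id = sprintf("S%d", 1:3),
    genotype = "APOE2", sex = c("F", "F", "M"),
    age_months = 12, diet = "CTRL", immunity = "HN"
  )
  oh <- encode_groups(dplyr::bind_rows(cov, cov), "sex")  # duplicate for >=2 per cell
  expect_equal(dim(oh), c(6, 2))
  expect_equal(unname(oh[, "F"]), c(1, 1, 0, 1, 1, 0))

  # one empty cell among the 2 x 2 cross leaves 3 columns
  cov4 <- tibble::tibble(
    subject_id = sprintf("S%d", 1:8),
    genotype = "APOE2",
    sex = c("F", "F", "F", "F", "M", "M", "M", "M"),
    age_months = 12, diet = "CTRL",
    immunity = c("HN", "HN", "mNos2", "mNos2", "HN", "HN", "HN", "HN")
  )
  oh4 <- encode_groups(cov4, c("sex", "immunity"))
  expect_equal(ncol(oh4), 3)

  covg <- tibble::tibble(
    subject_id = sprintf("S%d", 1:8),
    genotype = rep(c("APOE2", "APOE3", "APOE4", "APOE2"), 2),
    sex = "F", age_months = 12, diet = "CTRL", immunity = "HN"
  )
  ohg <- encode_groups(covg, "genotype", genotype_coding = "APOE2_vs_rest")
  expect_equal(ncol(ohg), 2)
  expect_equal(unname(ohg[, "APOE2"]), as.numeric(covg$genotype == "APOE2"))

  cov_deg <- covg[1:5, ]
  expect_error(encode_groups(cov_deg, c("genotype", "sex")), "< 2 subjects")
})

test_that("unbiased distance correlation matches the U-centering loop oracle", {
  d <- as.matrix(dist(1:4))
  expect_equal(as.numeric(dcorr_unbiased(d, d)), 1)

  const <- matrix(0, 5, 5)
  stat <- dcorr_unbiased(as.matrix(dist(rnorm(5))), const)
  expect_equal(as.numeric(stat), 0)
  expect_true(attr(stat, "degenerate"))

  set.seed(101)
  for (i in 1:5) {
    x <- matrix(rnorm(20 * 3), 20, 3)
    y <- matrix(rnorm(20 * 2), 20, 2)
    dx <- as.matrix(dist(x))
    dy <- as.matrix(dist(y))
    expect_equal(as.numeric(dcorr_unbiased(dx, dy)), oracle_dcorr(dx, dy),
                 tolerance = 1e-12)
  }
  expect_error(dcorr_unbiased(as.matrix(dist(1:3)), as.matrix(dist(1:3))),
               "at least 4")
})

test_that("chi-squared p-values follow the centered chi-square null", {
  expect_equal(chi2_pvalue(0, 30), pchisq(1, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(chi2_pvalue(2, 30), 1e-10)  # s * stat + 1 = 61, deep tail
  stats <- seq(-0.02, 0.5, by = 0.01)
  p <- chi2_pvalue(stats, 30)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(chi2_pvalue(0.1, 3), ">= 4")
})

test_that("permutation p-values are deterministic, degenerate-safe and uniform under the null", {
  set.seed(5)
  feats <- matrix(rnorm(20 * 4), 20, 4)
  one_group <- matrix(1, 20, 1)
  expect_equal(as.numeric(permutation_pvalue(feats, one_group, 200, seed = 1)), 1)

  labels <- matrix(0, 20, 2)
  labels[cbind(1:20, rep(1:2, 10))] <- 1
  p1 <- permutation_pvalue(feats, labels, 500, seed = 42)
  p2 <- permutation_pvalue(feats, labels, 500, seed = 42)
  expect_identical(p1, p2)

  # empirical rejection rate at alpha = 0.05 across null replicates
  set.seed(900)
  rej <- replicate(500, {
    f <- matrix(rnorm(30 * 2), 30, 2)
    l <- matrix(0, 30, 2)
    l[cbind(1:30, rep(1:2, 15))] <- 1
    permutation_pvalue(f, l, n_perm = 999, seed = sample.int(1e6, 1)) <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("region tests detect planted shifts and are rotation invariant", {
  cov <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:30),
    genotype = "APOE2", sex = rep(c("F", "M"), each = 15),
    age_months = 12, diet = "CTRL", immunity = "HN"
  )
  same <- matrix(1, 30, 6)
  res0 <- region_test(same, cov, "sex")
  expect_true(res0$degenerate)
  expect_equal(res0$p, 1)
  expect_equal(res0$stat, 0)

  set.seed(77)
  feats <- matrix(rnorm(30 * 6), 30, 6)
  feats[1:15, 1] <- feats[1:15, 1] + 5  # five pooled-SD mean shift
  res <- region_test(feats, cov, "sex")
  expect_lt(res$p, 0.001)
  labels <- encode_groups(cov, "sex")
  p_perm <- permutation_pvalue(feats, labels, n_perm = 2000, seed = 3)
  expect_lt(p_perm, 0.005)

  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  res_rot <- region_test(feats %*% q, cov, "sex")
  expect_equal(res_rot$stat, res$stat, tolerance = 1e-9)
  expect_equal(res_rot$p, res$p, tolerance = 1e-9)
})

test_that("spec enumeration emits every non-empty factor subset once per coding rule", {
  specs_a <- enumerate_specs("A")
  expect_equal(nrow(specs_a), 15)  # 2^4 - 1 subsets, three-level genotype only
  expect_true(all(vapply(specs_a$factors, function(f)
    !"diet" %in% f, logical(1))))

  specs_b <- enumerate_specs("B")
  expect_equal(nrow(specs_b), 15)
  expect_true(all(vapply(specs_b$factors, function(f)
    !"immunity" %in% f, logical(1))))

  # one-vs-rest codings only multiply the genotype-containing subsets
  all_cod <- c("three_level", "APOE2_vs_rest", "APOE3_vs_rest", "APOE4_vs_rest")
  specs_full <- enumerate_specs("A", codings = all_cod)
  n_geno <- sum(vapply(specs_full$factors, function(f) "genotype" %in% f, logical(1)))
  expect_equal(nrow(specs_full), 7 + 8 * 4)  # 7 genotype-free + 8 subsets x 4 codings
  expect_equal(n_geno, 32)
  expect_false(anyDuplicated(specs_full$spec_id) > 0)

  expect_error(enumerate_specs("A", codings = "APOE5_vs_rest"), "unknown genotype coding")
})

test_that("the battery tests every region against every feasible spec", {
  co <- simulate_cohort(synth_config(seed = 8, n_regions = 12))
  ev <- omni_embed(build_networks(normalize_features(co$volume)), d = 3,
                   mode = "implicit")
  ef <- omni_embed(build_networks(normalize_features(co$fa)), d = 3,
                   mode = "implicit")
  cc <- concat_modalities(ev, ef)
  cov <- binarize_age(co$covariates)
  bat <- suppressWarnings(run_battery(cc, cov, analysis = "A", atlas = co$atlas))
  n_specs_run <- dplyr::n_distinct(bat$spec_id)
  expect_equal(nrow(bat), 12 * n_specs_run)
  expect_equal(n_specs_run + length(attr(bat, "skipped_specs")), 15)
  expect_true(all(bat$p <= bat$p_adj | abs(bat$p - bat$p_adj) < 1e-15))
  expect_true(all(bat$p_adj <= 1))
  expect_true(all(bat$p_adj[bat$reject] <= attr(bat, "alpha")))
  expect_true(all(bat$hemisphere %in% c("left", "right")))
  # analysis A keeps only the control-diet cohort
  expect_equal(unique(bat$n_subjects),
               length(filter_cohort(cov, diet = "CTRL")))
  g <- glance(bat)
  expect_equal(g$n_tests, nrow(bat))
  expect_s3_class(tidy(bat), "tbl_df")
})
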