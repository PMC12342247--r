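#' Configuration for a synthetic mouse cohort
#'
#' Describes a factorial cohort emulating the ApoE study design: three
#' genotypes crossed with sex, diet and immunity, with the high-fat-diet x
#' mouse-Nos2 cells empty by default (those combinations are unsupported in
#' the real design, which is what forces the two-analysis split). Regional
#' volumes are log-normal around per-region baselines; regional FA is
#' clipped Gaussian inside (0, 1); planted "vulnerable region" effects add
#' shifts on the log-volume and/or FA scale for subjects matching a factor
#' level.
#'
#' Defaults give a 96-subject cohort over 40 hemisphere-balanced regions:
#' 6 subjects in each of the 12 control-diet cells and 4 in each of the 6
#' HFD x HN cells.
#'
#' @param seed Integer seed; all randomness derives from it through named
#'   substreams (covariates / volume / fa), so adding one modality never
#'   perturbs another's draws.
#' @param n_regions Even region count (default 40).
#' @param cell_counts Tibble with columns `genotype`, `sex`, `diet`,
#'   `immunity`, `n`; default as described above.
#' @param effects Tibble with columns `region_id`, `factor`, `level`,
#'   `delta_vol` (log-volume shift), `delta_fa` (FA shift); empty by
#'   default. Factors may be `genotype`, `sex`, `diet`, `immunity`
#'   (planting on binarized age is not supported: the bin is derived from
#'   the generated ages).
#' @param mu_log_volume Per-region baseline log-volumes (length
#'   `n_regions`); the default is a fixed hemisphere-symmetric profile of
#'   log-volumes spanning 0.6-2.5 mm^3, mirroring a symmetrized atlas in
#'   which region sizes are fixed anatomy, not cohort randomness.
#' @param baseline_fa Per-region baseline FA in (0, 1); default a fixed
#'   hemisphere-symmetric profile spanning 0.15-0.50.
#' @param sigma_v Log-volume noise sd (default 0.1).
#' @param sigma_f FA noise sd (default 0.02).
#' @param age_range Age range in months, sampled uniformly (default
#'   c(12, 20)).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1, n_regions = 40, cell_counts = NULL,
                         effects = NULL, mu_log_volume = NULL,
                         baseline_fa = NULL, sigma_v = 0.1, sigma_f = 0.02,
                         age_range = c(12, 20)) {
  if (n_regions < 2 || n_regions %% 2 != 0) {
    abort("n_regions must be a positive even number")
  }
  if (is.null(cell_counts)) {
    cell_counts <- default_cell_counts()
  }
  required <- c("genotype", "sex", "diet", "immunity", "n")
  if (!all(required %in% names(cell_counts))) {
    abort("cell_counts needs columns genotype, sex, diet, immunity, n")
  }
  if (any(cell_counts$n < 0) || any(cell_counts$n != round(cell_counts$n))) {
    abort("cell counts must be non-negative integers")
  }
  effects <- effects %||% tibble::tibble(
    region_id = character(0), factor = character(0), level = character(0),
    delta_vol = numeric(0), delta_fa = numeric(0)
  )
  if (any(!effects$factor %in% c("genotype", "sex", "diet", "immunity"))) {
    abort("effects may target genotype, sex, diet or immunity only")
  }
  atlas <- synthetic_atlas(n_regions)
  half <- n_regions / 2
  if (is.null(mu_log_volume)) {
    # same profile in both hemispheres, as in a symmetrized atlas
    mu_log_volume <- rep(log(seq(0.6, 2.5, length.out = half)), 2)
  }
  if (is.null(baseline_fa)) {
    baseline_fa <- rep(seq(0.15, 0.50, length.out = half), 2)
  }
  stopifnot(length(mu_log_volume) == n_regions, length(baseline_fa) == n_regions)
  if (any(baseline_fa <= 0 | baseline_fa >= 1)) {
    abort("baseline_fa must lie strictly inside (0, 1)")
  }
  structure(
    list(seed = seed, n_regions = n_regions, atlas = atlas,
         cell_counts = tibble::as_tibble(cell_counts),
         effects = tibble::as_tibble(effects),
         mu_log_volume = mu_log_volume, baseline_fa = baseline_fa,
         sigma_v = sigma_v, sigma_f = sigma_f, age_range = age_range),
    class = "synth_config"
  )
}

# Balanced supported-design default: 12 control-diet cells x 6 subjects and
# 6 HFD x HN cells x 4 subjects (HFD x mNos2 left empty) = 96 subjects.
default_cell_counts <- function() {
  lv <- scn_factor_levels()
  grid <- tidyr::expand_grid(
    genotype = lv$genotype, sex = lv$sex, diet = lv$diet, immunity = lv$immunity
  )
  dplyr::mutate(grid, n = dplyr::case_when(
    diet == "CTRL" ~ 6L,
    diet == "HFD" & immunity == "HN" ~ 4L,
    TRUE ~ 0L
  ))
}

# Deterministic named substream: a distinct 31-bit seed per (seed, name).
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483647)
}

#' Generate a synthetic cohort with planted vulnerable regions
#'
#' Draws covariates, regional volumes and regional FA under the generative
#' model of [synth_config()]:
#' volume `V(s, r) = exp(mu_r + sum of matching delta_vol + eps)` with
#' `eps ~ N(0, sigma_v^2)`; FA
#' `clip(phi_r + sum of matching delta_fa + eps', 0.01, 0.99)` with
#' `eps' ~ N(0, sigma_f^2)`; ages Uniform over `age_range`. Everything is
#' deterministic given the config seed.
#'
#' @param cfg A `synth_config`.
#' @return List with elements `volume` and `fa` (feature tibbles in the
#'   exact format [read_region_table()] consumes), `covariates` (tibble),
#'   `truth` (the planted-effect table: the ground-truth vulnerable
#'   regions), and `atlas`.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "synth_config")) {
    abort("cfg must come from synth_config()")
  }
  counts <- cfg$cell_counts[cfg$cell_counts$n > 0, ]
  n_sub <- sum(counts$n)
  if (n_sub == 0) {
    abort("cohort is empty: all cell counts are zero")
  }
  cov <- tidyr::uncount(counts, weights = .data$n)
  cov$subject_id <- sprintf("S%04d", seq_len(n_sub))
  set.seed(substream_seed(cfg$seed, "covariates"))
  cov$age_months <- round(runif(n_sub, cfg$age_range[1], cfg$age_range[2]), 2)
  cov <- validate_covariates(
    cov[c("subject_id", "genotype", "sex", "age_months", "diet", "immunity")]
  )

  n_r <- cfg$n_regions
  region_ids <- cfg$atlas$region_id

  shift <- function(which_delta) {
    m <- matrix(0, n_sub, n_r, dimnames = list(cov$subject_id, region_ids))
    for (i in seq_len(nrow(cfg$effects))) {
      ef <- cfg$effects[i, ]
      hit <- cov[[ef$factor]] == ef$level
      m[hit, ef$region_id] <- m[hit, ef$region_id] + ef[[which_delta]]
    }
    m
  }

  set.seed(substream_seed(cfg$seed, "volume"))
  eps_v <- matrix(rnorm(n_sub * n_r, sd = cfg$sigma_v), n_sub, n_r)
  vol <- exp(matrix(cfg$mu_log_volume, n_sub, n_r, byrow = TRUE) +
               shift("delta_vol") + eps_v)

  set.seed(substream_seed(cfg$seed, "fa"))
  eps_f <- matrix(rnorm(n_sub * n_r, sd = cfg$sigma_f), n_sub, n_r)
  fa <- pmin(pmax(matrix(cfg$baseline_fa, n_sub, n_r, byrow = TRUE) +
                    shift("delta_fa") + eps_f, 0.01), 0.99)

  as_feature_tbl <- function(vals, modality) {
    tbl <- tibble::as_tibble(vals, .name_repair = "minimal")
    names(tbl) <- region_ids
    tbl <- dplyr::bind_cols(tibble::tibble(subject_id = cov$subject_id), tbl)
    validate_region_table(tbl, cfg$atlas, modality)
  }

  list(
    volume = as_feature_tbl(vol, "volume"),
    fa = as_feature_tbl(fa, "fa"),
    covariates = cov,
    truth = cfg$effects,
    atlas = cfg$atlas
  )
}

#' Sample a binary random dot product graph
#'
#' Given latent positions `X`, edges are independent Bernoulli draws with
#' `P = X X^T` (upper triangle sampled, mirrored, hollow diagonal). Used
#' for unit-level validation of the spectral machinery.
#'
#' @param x `n x d` latent position matrix with all entries of `x x^T` in
#'   [0, 1].
#' @param seed Optional integer seed.
#' @return Symmetric hollow binary `n x n` adjacency matrix.
#' @export
sample_rdpg <- function(x, seed = NULL) {
  p <- tcrossprod(x)
  off <- p[row(p) != col(p)]
  if (any(off < -1e-12) || any(off > 1 + 1e-12)) {
    abort("X X^T must have all off-diagonal entries in [0, 1]")
  }
  p <- pmin(pmax(p, 0), 1)
  n <- nrow(p)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  a <- matrix(0, n, n)
  upper <- upper.tri(p)
  a[upper] <- rbinom(sum(upper), 1, p[upper])
  a <- a + t(a)
  if (!is.null(rownames(x))) {
    dimnames(a) <- list(rownames(x), rownames(x))
  }
  a
}
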