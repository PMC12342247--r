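#' Assemble a pipeline configuration
#'
#' Collects file paths and modelling options for [run_pipeline()]. Input
#' files are checked for existence up front so a misconfigured run fails
#' before any computation.
#'
#' @param volume,fa Feature CSV paths (see [read_region_table()]).
#' @param covariates Covariate CSV path.
#' @param atlas Atlas TSV path.
#' @param output_dir Directory for result TSVs and the run manifest
#'   (created if needed).
#' @param analysis `"A"`, `"B"` or `"both"`.
#' @param n_elbows Elbow used for automatic dimension selection.
#' @param d Optional fixed embedding dimension (applied to both
#'   modalities); `NULL` selects automatically.
#' @param mode Omnibus mode: `"auto"`, `"dense"` or `"implicit"`.
#' @param codings Genotype codings for the battery.
#' @param alpha Familywise level.
#' @param family Correction family (`"per_spec"` or `"global"`).
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed namespaces any future stochastic stage).
#' @param export_group_matrices If `TRUE`, per-genotype mean networks and
#'   their pairwise contrasts are written as TSV.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(volume, fa, covariates, atlas, output_dir,
                            analysis = c("both", "A", "B"), n_elbows = 2,
                            d = NULL, mode = "auto", codings = "three_level",
                            alpha = 0.05, family = "per_spec", seed = 1,
                            export_group_matrices = FALSE) {
  analysis <- match.arg(analysis)
  paths <- c(volume = volume, fa = fa, covariates = covariates, atlas = atlas)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ",
                 paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", ")))
  }
  structure(
    list(volume = volume, fa = fa, covariates = covariates, atlas = atlas,
         output_dir = output_dir, analysis = analysis, n_elbows = n_elbows,
         d = d, mode = mode, codings = codings, alpha = alpha, family = family,
         seed = seed, export_group_matrices = export_group_matrices),
    class = "pipeline_config"
  )
}

#' Run the full vulnerable-region detection pipeline
#'
#' Executes load -> normalize -> per-subject networks -> omnibus embedding
#' per modality -> multimodal concatenation -> test battery -> Holm
#' correction, writing one results TSV per analysis plus a JSON manifest
#' (config hash, seed, package and R versions). Any stage failure aborts
#' with the stage name.
#'
#' @param cfg A `pipeline_config`.
#' @param verbose Print stage progress (default `TRUE`).
#' @return Invisibly, a list with the battery tibbles (per analysis), the
#'   concatenated features, and the output file paths.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  if (!inherits(cfg, "pipeline_config")) {
    abort("cfg must come from pipeline_config()")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  say("[load] reading atlas, features, covariates")
  atlas <- stage("load", read_atlas(cfg$atlas))
  vol <- stage("load", read_region_table(cfg$volume, atlas, "volume"))
  fa <- stage("load", read_region_table(cfg$fa, atlas, "fa"))
  cov <- stage("load", binarize_age(read_covariates(cfg$covariates)))
  if (!setequal(cov$subject_id, vol$subject_id) ||
      !setequal(cov$subject_id, fa$subject_id)) {
    abort("pipeline stage 'load' failed: subjects differ across inputs")
  }

  say("[networks] building %d x 2 distance networks", nrow(vol))
  nets_vol <- stage("networks", build_networks(normalize_features(vol)))
  nets_fa <- stage("networks", build_networks(normalize_features(fa)))

  if (cfg$export_group_matrices) {
    say("[networks] exporting per-genotype mean and contrast matrices")
    export_group_matrices(nets_vol, nets_fa, cov, cfg$output_dir)
  }

  say("[embed] omnibus embedding per modality (mode = %s)", cfg$mode)
  emb_vol <- stage("embed", omni_embed(nets_vol, d = cfg$d,
                                       n_elbows = cfg$n_elbows, mode = cfg$mode))
  emb_fa <- stage("embed", omni_embed(nets_fa, d = cfg$d,
                                      n_elbows = cfg$n_elbows, mode = cfg$mode))
  say("[embed] selected d: volume = %d, fa = %d",
      attr(emb_vol, "d"), attr(emb_fa, "d"))
  concat <- stage("embed", concat_modalities(emb_vol, emb_fa))

  analyses <- if (cfg$analysis == "both") c("A", "B") else cfg$analysis
  results <- list()
  result_paths <- character(0)
  for (an in analyses) {
    say("[test] analysis %s battery", an)
    bat <- stage("test", run_battery(concat, cov, analysis = an,
                                     alpha = cfg$alpha, codings = cfg$codings,
                                     atlas = atlas, family = cfg$family))
    path <- file.path(cfg$output_dir, sprintf("results_analysis_%s.tsv", an))
    write_battery(bat, path)
    results[[an]] <- bat
    result_paths <- c(result_paths, path)
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "output_dir")],
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "output_dir")]),
    seed = cfg$seed,
    d_volume = attr(emb_vol, "d"),
    d_fa = attr(emb_fa, "d"),
    n_subjects = nrow(vol),
    n_regions = nrow(atlas),
    package_version = as.character(utils::packageVersion("scnvuln")),
    r_version = R.version.string
  )
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  say("[done] results: %s", paste(result_paths, collapse = ", "))
  invisible(list(results = results, concat = concat,
                 embeddings = list(volume = emb_vol, fa = emb_fa),
                 paths = c(result_paths, manifest_path)))
}

export_group_matrices <- function(nets_vol, nets_fa, cov, output_dir) {
  lv <- scn_factor_levels()
  for (mod in c("volume", "fa")) {
    nets <- if (mod == "volume") nets_vol else nets_fa
    means <- lapply(lv$genotype, function(g) {
      group_mean_network(nets, cov$subject_id[cov$genotype == g])
    })
    names(means) <- lv$genotype
    for (g in lv$genotype) {
      write_network(means[[g]],
                    file.path(output_dir, sprintf("mean_%s_%s.tsv", mod, g)))
    }
    pairs <- combn(lv$genotype, 2, simplify = FALSE)
    for (pr in pairs) {
      write_network(
        network_contrast(means[[pr[1]]], means[[pr[2]]]),
        file.path(output_dir, sprintf("contrast_%s_%s_vs_%s.tsv", mod, pr[1], pr[2]))
      )
    }
  }
}
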