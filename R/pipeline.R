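#' Pipeline run configuration
#'
#' Collects the input paths and stage parameters of a full run:
#' mapping -> per-pathway autoencoder scoring -> consensus sNMF
#' bi-clustering with rank selection -> Shapley interpretation ->
#' post-hoc statistics. Defaults follow the reference protocol
#' (hyper-opt budget 50, 5 folds, 500 consensus runs, 40 permutations,
#' ranks 2..9, beta grid in `[0.001, 1]`); `profile = "fast"` switches to
#' the reduced desk-scale profile used for testing (budget 10, 50 runs,
#' 10 permutations, ranks 2..5).
#'
#' @param input_dir Directory holding `<modality>.tsv` omics tables,
#'   `pathways.gmt`, optional `map_<modality>.tsv` annotation files, and
#'   optional `mutations.tsv` / `clinical.tsv`.
#' @param out_dir Output directory for results, cache and manifest.
#' @param modalities Modalities to load (default: every `<mod>.tsv`).
#' @param profile `"reference"` or `"fast"`.
#' @param seed Master seed.
#' @param ... Overrides for individual parameters (`budget`, `folds`,
#'   `runs`, `n_perm`, `ranks`, `beta_grid`, `max_epochs`,
#'   `min_features_per_modality`, `shap_samples`, `shap_top_pathways`).
#' @return A `run_config` object.
#' @export
run_config <- function(input_dir, out_dir, modalities = NULL,
                       profile = c("reference", "fast"), seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "reference") {
    list(budget = 50L, folds = 5L, runs = 500L, n_perm = 40L, ranks = 2:9,
         beta_grid = c(0.001, 0.01, 0.1, 1), max_epochs = 500L)
  } else {
    list(budget = 10L, folds = 5L, runs = 50L, n_perm = 10L, ranks = 2:5,
         beta_grid = 0.01, max_epochs = 150L)
  }
  cfg <- utils::modifyList(
    c(base, list(
      input_dir = input_dir, out_dir = out_dir, modalities = modalities,
      profile = profile, seed = as.integer(seed),
      min_features_per_modality = 1L, shap_samples = 50L,
      shap_top_pathways = 2L
    )),
    list(...)
  )
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Every field of [run_config()] can be set from a YAML file; `input_dir`
#' and `out_dir` are required keys.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_input("the yaml package is required to read YAML configs")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$input_dir) || is.null(y$out_dir)) {
    stop_input("config must define input_dir and out_dir")
  }
  args <- y[setdiff(names(y), c("input_dir", "out_dir"))]
  do.call(run_config, c(list(input_dir = y$input_dir, out_dir = y$out_dir), args))
}

# content-addressed stage cache: recompute only when the key changes
stage_cached <- function(out_dir, stage, key, compute, verbose = TRUE) {
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(key)
  path <- file.path(cache_dir, sprintf("%s-%s.rds", stage, hash))
  if (file.exists(path)) {
    if (verbose) message(sprintf("[%s] cache hit (%s)", stage, substr(hash, 1, 8)))
    return(readRDS(path))
  }
  if (verbose) message(sprintf("[%s] computing ...", stage))
  value <- tryCatch(compute(), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "pathembed_stage_error")
  })
  saveRDS(value, path)
  value
}

file_hashes <- function(paths) {
  paths <- paths[file.exists(paths)]
  setNames(as.vector(tools::md5sum(paths)), basename(paths))
}

#' Run the full pathway-embedding pipeline
#'
#' Executes mapping, per-pathway autoencoder tuning/training/scoring,
#' rank-selected consensus sNMF bi-clustering, Shapley interpretation of
#' the cluster-descriptive pathways, and post-hoc statistics, with every
#' stage cached on disk by a content hash of its inputs and parameters:
#' re-running with identical inputs and config performs no recomputation,
#' and corrupting an input invalidates exactly the downstream stages.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return A `results_bundle`: views, models (glance table), `scores`
#'   (`pathway_scores`), `rank_selection`, `consensus`
#'   (`consensus_result`), `attributions`, `stats`, and the manifest.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  inputs <- read_fixture(config$input_dir, config$modalities)
  in_hash <- file_hashes(list.files(config$input_dir, full.names = TRUE))
  in_hash <- in_hash[names(in_hash) != "truth_labels.tsv"]  # leakage guard
  par <- unclass(config)[c("budget", "folds", "runs", "n_perm", "ranks",
                           "beta_grid", "max_epochs",
                           "min_features_per_modality", "seed")]

  views <- stage_cached(out, "map", list(in_hash, par$min_features_per_modality),
                        function() {
    build_pathway_views(inputs$blocks, inputs$gene_sets, inputs$maps,
                        config$min_features_per_modality)
  }, verbose)

  score_key <- list(in_hash, par[c("budget", "folds", "max_epochs",
                                   "min_features_per_modality", "seed")])
  scored <- stage_cached(out, "score", score_key, function() {
    models <- list()
    for (i in seq_along(views)) {
      pw <- names(views)[i]
      tuned <- tune_pathway_autoencoder(
        views[[pw]], budget = config$budget, folds = config$folds,
        seed = config$seed + i, max_epochs = config$max_epochs
      )
      fit <- train_pathway_autoencoder(views[[pw]], tuned$hidden, tuned$config)
      fit$cv_errors <- tuned$cv_error
      models[[pw]] <- fit
      if (verbose) {
        message(sprintf(
          "[score] %s: cv_error=%.4f epochs=%d lambda=%.2e alpha=%.2f opt=%s",
          pw, tuned$cv_error, fit$epochs, tuned$config$lambda,
          tuned$config$alpha, tuned$config$optimizer
        ))
      }
    }
    list(models = models, scores = assemble_score_matrix(models, views))
  }, verbose)
  write_score_matrix(scored$scores, file.path(out, "scores.tsv"))

  cluster_key <- list(in_hash, par)
  clustered <- stage_cached(out, "cluster", cluster_key, function() {
    rs <- select_rank(
      scored$scores$scores, ranks = config$ranks,
      beta_grid = config$beta_grid, runs = config$runs,
      n_perm = config$n_perm, seed = config$seed
    )
    m_star <- if (rs$resolved) rs$selected else {
      warn("rank selection unresolved; falling back to the cophenetic maximum")
      rs$summary$rank[which.max(rs$summary$real_cophenetic)]
    }
    beta_star <- rs$summary$best_beta[rs$summary$rank == m_star]
    cons <- consensus_cluster(
      scored$scores$scores, m_star, beta = beta_star,
      runs = config$runs, seed = config$seed
    )
    list(rank_selection = rs, consensus = cons)
  }, verbose)
  cons <- clustered$consensus
  readr::write_tsv(tidy(cons), file.path(out, "labels.tsv"), progress = FALSE)
  utils::write.table(cons$consensus, file.path(out, "consensus_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(
    clustered$rank_selection$summary, file.path(out, "rank_selection.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )

  explain_key <- list(in_hash, par, config$shap_samples, config$shap_top_pathways)
  attributions <- stage_cached(out, "explain", explain_key, function() {
    res <- list()
    for (comp in seq_len(cons$m)) {
      top <- utils::head(
        descriptive_features(cons$best_fit$B, comp), config$shap_top_pathways
      )
      for (pw in setdiff(top, names(res))) {
        res[[pw]] <- attribute_pathway(
          scored$models[[pw]], views[[pw]],
          n_samples = config$shap_samples, seed = config$seed
        )
      }
    }
    res
  }, verbose)
  if (length(attributions)) {
    readr::write_tsv(dplyr::bind_rows(lapply(attributions, tidy)),
                     file.path(out, "attributions.tsv"), progress = FALSE)
  }

  stats <- stage_cached(out, "stats", cluster_key, function() {
    res <- list()
    if (!is.null(inputs$mutations)) {
      res$mutational_burden <- mutational_burden_test(
        inputs$mutations, inputs$gene_sets, cons$labels
      )
    }
    if (!is.null(inputs$clinical)) {
      eps <- sub("_time$", "", grep("_time$", names(inputs$clinical), value = TRUE))
      res$survival <- dplyr::bind_rows(lapply(eps, function(e) {
        survival_association(cons$labels, inputs$clinical, e)
      }))
      res$clinical <- clinical_associations(cons$labels, inputs$clinical)
    }
    res
  }, verbose)
  for (nm in names(stats)) {
    readr::write_tsv(stats[[nm]], file.path(out, paste0("stats_", nm, ".tsv")),
                     progress = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pathembed")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    profile = config$profile,
    parameters = par,
    input_hashes = as.list(in_hash),
    selected_rank = cons$m
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(
    list(
      views = views, models = scored$models, scores = scored$scores,
      rank_selection = clustered$rank_selection, consensus = cons,
      attributions = attributions, stats = stats, manifest = manifest,
      config = config
    ),
    class = "results_bundle"
  )
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf(
    "<results_bundle> %d pathways, %d patients -> %d clusters (cophenetic %.3f)\n",
    length(x$views), length(x$consensus$labels), x$consensus$m,
    x$consensus$cophenetic
  ))
  invisible(x)
}
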