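#' Configuration of the synthetic multi-omics study generator
#'
#' Describes a cohort with planted patient clusters expressed through
#' cluster-specific pathway activity across several omics modalities, plus
#' matching somatic-mutation and clinical tables. Defaults emulate a
#' desk-scale multi-omics cohort: n = 150 patients in 3 balanced clusters,
#' 20 pathways of which 5 are cluster-driving, and three modalities with
#' heterogeneous numeric ranges (log-expression-like, miRNA-like, and a
#' methylation-like modality squashed to `[0, 1]`).
#'
#' @param n Number of patients.
#' @param m_true Number of planted clusters.
#' @param proportions Cluster mixing proportions (must sum to 1).
#' @param P Number of pathways.
#' @param n_informative Number of cluster-driving pathways (`<= P`).
#' @param genes_per_pathway Genes per pathway.
#' @param features Named integer vector: features per pathway for the
#'   `mrna`, `mirna`, `meth` modalities.
#' @param noise_sd Named numeric vector of per-modality noise standard
#'   deviations (on the latent scale for `meth`).
#' @param location Named numeric vector of per-modality baseline means.
#' @param effect_size Cluster-mean shift of driver features, in units of
#'   the modality noise sd (adjacent planted clusters are separated by
#'   `effect_size * noise_sd`).
#' @param driver_fraction Fraction of each informative pathway's features
#'   (per modality) that carry the cluster signal.
#' @param hazard_ratios Per-cluster hazard ratios for the survival
#'   endpoints (length `m_true`).
#' @param censoring_fraction Target overall censoring fraction.
#' @param mutation_rate Baseline per-gene somatic mutation probability.
#' @param mutation_odds Odds ratio of mutation enrichment in the
#'   designated (cluster, pathway) pairs: cluster c is enriched in the
#'   c-th informative pathway.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n = 150L, m_true = 3L,
                             proportions = rep(1 / m_true, m_true),
                             P = 20L, n_informative = 5L,
                             genes_per_pathway = 30L,
                             features = c(mrna = 30L, mirna = 15L, meth = 30L),
                             noise_sd = c(mrna = 2, mirna = 1, meth = 1),
                             location = c(mrna = 8, mirna = 4, meth = 0),
                             effect_size = 4, driver_fraction = 0.5,
                             hazard_ratios = seq(1, 3, length.out = m_true),
                             censoring_fraction = 0.3,
                             mutation_rate = 0.05, mutation_odds = 8,
                             seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-8) stop_input("proportions must sum to 1")
  if (length(proportions) != m_true) stop_input("proportions must have m_true entries")
  if (effect_size < 0) stop_input("effect_size must be >= 0")
  if (n_informative > P) stop_input("n_informative must be <= P")
  if (driver_fraction <= 0 || driver_fraction > 1) {
    stop_input("driver_fraction must lie in (0, 1]")
  }
  mods <- names(features)
  if (is.null(mods) || !identical(sort(mods), sort(names(noise_sd))) ||
      !identical(sort(mods), sort(names(location)))) {
    stop_input("features, noise_sd and location must share modality names")
  }
  n_driver <- ceiling(driver_fraction * features)
  if (any(n_driver > features)) stop_input("more driver features than features")
  gene_level <- setdiff(mods, "mirna")
  if (any(features[gene_level] > genes_per_pathway)) {
    stop_input("gene-level modalities cannot have more features than genes per pathway")
  }
  if (length(hazard_ratios) != m_true) {
    stop_input("hazard_ratios must have m_true entries")
  }
  structure(
    list(
      n = as.integer(n), m_true = as.integer(m_true), proportions = proportions,
      P = as.integer(P), n_informative = as.integer(n_informative),
      genes_per_pathway = as.integer(genes_per_pathway),
      features = features, noise_sd = noise_sd, location = location,
      effect_size = effect_size, driver_fraction = driver_fraction,
      hazard_ratios = hazard_ratios, censoring_fraction = censoring_fraction,
      mutation_rate = mutation_rate, mutation_odds = mutation_odds,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic multi-omics study
#'
#' Draws a cohort according to a [synthetic_config()]: informative
#' pathways' driver features get cluster-specific means (each informative
#' pathway assigns the clusters a random permutation of equally spaced
#' levels in `[-1, 1]`, scaled by `effect_size * noise_sd`); all other
#' features are pure modality noise. Survival times are exponential with
#' per-cluster hazard ratios and independent exponential censoring
#' calibrated to the target censoring fraction; mutations are Bernoulli
#' with enriched odds in the designated (cluster, pathway) pairs.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_study` list: `blocks` (list of [omics_block()]),
#'   `gene_sets`, `maps` (list of [feature_gene_map()]), `mutations`
#'   (patients x genes binary matrix), `clinical` (tibble), `labels`
#'   (named integer vector of planted clusters), `informative_pathways`,
#'   `driver_features`, and the `config`.
#' @export
generate_synthetic_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n
  m <- config$m_true
  patients <- sprintf("P%03d", seq_len(n))
  counts <- diff(round(cumsum(c(0, config$proportions)) * n))  # sums to n exactly
  labels <- setNames(sample(rep(seq_len(m), times = counts)), patients)
  pathway_ids <- sprintf("PW%02d", seq_len(config$P))
  informative <- pathway_ids[seq_len(config$n_informative)]

  gene_sets <- setNames(lapply(pathway_ids, function(pw) {
    sprintf("%s_G%02d", pw, seq_len(config$genes_per_pathway))
  }), pathway_ids)
  attr(gene_sets, "descriptions") <- setNames(
    ifelse(pathway_ids %in% informative, "cluster-driving", "noise"), pathway_ids
  )
  class(gene_sets) <- "gene_sets"

  # per-pathway cluster levels: equally spaced in [-1, 1], randomly permuted
  base_levels <- if (m == 1L) 0 else seq(-1, 1, length.out = m)
  cluster_levels <- lapply(informative, function(pw) sample(base_levels))
  names(cluster_levels) <- informative

  mods <- names(config$features)
  blocks <- list()
  maps <- list()
  driver_features <- list()
  for (mod in mods) {
    pfeat <- config$features[[mod]]
    sdv <- config$noise_sd[[mod]]
    loc <- config$location[[mod]]
    n_driver <- ceiling(config$driver_fraction * pfeat)
    cols <- list()
    map_rows <- list()
    for (pw in pathway_ids) {
      feats <- switch(mod,
        mrna = gene_sets[[pw]][seq_len(pfeat)],
        mirna = sprintf("%s_mir%02d", pw, seq_len(pfeat)),
        meth = sprintf("%s_cg%02d", pw, seq_len(pfeat)),
        sprintf("%s_%s%02d", pw, mod, seq_len(pfeat))
      )
      M <- matrix(rnorm(n * pfeat, mean = loc, sd = sdv), n, pfeat,
                  dimnames = list(patients, feats))
      if (pw %in% informative && config$effect_size > 0) {
        shift <- config$effect_size * sdv * cluster_levels[[pw]][labels]
        drv <- seq_len(n_driver)
        M[, drv] <- M[, drv] + shift
        driver_features[[paste(mod, pw, sep = ".")]] <- feats[drv]
      }
      cols[[pw]] <- M
      map_rows[[pw]] <- switch(mod,
        mrna = tibble(feature_id = feats, gene_id = feats),
        mirna = tibble(
          feature_id = rep(feats, each = 2L),
          gene_id = gene_sets[[pw]][pmin(
            rep(seq_len(pfeat) * 2L, each = 2L) - c(1L, 0L),
            config$genes_per_pathway
          )]
        ),
        tibble(feature_id = feats,
               gene_id = gene_sets[[pw]][seq_len(pfeat)])
      )
    }
    values <- do.call(cbind, cols)
    if (mod == "meth") values <- pnorm(values)  # bounded beta-value-like scale
    blocks[[mod]] <- omics_block(values, mod)
    maps[[mod]] <- feature_gene_map(dplyr::bind_rows(map_rows), mod)
  }

  mutations <- synth_mutations(config, labels, gene_sets, informative)
  clinical <- synth_clinical(config, labels, patients)

  structure(
    list(
      blocks = blocks, gene_sets = gene_sets, maps = maps,
      mutations = mutations, clinical = clinical, labels = labels,
      informative_pathways = informative, driver_features = driver_features,
      config = config
    ),
    class = "synthetic_study"
  )
}

synth_mutations <- function(config, labels, gene_sets, informative) {
  genes <- unlist(gene_sets, use.names = FALSE)
  n <- length(labels)
  rate <- matrix(config$mutation_rate, n, length(genes),
                 dimnames = list(names(labels), genes))
  base_logit <- stats::qlogis(config$mutation_rate)
  n_pairs <- min(config$m_true, length(informative))
  for (c in seq_len(n_pairs)) {
    pw_genes <- gene_sets[[informative[c]]]
    rate[labels == c, pw_genes] <-
      stats::plogis(base_logit + log(config$mutation_odds))
  }
  mut <- matrix(rbinom(length(rate), 1L, rate), n, length(genes),
                dimnames = dimnames(rate))
  mut
}

synth_clinical <- function(config, labels, patients) {
  n <- length(labels)
  hr <- config$hazard_ratios[labels]
  pis <- as.vector(table(factor(labels, seq_len(config$m_true)))) / n

  make_endpoint <- function(median_days) {
    base_rate <- log(2) / median_days
    rates <- base_rate * config$hazard_ratios
    target <- config$censoring_fraction
    cens_rate <- uniroot(
      function(rc) sum(pis * rc / (rc + rates)) - target,
      lower = 1e-10, upper = 1e3, tol = 1e-12
    )$root
    T_evt <- rexp(n, rate = base_rate * hr)
    C_evt <- rexp(n, rate = cens_rate)
    list(time = round(pmin(T_evt, C_evt), 1), event = as.integer(T_evt <= C_evt))
  }
  os <- make_endpoint(1000)
  pfs <- make_endpoint(600)
  dfs <- make_endpoint(800)

  tibble(
    patient_id = patients,
    os_time = os$time, os_event = os$event,
    pfs_time = pfs$time, pfs_event = pfs$event,
    dfs_time = dfs$time, dfs_event = dfs$event,
    age = round(rnorm(n, 62, 10), 1),
    gender = sample(c("female", "male"), n, replace = TRUE),
    bmi = round(rnorm(n, 26, 4), 1)
  )
}

#' Write a synthetic study to its interchange files
#'
#' Emits every file the pipeline consumes: one omics TSV per modality,
#' the pathway GMT, feature-annotation TSVs for the non-gene-level
#' modalities, mutation and clinical TSVs. The planted truth labels are
#' written separately (`truth_labels.tsv`) and are not part of the
#' pipeline's visible inputs.
#'
#' @param study A `synthetic_study` from [generate_synthetic_study()].
#' @param dir Output directory (created if missing).
#' @return Named list of written file paths, invisibly.
#' @export
write_fixture <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (mod in names(study$blocks)) {
    paths[[paste0("omics_", mod)]] <-
      write_omics_block(study$blocks[[mod]], file.path(dir, paste0(mod, ".tsv")))
  }
  paths$gmt <- write_gene_sets(study$gene_sets, file.path(dir, "pathways.gmt"))
  for (mod in setdiff(names(study$maps), "mrna")) {
    p <- file.path(dir, paste0("map_", mod, ".tsv"))
    readr::write_tsv(study$maps[[mod]]$pairs, p, progress = FALSE)
    paths[[paste0("map_", mod)]] <- p
  }
  mut_df <- cbind(
    tibble(patient_id = rownames(study$mutations)),
    as_tibble(as.data.frame(study$mutations))
  )
  paths$mutations <- file.path(dir, "mutations.tsv")
  readr::write_tsv(mut_df, paths$mutations, progress = FALSE)
  paths$clinical <- file.path(dir, "clinical.tsv")
  readr::write_tsv(study$clinical, paths$clinical, progress = FALSE)
  paths$truth <- file.path(dir, "truth_labels.tsv")
  readr::write_tsv(
    tibble(patient_id = names(study$labels), cluster = as.integer(study$labels)),
    paths$truth, progress = FALSE
  )
  invisible(paths)
}

#' Read a written fixture back into memory
#'
#' @param dir Directory produced by [write_fixture()].
#' @param modalities Modality names to load (default: every `<mod>.tsv`).
#' @return List with `blocks`, `gene_sets`, `maps`, `mutations`,
#'   `clinical` (truth labels are not loaded).
#' @export
read_fixture <- function(dir, modalities = NULL) {
  if (is.null(modalities)) {
    files <- setdiff(list.files(dir, pattern = "\\.tsv$"),
                     c("mutations.tsv", "clinical.tsv", "truth_labels.tsv"))
    files <- files[!grepl("^map_", files)]
    modalities <- sub("\\.tsv$", "", files)
  }
  blocks <- lapply(modalities, function(mod) {
    read_omics_block(file.path(dir, paste0(mod, ".tsv")), mod)
  })
  names(blocks) <- modalities
  maps <- list()
  for (mod in modalities) {
    p <- file.path(dir, paste0("map_", mod, ".tsv"))
    if (file.exists(p)) maps[[mod]] <- read_feature_map(p, mod)
  }
  mut_df <- readr::read_tsv(file.path(dir, "mutations.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  mutations <- as.matrix(mut_df[, -1, drop = FALSE])
  rownames(mutations) <- as.character(mut_df[[1]])
  list(
    blocks = blocks,
    gene_sets = load_gene_sets(file.path(dir, "pathways.gmt")),
    maps = maps,
    mutations = mutations,
    clinical = readr::read_tsv(file.path(dir, "clinical.tsv"),
                               show_col_types = FALSE, progress = FALSE)
  )
}
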