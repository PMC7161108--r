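#' Read pathway gene sets from a GMT file
#'
#' Parses the standard GMT dialect: one pathway per line, tab-separated
#' fields `id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Duplicate
#' genes within a line are dropped; file order is preserved.
#'
#' @param path Path to a GMT file.
#' @return A named list of class `gene_sets`; each element is a character
#'   vector of unique gene identifiers, named by pathway id, with the
#'   description kept in the `"descriptions"` attribute.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("PW1\tfirst\tG1\tG2\tG2", "PW2\tsecond\tG3"), gmt)
#' gs <- load_gene_sets(gmt)
#' gs[["PW1"]]
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) stop_input("GMT file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("GMT file is empty: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop_input("malformed GMT line %d: fewer than 3 tab-separated fields", bad[1L])
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop_input("duplicated pathway id in GMT: %s", ids[duplicated(ids)][1L])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, "", 2L), ids)
  class(sets) <- "gene_sets"
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets A `gene_sets` object or named list of gene id vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  desc <- attr(gene_sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(gene_sets)), names(gene_sets))
  lines <- vapply(names(gene_sets), function(id) {
    paste(c(id, desc[[id]], gene_sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
tidy.gene_sets <- function(x, ...) {
  tibble(
    pathway_id = rep(names(x), lengths(x)),
    gene_id = unlist(x, use.names = FALSE)
  )
}

#' Construct an omics block
#'
#' One omics modality as a patients-by-features numeric matrix with
#' mandatory dimnames. Units are modality-native (log-expression, beta
#' values, gene-level copy-number estimates, ...).
#'
#' @param values Numeric matrix, patients in rows, features in columns;
#'   rownames are patient ids, colnames are feature ids.
#' @param modality Modality label (e.g. `"mrna"`, `"mirna"`, `"meth"`).
#' @return An `omics_block` object.
#' @export
omics_block <- function(values, modality) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("omics block values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("omics block matrix needs patient rownames and feature colnames")
  }
  if (anyDuplicated(colnames(values))) {
    stop_input("duplicate feature ids in modality '%s'", modality)
  }
  if (anyDuplicated(rownames(values)) || any(!nzchar(rownames(values)))) {
    stop_input("duplicate or empty patient ids in modality '%s'", modality)
  }
  structure(
    list(
      modality = as.character(modality),
      patients = rownames(values),
      features = colnames(values),
      values = values
    ),
    class = "omics_block"
  )
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf(
    "<omics_block> %s: %d patients x %d features\n",
    x$modality, length(x$patients), length(x$features)
  ))
  invisible(x)
}

#' Read an omics matrix from TSV
#'
#' Expects a header row of feature ids and a first column of patient ids.
#'
#' @param path TSV file path.
#' @param modality Modality label for the resulting block.
#' @return An [omics_block()].
#' @export
read_omics_block <- function(path, modality) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  omics_block(m, modality)
}

#' Write an omics block to TSV
#' @param block An [omics_block()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_block <- function(block, path) {
  df <- as.data.frame(block$values)
  df <- cbind(patient_id = block$patients, df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Feature-to-gene annotation map
#'
#' Many-to-many mapping between modality features (CpGs, miRNAs, ...) and
#' gene identifiers. Gene-level modalities (expression, CNV) can use
#' [identity_feature_map()].
#'
#' @param pairs Data frame (or tibble) with columns `feature_id`, `gene_id`.
#' @param modality Modality label the map applies to.
#' @return A `feature_gene_map` object.
#' @export
feature_gene_map <- function(pairs, modality) {
  pairs <- as_tibble(pairs)
  if (!all(c("feature_id", "gene_id") %in% names(pairs))) {
    stop_input("feature map needs columns feature_id and gene_id")
  }
  pairs <- dplyr::distinct(pairs[, c("feature_id", "gene_id")])
  pairs$feature_id <- as.character(pairs$feature_id)
  pairs$gene_id <- as.character(pairs$gene_id)
  structure(list(modality = modality, pairs = pairs), class = "feature_gene_map")
}

#' @rdname feature_gene_map
#' @param block An [omics_block()] whose feature ids already are gene ids.
#' @export
identity_feature_map <- function(block) {
  feature_gene_map(
    tibble(feature_id = block$features, gene_id = block$features),
    block$modality
  )
}

#' Read a 2-column feature annotation TSV (feature_id, gene_id)
#' @param path TSV path.
#' @param modality Modality label.
#' @return A [feature_gene_map()].
#' @export
read_feature_map <- function(path, modality) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1:2] <- c("feature_id", "gene_id")
  feature_gene_map(df, modality)
}

#' Assemble per-pathway multi-omics views
#'
#' For each pathway, collects from every modality the features whose mapped
#' genes intersect the pathway's gene set, restricted to the patients shared
#' by all modalities (sorted order). Modalities contributing fewer than
#' `min_features_per_modality` features are dropped from that pathway's
#' view; pathways retaining no modality are omitted.
#'
#' @param blocks List of [omics_block()] objects (one per modality).
#' @param gene_sets A [load_gene_sets()] result or named list of gene id
#'   vectors.
#' @param maps List of [feature_gene_map()] objects. Modalities missing a
#'   map are given an identity map (gene-level modalities).
#' @param min_features_per_modality Minimum features a modality must
#'   contribute to stay in a view (default 1).
#' @return A list of `pathway_view` objects: each holds the shared sorted
#'   patient vector and one patients-by-features submatrix per retained
#'   modality, feature columns in lexicographic order.
#' @export
build_pathway_views <- function(blocks, gene_sets, maps = list(),
                                min_features_per_modality = 1L) {
  if (length(blocks) < 1L) stop_input("at least one omics block is required")
  modalities <- vapply(blocks, function(b) b$modality, "")
  if (anyDuplicated(modalities)) stop_input("duplicate modality names in blocks")
  names(blocks) <- modalities

  map_mod <- vapply(maps, function(m) m$modality, character(1))
  maps <- setNames(maps, map_mod)
  for (mod in modalities) {
    if (is.null(maps[[mod]])) maps[[mod]] <- identity_feature_map(blocks[[mod]])
  }

  patients <- Reduce(intersect, lapply(blocks, function(b) b$patients))
  if (length(patients) == 0L) {
    stop_input("patient intersection across modalities is empty")
  }
  patients <- sort(patients)

  views <- list()
  for (pw in names(gene_sets)) {
    genes <- gene_sets[[pw]]
    sub <- list()
    for (mod in modalities) {
      pr <- maps[[mod]]$pairs
      feats <- sort(unique(pr$feature_id[pr$gene_id %in% genes]))
      feats <- feats[feats %in% blocks[[mod]]$features]
      if (length(feats) >= min_features_per_modality && length(feats) > 0L) {
        sub[[mod]] <- blocks[[mod]]$values[patients, feats, drop = FALSE]
      }
    }
    if (length(sub) >= 1L) {
      views[[pw]] <- structure(
        list(
          pathway_id = pw,
          blocks = sub,
          patients = patients,
          p_j = vapply(sub, ncol, 1L),
          k = length(sub),
          n = length(patients)
        ),
        class = "pathway_view"
      )
    }
  }
  views
}

#' @export
print.pathway_view <- function(x, ...) {
  cat(sprintf(
    "<pathway_view> %s: n=%d patients, k=%d modalities (%s)\n",
    x$pathway_id, x$n, x$k,
    paste(sprintf("%s:%d", names(x$blocks), x$p_j), collapse = ", ")
  ))
  invisible(x)
}

# concatenated feature matrix of a view (patients x sum(p_j)),
# with modality-qualified column names
view_matrix <- function(view) {
  m <- do.call(cbind, lapply(names(view$blocks), function(mod) {
    b <- view$blocks[[mod]]
    colnames(b) <- paste(mod, colnames(b), sep = ":")
    b
  }))
  rownames(m) <- view$patients
  m
}
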