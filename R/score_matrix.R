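#' Assemble the pathway-by-patient score matrix
#'
#' Scores every patient with each pathway's trained autoencoder and stacks
#' the results into a P-by-n matrix. Because the downstream non-negative
#' factorization requires `X >= 0` while tanh scores are signed, each
#' pathway row is independently min-max rescaled to `[0, 1]` across
#' patients; constant rows map to 0.5.
#'
#' @param models Named list of `trained_pathway_model` (or `ae_model`)
#'   objects, one per pathway.
#' @param views Named list of `pathway_view` objects matching `models`;
#'   all must share the same patient vector.
#' @return A `pathway_scores` object: `scores` (P x n matrix in `[0, 1]`),
#'   `raw` (unscaled tanh scores), pathway and patient ids.
#' @export
assemble_score_matrix <- function(models, views) {
  if (length(models) == 0L) stop_input("no models supplied")
  ids <- names(views)
  if (is.null(ids)) ids <- vapply(views, function(v) v$pathway_id, "")
  if (is.null(names(models))) names(models) <- ids
  patients <- views[[1L]]$patients
  for (v in views) {
    if (!identical(v$patients, patients)) {
      stop_input("views do not share an identical patient list")
    }
  }
  raw <- matrix(NA_real_, length(ids), length(patients),
                dimnames = list(ids, patients))
  for (pw in ids) {
    m <- models[[pw]]
    if (inherits(m, "trained_pathway_model")) m <- m$model
    raw[pw, ] <- score_patients(m, views[[pw]])
  }
  new_pathway_scores(raw)
}

new_pathway_scores <- function(raw) {
  if (is.null(rownames(raw))) rownames(raw) <- sprintf("PW%03d", seq_len(nrow(raw)))
  if (is.null(colnames(raw))) colnames(raw) <- sprintf("S%03d", seq_len(ncol(raw)))
  scores <- t(apply(raw, 1L, rescale_minmax))
  dimnames(scores) <- dimnames(raw)
  structure(
    list(
      scores = scores, raw = raw,
      pathways = rownames(raw), patients = colnames(raw)
    ),
    class = "pathway_scores"
  )
}

# min-max rescale to [0, 1]; constant vectors map to 0.5
rescale_minmax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < 1e-12) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("<pathway_scores> %d pathways x %d patients, range [%.3f, %.3f]\n",
              length(x$pathways), length(x$patients),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
tidy.pathway_scores <- function(x, ...) {
  tibble(
    pathway_id = rep(x$pathways, times = length(x$patients)),
    patient_id = rep(x$patients, each = length(x$pathways)),
    score = as.vector(x$scores),
    score_raw = as.vector(x$raw)
  )
}

#' @export
autoplot.pathway_scores <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$patient_id, .data$pathway_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "patient", y = "pathway", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Write / read a pathway score matrix as TSV
#'
#' Pathways as rows, patients as columns; first column holds pathway ids.
#'
#' @param x A `pathway_scores` object.
#' @param path TSV path.
#' @return `path` (write) or a `pathway_scores` object (read).
#' @export
write_score_matrix <- function(x, path) {
  df <- cbind(
    tibble(pathway_id = x$pathways),
    as_tibble(as.data.frame(x$scores))
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  obj <- new_pathway_scores(m)
  # file already holds rescaled scores; keep them verbatim
  obj$scores <- m
  obj
}
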