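#' Exact Shapley values by subset enumeration
#'
#' Attributes `f(x) - f(background)` to individual features with the exact
#' Shapley formula: `phi_i = sum over subsets S of F without i of
#' |S|! (|F|-|S|-1)! / |F|! * (f(S with i) - f(S))`, where `f(S)` evaluates
#' the model on an input whose features outside `S` are replaced by the
#' background value (conditional-expectation surrogate). Satisfies
#' efficiency (`sum(phi) = f(x) - f(background)`), symmetry, and the dummy
#' axiom exactly.
#'
#' @param f Vectorized score function: takes a numeric matrix (rows =
#'   inputs) and returns one number per row.
#' @param x Numeric feature vector to explain.
#' @param background Reference feature vector of the same length.
#' @param guard Maximum number of features for full enumeration
#'   (default 15).
#' @return Named numeric vector of Shapley values, one per feature.
#' @export
exact_shapley <- function(f, x, background, guard = 15L) {
  p <- length(x)
  if (length(background) != p) stop_input("background must match x in length")
  if (p > guard) {
    stop_input("%d features exceed the exact enumeration guard (%d); use approx_shapley",
               p, guard)
  }
  n_sub <- 2L^p
  # subset membership matrix: row = subset mask, col = feature
  member <- matrix(FALSE, n_sub, p)
  for (i in seq_len(p)) {
    member[, i] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }
  inputs <- matrix(rep(background, each = n_sub), n_sub, p)
  inputs[member] <- rep(x, each = n_sub)[member]
  vals <- f(inputs)
  if (length(vals) != n_sub) stop_input("f must return one value per input row")

  sizes <- rowSums(member)
  lw <- lfactorial(sizes) + lfactorial(p - sizes - 1L) - lfactorial(p)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    without <- !member[, i]
    idx_s <- which(without)
    idx_si <- idx_s + bitwShiftL(1L, i - 1L)   # same subset plus feature i
    phi[i] <- sum(exp(lw[idx_s]) * (vals[idx_si] - vals[idx_s]))
  }
  names(phi) <- names(x)
  phi
}

# score function of a trained model over concatenated raw-unit inputs
ae_score_fun <- function(model) {
  force(model)
  function(M) unname(score_patients(model, M))
}

#' Approximate Shapley attribution of a pathway score
#'
#' Permutation-sampling estimator of the Shapley values of the bottleneck
#' pathway score with respect to all (concatenated) input features.
#' For each sampled feature ordering, features are switched one at a time
#' from the background value to the patient's value and the marginal score
#' changes are recorded; averaging over orderings estimates the Shapley
#' value. Each ordering's contributions telescope, so efficiency holds
#' exactly; for models that are linear in the inputs the estimate equals
#' the exact Shapley value for any number of samples. Antithetic pairs
#' (each ordering and its reverse) reduce variance.
#'
#' @param model A `trained_pathway_model` or `ae_model`.
#' @param x Concatenated feature vector (original units, block order of
#'   the model's modalities), or a 1-row matrix.
#' @param background Reference vector; defaults to the model's stored
#'   per-feature training means.
#' @param n_samples Number of sampled orderings (default 200).
#' @param seed Integer seed.
#' @return Named numeric vector of Shapley value estimates per feature.
#' @export
approx_shapley <- function(model, x, background = NULL, n_samples = 200L,
                           seed = 1L) {
  if (inherits(model, "trained_pathway_model")) model <- model$model
  arch <- model$architecture
  p <- sum(arch$p_j)
  if (is.matrix(x)) x <- drop(x)
  if (length(x) != p) stop_input("x has %d features; model expects %d", length(x), p)
  if (is.null(background)) {
    background <- unlist(lapply(arch$modalities, function(mod) model$stats[[mod]]$mean))
  }
  if (length(background) != p) stop_input("background must have %d features", p)
  f <- ae_score_fun(model)

  set.seed(seed)
  half <- ceiling(n_samples / 2)
  orders <- vector("list", 2L * half)
  for (s in seq_len(half)) {
    o <- sample.int(p)
    orders[[2L * s - 1L]] <- o
    orders[[2L * s]] <- rev(o)
  }
  orders <- orders[seq_len(max(2L, n_samples))]

  phi <- numeric(p)
  for (o in orders) {
    # rows 1..p+1: background with the first 0..p features (in order o) set to x
    M <- matrix(rep(background, each = p + 1L), p + 1L, p)
    for (j in seq_len(p)) {
      M[(j + 1L):(p + 1L), o[j]] <- x[o[j]]
    }
    v <- f(M)
    phi[o] <- phi[o] + diff(v)
  }
  phi <- phi / length(orders)
  names(phi) <- unlist(lapply(arch$modalities, function(mod) {
    paste(mod, model$features[[mod]] %||% seq_len(arch$p_j[[mod]]), sep = ":")
  }))
  phi
}

#' Aggregate Shapley attributions over patients
#'
#' Per-feature impact is the mean over patients of `|phi|`; per-modality
#' impact is the mean of `|phi|` over all patient-feature pairs of that
#' modality. Both tables are sorted by decreasing impact.
#'
#' @param phi Patients-by-features matrix of Shapley values (columns named
#'   `modality:feature`, as produced by [attribute_pathway()]), or any
#'   matrix plus an explicit `modality` vector.
#' @param modality Optional character vector giving each column's
#'   modality; defaults to the prefix before `":"` in the column names.
#' @return List of two tibbles: `features` (feature, modality,
#'   mean_abs_shap) and `modalities` (modality, mean_abs_shap).
#' @export
aggregate_attributions <- function(phi, modality = NULL) {
  phi <- as.matrix(phi)
  if (nrow(phi) == 0L || ncol(phi) == 0L) stop_input("phi is empty")
  if (is.null(modality)) {
    if (is.null(colnames(phi))) stop_input("phi needs column names or a modality vector")
    modality <- sub(":.*$", "", colnames(phi))
  }
  if (length(modality) != ncol(phi)) {
    stop_input("modality vector must have one entry per feature column")
  }
  feat <- tibble(
    feature = colnames(phi) %||% as.character(seq_len(ncol(phi))),
    modality = modality,
    mean_abs_shap = unname(colMeans(abs(phi)))
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
  # every feature carries the same number of patients, so the modality mean
  # over all its patient-feature |phi| values is the mean of feature means
  mods <- feat |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(mean_abs_shap = mean(.data$mean_abs_shap), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
  list(features = feat, modalities = mods)
}

#' Shapley attribution of one pathway model over a cohort
#'
#' Runs [approx_shapley()] (or [exact_shapley()] when the view is small
#' enough and `exact = TRUE`) for every patient in a view and aggregates.
#'
#' @param model A `trained_pathway_model`.
#' @param view The matching `pathway_view`.
#' @param n_samples Orderings per patient for the sampling estimator.
#' @param exact Use exact enumeration (only for `<= 15` total features).
#' @param seed Integer seed.
#' @return An `attribution` object: `phi` (patients x features),
#'   aggregate tibbles, pathway id, and the background used.
#' @export
attribute_pathway <- function(model, view, n_samples = 200L, exact = FALSE,
                              seed = 1L) {
  tm <- if (inherits(model, "trained_pathway_model")) model$model else model
  M <- view_matrix(view)
  background <- unlist(lapply(tm$architecture$modalities,
                              function(mod) tm$stats[[mod]]$mean))
  phi <- matrix(NA_real_, nrow(M), ncol(M))
  rownames(phi) <- rownames(M)
  if (exact) {
    f <- ae_score_fun(tm)
    for (i in seq_len(nrow(M))) {
      phi[i, ] <- exact_shapley(f, M[i, ], background)
    }
    colnames(phi) <- colnames(M)
  } else {
    for (i in seq_len(nrow(M))) {
      phi[i, ] <- approx_shapley(tm, M[i, ], background,
                                 n_samples = n_samples, seed = seed + i)
    }
    colnames(phi) <- colnames(M)
  }
  agg <- aggregate_attributions(phi)
  structure(
    list(
      pathway_id = view$pathway_id, phi = phi,
      features = agg$features, modalities = agg$modalities,
      background = background
    ),
    class = "attribution"
  )
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution> pathway %s: %d patients x %d features\n",
              x$pathway_id, nrow(x$phi), ncol(x$phi)))
  print(head(x$features, 5))
  invisible(x)
}

#' @export
tidy.attribution <- function(x, ...) {
  tibble(
    pathway_id = x$pathway_id,
    patient_id = rep(rownames(x$phi), times = ncol(x$phi)),
    feature = rep(colnames(x$phi), each = nrow(x$phi)),
    modality = rep(sub(":.*$", "", colnames(x$phi)), each = nrow(x$phi)),
    phi = as.vector(x$phi)
  )
}

#' @export
autoplot.attribution <- function(object, top_n = 15L, ...) {
  df <- head(object$features, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_abs_shap, .data$feature,
                                   fill = .data$modality)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |SHAP|", y = NULL,
                  title = object$pathway_id) +
    ggplot2::theme_minimal()
}
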