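#' Consensus clustering over repeated sNMF runs
#'
#' Runs [snmf_factorize()] `runs` times from different random
#' initializations (per-run seeds derived deterministically from `seed`),
#' records for every patient pair the fraction of runs in which they share
#' a cluster (the consensus matrix `C`), and extracts final labels by
#' average-linkage hierarchical clustering of the distance `1 - C` cut
#' into `m` clusters. Attaches the cophenetic correlation of that
#' dendrogram, the consensus silhouette (distance `1 - C`), and the
#' silhouette of the best single run (lowest objective; Euclidean distance
#' between patient score profiles).
#'
#' @inheritParams snmf_factorize
#' @param runs Number of random restarts (the reference protocol uses 500).
#' @return A `consensus_result` with `consensus` (n x n), `labels`,
#'   `cophenetic`, `silhouette_consensus`, `silhouette_best_run`,
#'   `objectives`, `best_fit`, and the call parameters.
#' @export
consensus_cluster <- function(X, m, beta = 0.01, eta = max(X), runs = 500L,
                              seed = 1L, max_iter = 500L, tol = 0,
                              method = c("mu", "anls"), conn_stop = TRUE,
                              conn_patience = 40L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (runs < 2L) stop_input("consensus clustering needs runs >= 2")
  n <- ncol(X)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, runs)

  C <- matrix(0, n, n)
  objectives <- rep(NA_real_, runs)
  best_fit <- NULL
  failed <- 0L
  for (r in seq_len(runs)) {
    fit <- tryCatch(
      snmf_factorize(X, m, beta = beta, eta = eta, seed = run_seeds[r],
                     max_iter = max_iter, tol = tol, method = method,
                     conn_stop = conn_stop, conn_patience = conn_patience),
      error = function(e) {
        warn(sprintf("sNMF restart %d failed: %s", r, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) {
      failed <- failed + 1L
      next
    }
    lab <- suppressWarnings(assign_clusters(fit$H))
    C <- C + outer(lab, lab, "==")
    objectives[r] <- fit$objective
    if (is.null(best_fit) || fit$objective < best_fit$objective) best_fit <- fit
  }
  ok <- runs - failed
  if (failed > 0.1 * runs) {
    stop_input("%d of %d sNMF restarts failed", failed, runs)
  }
  C <- C / ok
  diag(C) <- 1
  dimnames(C) <- list(colnames(X), colnames(X))

  hc <- hclust(as.dist(1 - C), method = "average")
  labels <- cutree(hc, k = m)
  names(labels) <- colnames(X)

  sil_cons <- silhouette_index(labels, 1 - C)
  best_labels <- suppressWarnings(assign_clusters(best_fit$H))
  Deuc <- as.matrix(stats::dist(t(X)))
  sil_best <- if (length(unique(best_labels)) > 1L) {
    silhouette_index(best_labels, Deuc)
  } else {
    list(mean = NA_real_, s = rep(NA_real_, n))
  }

  structure(
    list(
      consensus = C, labels = labels, hclust = hc,
      cophenetic = cophenetic_correlation(C),
      silhouette_consensus = sil_cons$mean,
      silhouette_best_run = sil_best$mean,
      silhouette_values = sil_cons$s,
      objectives = objectives, best_fit = best_fit,
      m = m, beta = beta, eta = eta, runs = runs, seed = seed,
      method = method
    ),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> m = %d over %d runs: cophenetic %.3f, consensus silhouette %.3f\n",
    x$m, x$runs, x$cophenetic, x$silhouette_consensus
  ))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
tidy.consensus_result <- function(x, ...) {
  tibble(
    patient_id = names(x$labels) %||% as.character(seq_along(x$labels)),
    cluster = as.integer(x$labels),
    silhouette = unname(x$silhouette_values)
  )
}

#' @export
glance.consensus_result <- function(x, ...) {
  tibble(
    m = x$m, beta = x$beta, runs = x$runs,
    cophenetic = x$cophenetic,
    silhouette_consensus = x$silhouette_consensus,
    silhouette_best_run = x$silhouette_best_run,
    best_objective = min(x$objectives, na.rm = TRUE)
  )
}

#' @export
autoplot.consensus_result <- function(object, ...) {
  ord <- object$hclust$order
  C <- object$consensus[ord, ord]
  ids <- colnames(C) %||% as.character(seq_len(ncol(C)))
  df <- tibble(
    a = factor(rep(ids, times = ncol(C)), levels = ids),
    b = factor(rep(ids, each = nrow(C)), levels = ids),
    consensus = as.vector(C)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-clustering") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the upper-triangle entries of the
#' dissimilarity `1 - C` and the cophenetic distances of the
#' average-linkage dendrogram built on it. Values near 1 indicate that the
#' hierarchical clustering faithfully represents the consensus similarity
#' structure.
#'
#' @param C Symmetric consensus matrix with entries in `[0, 1]` and unit
#'   diagonal, `n >= 3`.
#' @return Numeric scalar in `[-1, 1]`; `NaN` (with a warning) when either
#'   distance vector is constant.
#' @export
cophenetic_correlation <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || nrow(C) < 3L) {
    stop_input("C must be a square matrix with n >= 3")
  }
  if (max(abs(C - t(C))) > 1e-8) stop_input("C must be symmetric")
  D <- 1 - C
  hc <- hclust(as.dist(D), method = "average")
  coph <- as.matrix(cophenetic(hc))
  up <- upper.tri(D)
  d1 <- D[up]
  d2 <- coph[up]
  if (sd(d1) < 1e-15 || sd(d2) < 1e-15) {
    warn("constant distance vector: cophenetic correlation undefined")
    return(NaN)
  }
  cor(d1, d2)
}

#' Silhouette values and index
#'
#' For patient i in cluster C_i with |C_i| > 1,
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where `a(i)` is the mean
#' distance to the other members of C_i and `b(i)` the smallest mean
#' distance to any other cluster; singletons get `s(i) = 0`. The index is
#' the mean `s(i)` over all patients.
#'
#' @param labels Cluster label vector.
#' @param D Symmetric pairwise distance matrix with zero diagonal.
#' @return List with `s` (per-point values in `[-1, 1]`) and `mean`.
#' @export
silhouette_index <- function(labels, D) {
  D <- as.matrix(D)
  n <- length(labels)
  if (nrow(D) != n || ncol(D) != n) stop_input("D must be n x n")
  cl <- unique(labels)
  if (length(cl) < 2L) {
    stop_input("silhouette is undefined for a single cluster")
  }
  # mean distance of every point to every cluster, in one matrix product
  M <- outer(labels, cl, "==") * 1           # n x k membership
  sums <- D %*% M                            # n x k distance sums
  sizes <- colSums(M)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], cl)
    if (sizes[ci] <= 1) {
      s[i] <- 0
      next
    }
    a <- sums[i, ci] / (sizes[ci] - 1)       # exclude the point itself
    b <- min(sums[i, -ci] / sizes[-ci])
    s[i] <- (b - a) / max(a, b)
  }
  list(s = s, mean = mean(s))
}

#' Rank selection by permutation-calibrated cophenetic correlation
#'
#' For every candidate rank and every `beta` in the grid, runs consensus
#' clustering on the real matrix and on `n_perm` null matrices obtained by
#' independently shuffling the entries within every row of `X` (preserving
#' each pathway's score distribution while destroying patient structure).
#' A rank qualifies when, at its best `beta` (highest real cophenetic),
#' the real cophenetic correlation exceeds the upper bound of the 95%
#' confidence interval (`mean + 1.96 sd`) of the permuted copheneties.
#' The selected rank `m*` is the smallest qualifying one; when none
#' qualifies the selection is flagged unresolved.
#'
#' @inheritParams consensus_cluster
#' @param ranks Candidate ranks (default `2:9`).
#' @param beta_grid Candidate sparsity weights within `[0.001, 1]`.
#' @param n_perm Number of row-wise permutations per rank/beta (default 40).
#' @return A `rank_selection` object: `selected` (`NA` if unresolved),
#'   `resolved`, `best_beta` per rank, and a `diagnostics` tibble with one
#'   cophenetic value per (rank, beta, real/permutation) combination.
#' @export
select_rank <- function(X, ranks = 2:9, beta_grid = c(0.001, 0.01, 0.1, 1),
                        runs = 500L, n_perm = 40L, eta = max(X), seed = 1L,
                        max_iter = 500L, tol = 0,
                        method = c("mu", "anls")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (any(X < 0)) stop_input("X must be non-negative")
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  cons_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  permute_rows <- function(M, s) {
    set.seed(s)
    t(apply(M, 1L, sample))
  }

  rows <- list()
  for (b in beta_grid) {
    for (m in ranks) {
      real <- consensus_cluster(X, m, beta = b, eta = eta, runs = runs,
                                seed = cons_seed, max_iter = max_iter,
                                tol = tol, method = method)
      rows[[length(rows) + 1L]] <- tibble(
        rank = m, beta = b, type = "real", perm = NA_integer_,
        cophenetic = real$cophenetic,
        silhouette_consensus = real$silhouette_consensus
      )
      for (q in seq_len(n_perm)) {
        Xp <- permute_rows(X, perm_seeds[q])
        pc <- consensus_cluster(Xp, m, beta = b, eta = max(Xp), runs = runs,
                                seed = cons_seed, max_iter = max_iter,
                                tol = tol, method = method)
        rows[[length(rows) + 1L]] <- tibble(
          rank = m, beta = b, type = "permuted", perm = q,
          cophenetic = pc$cophenetic,
          silhouette_consensus = pc$silhouette_consensus
        )
      }
    }
  }
  diagnostics <- dplyr::bind_rows(rows)

  per_rank <- diagnostics |>
    dplyr::filter(.data$type == "real") |>
    dplyr::group_by(.data$rank) |>
    dplyr::slice_max(.data$cophenetic, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(real_cophenetic = "cophenetic", best_beta = "beta") |>
    dplyr::select("rank", "best_beta", "real_cophenetic")
  null_stats <- diagnostics |>
    dplyr::filter(.data$type == "permuted") |>
    dplyr::group_by(.data$rank, .data$beta) |>
    dplyr::summarise(
      null_mean = mean(.data$cophenetic, na.rm = TRUE),
      null_sd = sd(.data$cophenetic, na.rm = TRUE),
      .groups = "drop"
    )
  per_rank <- per_rank |>
    dplyr::left_join(null_stats, by = c(rank = "rank", best_beta = "beta")) |>
    dplyr::mutate(
      null_upper = .data$null_mean + 1.96 * .data$null_sd,
      qualifies = .data$real_cophenetic > .data$null_upper
    ) |>
    dplyr::arrange(.data$rank)

  qualifying <- per_rank$rank[per_rank$qualifies %in% TRUE]
  structure(
    list(
      selected = if (length(qualifying)) min(qualifying) else NA_integer_,
      resolved = length(qualifying) > 0L,
      summary = per_rank,
      diagnostics = diagnostics,
      ranks = ranks, beta_grid = beta_grid, n_perm = n_perm, runs = runs,
      seed = seed
    ),
    class = "rank_selection"
  )
}

#' @export
print.rank_selection <- function(x, ...) {
  if (x$resolved) {
    cat(sprintf("<rank_selection> selected m* = %d\n", x$selected))
  } else {
    cat("<rank_selection> unresolved: no rank beats the permutation null\n")
  }
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' @export
tidy.rank_selection <- function(x, ...) x$summary

#' @export
autoplot.rank_selection <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$rank)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$null_mean - 1.96 * .data$null_sd,
                   ymax = .data$null_upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$real_cophenetic), colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(y = .data$real_cophenetic), colour = "#2166ac") +
    ggplot2::labs(x = "rank (clusters)", y = "cophenetic correlation") +
    ggplot2::theme_minimal()
}
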