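#' Sparse non-negative matrix factorization
#'
#' Factorizes a non-negative P-by-n matrix `X ~ B %*% H` (`B`: P-by-m
#' basis, `H`: m-by-n coefficients) by minimizing
#' `0.5 * (||X - BH||_F^2 + eta * ||B||_F^2 + beta * sum_j ||H[, j]||_1^2)`
#' subject to `B, H >= 0`. Two solvers are available, both with a
#' monotone non-increasing objective: `"mu"` (default) uses multiplicative
#' updates (Lee-Seung rules applied to the augmented least-squares forms
#' of the two subproblems), whose restart-to-restart variability across
#' random initializations is what random-restart consensus clustering
#' measures; `"anls"` solves each alternating non-negative least-squares
#' subproblem exactly by block principal pivoting (Kim & Park) and lands
#' near-deterministically in a far better optimum per restart. `B` and
#' `H` are initialized uniform at random, so runs are deterministic given
#' `seed`.
#'
#' @param X Non-negative numeric matrix (pathways x patients).
#' @param m Factorization rank (number of clusters), `1 <= m <= min(dim(X))`.
#' @param beta Column-sparsity weight on `H` (>= 0; the model-selection
#'   grid of this package spans `[0.001, 1]`).
#' @param eta Ridge weight on `B`; defaults to `max(X)`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum alternating iterations.
#' @param tol Relative objective-change stopping tolerance.
#' @param method `"mu"` (multiplicative updates) or `"anls"` (exact
#'   alternating NNLS).
#' @param conn_stop Use the Brunet connectivity stopping rule: stop once
#'   the argmax partition of `H` has been unchanged for `conn_patience`
#'   consecutive iterations. This is the stopping criterion of classic
#'   consensus NMF protocols; [consensus_cluster()] switches it on so that
#'   restarts retain the initialization-dependence that consensus
#'   stability measurement relies on. Set `tol = 0` to disable the
#'   objective-tolerance stop when using it.
#' @param conn_patience Iterations the partition must stay unchanged
#'   before stopping (default 40).
#' @return An `snmf_fit`: `B`, `H`, `objective`, `trace` (objective per
#'   iteration), plus the call parameters.
#' @export
snmf_factorize <- function(X, m, beta = 0.01, eta = max(X), seed = 1L,
                           max_iter = 500L, tol = 1e-6,
                           method = c("mu", "anls"), conn_stop = FALSE,
                           conn_patience = 40L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (any(X < 0)) stop_input("X must be non-negative for sNMF")
  if (any(!is.finite(X))) stop_input("X contains non-finite values")
  m <- as.integer(m)
  if (m < 1L || m > min(dim(X))) {
    stop_input("rank m = %d out of range [1, %d]", m, min(dim(X)))
  }
  if (beta < 0) stop_input("beta must be >= 0")
  if (eta < 0) stop_input("eta must be >= 0")
  set.seed(seed)
  B0 <- matrix(runif(nrow(X) * m), nrow(X), m)
  H0 <- matrix(runif(m * ncol(X)), m, ncol(X))
  res <- snmf_solve_cpp(X, B0, H0, beta, eta, as.integer(max_iter), tol,
                        method, isTRUE(conn_stop), as.integer(conn_patience))
  rownames(res$B) <- rownames(X)
  colnames(res$H) <- colnames(X)
  structure(
    list(
      B = res$B, H = res$H, objective = res$objective, trace = res$trace,
      m = m, beta = beta, eta = eta, seed = seed, method = method,
      iterations = length(res$trace) - 1L
    ),
    class = "snmf_fit"
  )
}

#' @export
print.snmf_fit <- function(x, ...) {
  cat(sprintf("<snmf_fit> rank %d, beta %.4g, eta %.4g: objective %.5g (%d iterations)\n",
              x$m, x$beta, x$eta, x$objective, x$iterations))
  invisible(x)
}

#' @export
glance.snmf_fit <- function(x, ...) {
  tibble(
    rank = x$m, beta = x$beta, eta = x$eta,
    objective = x$objective, iterations = x$iterations,
    h_sparsity = mean(x$H < 1e-8)
  )
}

#' @export
tidy.snmf_fit <- function(x, matrix = c("B", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "B") {
    tibble(
      pathway_id = rep(rownames(x$B) %||% as.character(seq_len(nrow(x$B))),
                       times = x$m),
      component = rep(seq_len(x$m), each = nrow(x$B)),
      loading = as.vector(x$B)
    )
  } else {
    tibble(
      component = rep(seq_len(x$m), times = ncol(x$H)),
      patient_id = rep(colnames(x$H) %||% as.character(seq_len(ncol(x$H))),
                       each = x$m),
      coefficient = as.vector(x$H)
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign patients to clusters from an NMF coefficient matrix
#'
#' Patient j goes to the component with the largest coefficient `H[, j]`;
#' ties break to the lowest row index. An all-zero column is assigned to
#' cluster 1 with a warning.
#'
#' @param H Non-negative m-by-n coefficient matrix (or an `snmf_fit`).
#' @return Integer vector of cluster labels in `1..m`, named by patient
#'   when `H` has column names.
#' @export
assign_clusters <- function(H) {
  if (inherits(H, "snmf_fit")) H <- H$H
  if (any(H < 0)) stop_input("H must be non-negative")
  zero <- colSums(H) == 0
  if (any(zero)) {
    warn(sprintf("%d all-zero coefficient column(s) assigned to cluster 1",
                 sum(zero)))
  }
  labels <- apply(H, 2L, which.max)  # which.max already breaks ties low
  setNames(as.integer(labels), colnames(H))
}

#' Most descriptive features of a basis component
#'
#' Sorts column `i` of the basis matrix by decreasing magnitude and keeps
#' the leading run of features up to the largest drop between consecutive
#' sorted values; at least one feature is always returned. A constant
#' positive column has no gap: the full list is returned, flagged
#' non-discriminative via the `"discriminative"` attribute.
#'
#' @param B Non-negative basis matrix (or an `snmf_fit`).
#' @param component Column index `i` in `1..m`.
#' @return Character vector of feature (pathway) ids, descending by
#'   loading, with attributes `loadings` and `discriminative`.
#' @export
descriptive_features <- function(B, component) {
  if (inherits(B, "snmf_fit")) B <- B$B
  if (component < 1 || component > ncol(B)) {
    stop_input("component %d out of range [1, %d]", component, ncol(B))
  }
  v <- B[, component]
  nms <- rownames(B) %||% as.character(seq_along(v))
  if (all(v == 0)) {
    warn(sprintf("component %d is all zero; no descriptive features", component))
    out <- character(0)
    attr(out, "loadings") <- numeric(0)
    attr(out, "discriminative") <- FALSE
    return(out)
  }
  ord <- order(v, decreasing = TRUE)
  sv <- v[ord]
  gaps <- sv[-length(sv)] - sv[-1L]
  if (length(gaps) == 0L || max(gaps) <= 1e-12) {
    out <- nms[ord]
    attr(out, "loadings") <- unname(sv)
    attr(out, "discriminative") <- FALSE
    return(out)
  }
  keep <- which.max(gaps)  # first position of the largest drop
  out <- nms[ord[seq_len(keep)]]
  attr(out, "loadings") <- unname(sv[seq_len(keep)])
  attr(out, "discriminative") <- TRUE
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions up
#' to relabeling, expectation 0 under independent random labelings.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_input("label vectors differ in length (%d vs %d)",
               length(labels_a), length(labels_b))
  }
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
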