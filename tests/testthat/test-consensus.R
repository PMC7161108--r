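# block-structured non-negative matrix with planted patient clusters
planted_X <- function(n = 45, P = 12, m = 3, noise = 0.05, seed = 1) {
  set.seed(seed)
  lab <- rep(seq_len(m), length.out = n)
  X <- matrix(runif(P * n, 0, noise), P, n)
  for (c in seq_len(m)) {
    rows <- ((c - 1) * floor(P / m) + 1):(c * floor(P / m))
    X[rows, lab == c] <- X[rows, lab == c] + 1
  }
  colnames(X) <- sprintf("S%02d", seq_len(n))
  list(X = X, labels = lab)
}

test_that("duplicate patients always co-cluster and runs=2 quantizes C", {
  d <- planted_X(n = 20)
  X <- d$X
  X[, 2] <- X[, 1]  # exact duplicate column
  cons <- consensus_cluster(X, 2, runs = 10, seed = 3)
  expect_identical(cons$consensus[1, 2], 1)
  cons2 <- consensus_cluster(X, 2, runs = 2, seed = 3)
  expect_true(all(cons2$consensus %in% c(0, 0.5, 1)))
  expect_true(isSymmetric(cons2$consensus))
  expect_true(all(diag(cons2$consensus) == 1))
})

test_that("planted 3-block structure is recovered exactly", {
  d <- planted_X(seed = 5)
  cons <- consensus_cluster(d$X, 3, runs = 30, seed = 7)
  expect_identical(adjusted_rand_index(cons$labels, d$labels), 1)
  expect_gt(cons$cophenetic, 0.99)
  expect_gt(cons$silhouette_consensus, 0.9)
})

test_that("consensus is invariant to patient order up to the permutation", {
  d <- planted_X(n = 18, seed = 2)
  cons <- consensus_cluster(d$X, 3, runs = 20, seed = 9)
  perm <- sample(ncol(d$X))
  cons_p <- consensus_cluster(d$X[, perm], 3, runs = 20, seed = 9)
  expect_equal(unname(cons_p$consensus[order(perm), order(perm)]),
               unname(cons$consensus))
})

test_that("cophenetic correlation is exact on ultrametric input and bounded", {
  # perfect two-block consensus
  C <- rbind(cbind(matrix(1, 4, 4), matrix(0, 4, 4)),
             cbind(matrix(0, 4, 4), matrix(1, 4, 4)))
  diag(C) <- 1
  expect_equal(cophenetic_correlation(C), 1)

  set.seed(21)
  for (i in 1:20) {
    n <- 12
    M <- matrix(runif(n * n), n, n)
    C <- (M + t(M)) / 2
    diag(C) <- 1
    r <- cophenetic_correlation(C)
    expect_true(r >= -1 && r <= 1)
    # independent oracle: walk the merge tree for cophenetic distances
    hc <- hclust(as.dist(1 - C), method = "average")
    Do <- oracle_cophenetic_dist(hc)
    up <- upper.tri(C)
    expect_equal(r, cor((1 - C)[up], Do[up]), tolerance = 1e-10)
  }
  expect_error(cophenetic_correlation(matrix(0.5, 2, 2)), "n >= 3")
  expect_warning(r0 <- cophenetic_correlation(matrix(1, 4, 4)), "constant")
  expect_true(is.nan(r0))
})

test_that("silhouette follows the definition, singletons scoring zero", {
  # 1-D points {0,1} vs {10,11}
  x <- c(0, 1, 10, 11)
  D <- as.matrix(dist(x))
  s <- silhouette_index(c(1, 1, 2, 2), D)
  expect_equal(s$s[1], (10.5 - 1) / 10.5, tolerance = 1e-12)
  # singleton cluster
  s2 <- silhouette_index(c(1, 1, 2, 3), D)
  expect_identical(s2$s[4], 0)
  expect_error(silhouette_index(rep(1, 4), D), "single cluster")

  set.seed(13)
  for (i in 1:20) {
    n <- 25
    pts <- matrix(rnorm(n * 2), n)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    D <- as.matrix(dist(pts))
    expect_equal(silhouette_index(lab, D)$s, oracle_silhouette(lab, D)$s,
                 tolerance = 1e-12)
  }
})

test_that("rank selection bookkeeping and the null flag behave", {
  d <- planted_X(n = 24, P = 8, m = 2, seed = 4)
  rs <- select_rank(d$X, ranks = 2:3, beta_grid = c(0.01, 0.1), runs = 10,
                    n_perm = 3, seed = 6)
  # one real + n_perm permuted copheneties per (rank, beta)
  expect_identical(nrow(rs$diagnostics), 2L * 2L * (1L + 3L))
  expect_true(all(c("rank", "best_beta", "real_cophenetic", "null_upper",
                    "qualifies") %in% names(rs$summary)))
  expect_s3_class(tidy(rs), "tbl_df")

  # feeding permuted data as "real" should usually not resolve
  set.seed(10)
  Xp <- t(apply(d$X, 1, sample))
  rs_null <- select_rank(Xp, ranks = 2:3, beta_grid = 0.01, runs = 10,
                         n_perm = 5, seed = 8)
  expect_true(is.na(rs_null$selected) || rs_null$resolved)
})

test_that("failed restarts beyond 10% abort the consensus", {
  d <- planted_X(n = 15, seed = 3)
  X <- d$X
  X[1, 1] <- -1  # invalid input -> every restart fails
  expect_error(suppressWarnings(consensus_cluster(X, 2, runs = 5, seed = 1)),
               "restarts failed")
})
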