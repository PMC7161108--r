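test_that("exact Shapley recovers linear attributions and the axioms", {
  f_lin <- function(M) M[, 1] + 2 * M[, 2]
  phi <- exact_shapley(f_lin, c(3, 1), c(0, 0))
  expect_equal(unname(phi), c(3, 2), tolerance = 1e-12)

  # dummy axiom: a feature the function ignores gets exactly 0
  f_dummy <- function(M) M[, 1]^2
  phi_d <- exact_shapley(f_dummy, c(2, 5), c(0, 0))
  expect_identical(phi_d[2], 0)

  # efficiency on random nonlinear functions
  set.seed(17)
  for (i in 1:10) {
    p <- sample(2:6, 1)
    W <- matrix(rnorm(p * 3), p)
    f <- function(M) rowSums(tanh(M %*% W))
    x <- rnorm(p); bg <- rnorm(p)
    phi <- exact_shapley(f, x, bg)
    expect_lt(abs(sum(phi) - (f(matrix(x, 1)) - f(matrix(bg, 1)))), 1e-10)
  }

  # symmetry: exchangeable features get equal values
  f_sym <- function(M) tanh(M[, 1] + M[, 2]) + M[, 3]
  phi_s <- exact_shapley(f_sym, c(1, 1, 2), c(0, 0, 0))
  expect_equal(phi_s[1], phi_s[2], tolerance = 1e-12)

  expect_error(exact_shapley(f_lin, rnorm(16), rnorm(16)), "guard")
})

test_that("sampling estimator is exact for linear models and efficient", {
  view <- rank1_view(n = 15, p = 5, noise = 0.02)
  fit <- train_pathway_autoencoder(view, config = training_config(
    mini_batch_size = 4, lambda = 0, p_keep = 1, rho = 0.01, seed = 2,
    max_epochs = 80))
  x <- pathembed:::view_matrix(view)[1, ]
  bg <- colMeans(pathembed:::view_matrix(view))

  # a patient equal to the background deviates nowhere
  phi0 <- approx_shapley(fit, bg, n_samples = 10, seed = 1)
  expect_true(all(abs(phi0) < 1e-12))

  # efficiency holds exactly for the estimator (telescoping orderings)
  phi <- approx_shapley(fit, x, n_samples = 20, seed = 3)
  f <- pathembed:::ae_score_fun(fit$model)
  expect_lt(abs(sum(phi) - (f(matrix(x, 1)) - f(matrix(bg, 1)))), 1e-10)

  # exact match on a hand-built linear score (single weights, tanh ~ id range)
  arch <- pathembed:::ae_architecture(c(m = 2L), c(m = 1L))
  params <- pathembed:::ae_init_params(arch, seed = 1)
  for (nm in names(params)) params[[nm]][] <- 0
  params[["enc1.W.m"]][] <- c(0.01, 0.02)  # tiny weights: tanh ~ identity
  params[["enc2.W"]][] <- 1
  stats <- list(m = list(mean = c(0, 0), sd = c(1, 1)))
  model <- pathembed:::new_ae_model(arch, params, stats, list(m = c("a", "b")))
  xs <- c(0.5, -0.3)
  phi_a <- approx_shapley(model, xs, background = c(0, 0), n_samples = 4,
                          seed = 5)
  phi_e <- exact_shapley(pathembed:::ae_score_fun(model), xs, c(0, 0))
  expect_equal(unname(phi_a), unname(phi_e), tolerance = 1e-6)
})

test_that("sampling estimator tracks exact Shapley on a trained autoencoder", {
  view <- rank1_view(n = 18, p = 8, noise = 0.05, seed = 4)
  fit <- train_pathway_autoencoder(view, config = training_config(
    mini_batch_size = 4, seed = 6, max_epochs = 60))
  M <- pathembed:::view_matrix(view)
  bg <- colMeans(M)
  f <- pathembed:::ae_score_fun(fit$model)
  cors <- vapply(1:3, function(i) {
    pe <- exact_shapley(f, M[i, ], bg)
    pa <- approx_shapley(fit, M[i, ], n_samples = 200, seed = 30 + i)
    cor(pe, pa)
  }, 0)
  expect_true(all(cors >= 0.95))
})

test_that("aggregation takes mean absolute values per feature and modality", {
  phi <- matrix(c(-2, 1), 1, 2, dimnames = list("P1", c("m1:a", "m2:b")))
  agg <- aggregate_attributions(phi)
  expect_equal(agg$features$mean_abs_shap, c(2, 1))

  # mirrored patients aggregate like a single absolute row
  phi2 <- rbind(phi, -phi)
  rownames(phi2) <- c("P1", "P2")
  expect_equal(aggregate_attributions(phi2)$features$mean_abs_shap, c(2, 1))

  # permutation over patients changes nothing
  set.seed(3)
  phi3 <- matrix(rnorm(20), 5, 4,
                 dimnames = list(sprintf("P%d", 1:5),
                                 c("m1:a", "m1:b", "m2:c", "m2:d")))
  a1 <- aggregate_attributions(phi3)
  a2 <- aggregate_attributions(phi3[sample(5), ])
  expect_equal(a1, a2)
  expect_error(aggregate_attributions(phi3[, 0]), "empty")
})

test_that("a zero-weight modality branch receives zero attribution", {
  view <- tiny_view(n = 10)
  fit <- train_pathway_autoencoder(view, config = training_config(
    mini_batch_size = 4, seed = 3, max_epochs = 30))
  # silence modality m2's branch
  fit$model$params[["enc1.W.m2"]][] <- 0
  fit$model$params[["enc1.b.m2"]][] <- 0
  att <- attribute_pathway(fit, view, n_samples = 30, seed = 2)
  m2 <- att$modalities$mean_abs_shap[att$modalities$modality == "m2"]
  expect_lt(m2, 1e-12)
  expect_identical(dim(att$phi), c(10L, 7L))
  expect_s3_class(tidy(att), "tbl_df")
})

test_that("exact attribution of a small view ranks the planted driver first", {
  # feature 1 drives a rank-1 signal; the rest is noise
  set.seed(9)
  n <- 16
  M <- cbind(rnorm(n, sd = 3), matrix(rnorm(n * 4, sd = 0.3), n, 4))
  M[, 2] <- M[, 1] * 0.1 + rnorm(n, sd = 0.3)
  dimnames(M) <- list(sprintf("P%d", 1:n), sprintf("f%d", 1:5))
  view <- structure(
    list(pathway_id = "PWd", blocks = list(m1 = M), patients = rownames(M),
         p_j = c(m1 = 5L), k = 1L, n = n),
    class = "pathway_view"
  )
  fit <- train_pathway_autoencoder(view, config = training_config(
    mini_batch_size = 4, lambda = 0, p_keep = 1, rho = 0.01, seed = 8,
    max_epochs = 120))
  att <- attribute_pathway(fit, view, exact = TRUE)
  expect_identical(att$features$feature[1], "m1:f1")
})
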