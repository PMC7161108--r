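test_that("zero-weight model scores 0 and reconstructs the feature means", {
  view <- tiny_view()
  model <- zero_weight_model(view)
  out <- encode_decode(model, view)
  expect_equal(unname(out$score), rep(0, view$n))
  # inverse-standardized zeros are the per-feature training means
  for (mod in names(view$blocks)) {
    mu <- colMeans(view$blocks[[mod]])
    expect_equal(out$reconstruction[[mod]],
                 matrix(mu, view$n, length(mu), byrow = TRUE,
                        dimnames = dimnames(view$blocks[[mod]])))
  }
})

test_that("1-feature identity model has 0 as a fixed point", {
  arch <- pathembed:::ae_architecture(c(m = 1L))
  params <- pathembed:::ae_init_params(arch, seed = 1)
  params[["enc1.W.m"]][] <- 1; params[["enc2.W"]][] <- 1
  params[["dec1.W"]][] <- 1; params[["dec2.W.m"]][] <- 1
  for (nm in grep("\\.b", names(params), value = TRUE)) params[[nm]][] <- 0
  stats <- list(m = list(mean = 0, sd = 1))  # no normalization
  model <- pathembed:::new_ae_model(arch, params, stats, list(m = "f1"))
  out <- encode_decode(model, matrix(0, 1, 1))
  expect_equal(unname(out$score), 0)
  expect_equal(unname(drop(out$reconstruction$m)), 0)
})

test_that("forward pass matches a straight-line hand implementation", {
  view <- tiny_view(n = 5)
  arch <- pathembed:::ae_architecture(view$p_j, c(m1 = 2L, m2 = 1L))
  params <- pathembed:::ae_init_params(arch, seed = 9)
  stats <- pathembed:::ae_fit_stats(view$blocks)
  model <- pathembed:::new_ae_model(arch, params, stats,
                                    lapply(view$blocks, colnames))
  out <- encode_decode(model, view)

  # hand evaluation, one layer at a time
  z1 <- scale(view$blocks$m1)
  z2 <- sweep(sweep(view$blocks$m2, 2, stats$m2$mean), 2, stats$m2$sd, "/")
  a1 <- tanh(cbind(
    z1 %*% params[["enc1.W.m1"]] +
      matrix(params[["enc1.b.m1"]], 5, 2, byrow = TRUE),
    z2 %*% params[["enc1.W.m2"]] + params[["enc1.b.m2"]]
  ))
  sc <- tanh(a1 %*% params[["enc2.W"]] + params[["enc2.b"]])
  a3 <- tanh(sc %*% params[["dec1.W"]] +
               matrix(params[["dec1.b"]], 5, 3, byrow = TRUE))
  r1 <- a3[, 1:2] %*% params[["dec2.W.m1"]] +
    matrix(params[["dec2.b.m1"]], 5, 4, byrow = TRUE)
  r1 <- sweep(sweep(r1, 2, stats$m1$sd, "*"), 2, stats$m1$mean, "+")

  expect_equal(unname(out$score), unname(drop(sc)), tolerance = 1e-12)
  expect_equal(unname(out$reconstruction$m1), unname(r1), tolerance = 1e-12)
})

test_that("reconstruction loss follows the mean-over-patients definition", {
  view <- tiny_view()
  model <- zero_weight_model(view)
  # zero weights reconstruct standardized 0, so sigma = mean rowwise ||z||^2
  Xs <- pathembed:::ae_standardize(view$blocks, model$stats)
  expect_equal(reconstruction_loss(model, view),
               sum(vapply(Xs, function(M) sum(M^2), 0)) / view$n)

  # hand case: 1 patient, residuals (1,0) and (0,2) -> 1 + 4 = 5
  arch <- pathembed:::ae_architecture(c(a = 2L, b = 2L), c(a = 1L, b = 1L))
  params <- pathembed:::ae_init_params(arch, seed = 1)
  for (nm in names(params)) params[[nm]][] <- 0
  stats <- list(a = list(mean = c(0, 0), sd = c(1, 1)),
                b = list(mean = c(0, 0), sd = c(1, 1)))
  m <- pathembed:::new_ae_model(arch, params, stats,
                                list(a = c("x1", "x2"), b = c("y1", "y2")))
  expect_equal(reconstruction_loss(m, list(a = matrix(c(1, 0), 1),
                                           b = matrix(c(0, 2), 1))), 5)

  # duplicating every patient leaves the mean unchanged
  doubled <- lapply(view$blocks, function(M) M[rep(seq_len(nrow(M)), 2), ])
  expect_equal(reconstruction_loss(model, doubled),
               reconstruction_loss(model, view))

  expect_error(
    reconstruction_loss(model, lapply(view$blocks, function(M) M[0, , drop = FALSE])),
    "empty"
  )
})

test_that("sparse group lasso penalty matches its closed form", {
  view <- tiny_view()
  model <- zero_weight_model(view)
  expect_identical(sgl_penalty(model, 0, 0.5), 0)

  # single group, one weight w = 2, s_l = s_lsucc = 1:
  # 0.05 * (0.5 * sqrt(1) * 4 + 0.5 * 2) = 0.15
  arch1 <- pathembed:::ae_architecture(c(m = 1L))
  p1 <- pathembed:::ae_init_params(arch1, seed = 1)
  for (nm in names(p1)) p1[[nm]][] <- 0
  p1[["enc1.W.m"]][] <- 2
  m1 <- pathembed:::new_ae_model(arch1, p1, list(m = list(mean = 0, sd = 1)),
                                 list(m = "f"))
  expect_equal(sgl_penalty(m1, 0.1, 0.5), 0.15)

  # alpha = 1 recovers the plain lasso over every weight matrix
  params <- pathembed:::ae_init_params(model$architecture, seed = 4)
  model$params <- params
  wsum <- sum(vapply(
    pathembed:::ae_weight_names(params),
    function(nm) sum(abs(params[[nm]])), 0
  ))
  expect_equal(sgl_penalty(model, 0.2, 1), 0.1 * wsum)
  expect_error(sgl_penalty(model, 0.1, 1.2), "alpha")
})

test_that("analytic gradients match central finite differences", {
  # <= 30-parameter model: 2 modalities x 2 features, h = 1 each
  set.seed(5)
  blocks <- list(
    a = matrix(rnorm(12), 6, 2, dimnames = list(sprintf("P%d", 1:6), c("f1", "f2"))),
    b = matrix(rnorm(12, 3), 6, 2, dimnames = list(sprintf("P%d", 1:6), c("g1", "g2")))
  )
  arch <- pathembed:::ae_architecture(c(a = 2L, b = 2L), c(a = 1L, b = 1L))
  stats <- pathembed:::ae_fit_stats(blocks)
  Xs <- pathembed:::ae_standardize(blocks, stats)
  for (cfg in list(c(0, 0.5), c(0.05, 0), c(0.05, 0.7))) {
    lam <- cfg[1]; alp <- cfg[2]
    params <- pathembed:::ae_init_params(arch, seed = 11)
    g <- pathembed:::ae_gradient(params, arch, Xs, Xs, lam, alp)
    obj <- function(p) pathembed:::ae_objective(p, arch, Xs, Xs, lam, alp)
    for (nm in names(params)) {
      for (i in seq_along(params[[nm]])) {
        h <- 1e-5
        up <- params; up[[nm]][i] <- up[[nm]][i] + h
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
        fd <- (obj(up) - obj(dn)) / (2 * h)
        expect_lt(abs(fd - g[[nm]][i]) / max(1e-8, abs(fd), abs(g[[nm]][i])),
                  1e-4)
      }
    }
  }
})

test_that("objective with lambda = 0 is exactly half the reconstruction loss", {
  view <- tiny_view()
  arch <- pathembed:::ae_architecture(view$p_j)
  params <- pathembed:::ae_init_params(arch, seed = 2)
  stats <- pathembed:::ae_fit_stats(view$blocks)
  Xs <- pathembed:::ae_standardize(view$blocks, stats)
  expect_identical(
    pathembed:::ae_objective(params, arch, Xs, Xs, 0, 0.3),
    0.5 * pathembed:::ae_sigma(params, arch, Xs)
  )
})

test_that("modality branches are block-separated", {
  view <- tiny_view()
  arch <- pathembed:::ae_architecture(view$p_j, c(m1 = 2L, m2 = 1L))
  params <- pathembed:::ae_init_params(arch, seed = 3)
  stats <- pathembed:::ae_fit_stats(view$blocks)
  Xs <- pathembed:::ae_standardize(view$blocks, stats)
  zeroed <- Xs
  zeroed$m2[] <- 0
  a_full <- pathembed:::ae_forward(params, arch, Xs, encoder_only = TRUE)$A1
  a_zero <- pathembed:::ae_forward(params, arch, zeroed, encoder_only = TRUE)$A1
  expect_identical(a_full[, 1:2], a_zero[, 1:2])  # m1 units untouched
  expect_false(isTRUE(all.equal(a_full[, 3], a_zero[, 3])))
})

test_that("scores are per-patient and shape errors are caught", {
  view <- tiny_view()
  model <- zero_weight_model(view)
  # constant rows give equal scores
  const <- lapply(view$blocks, function(M) {
    M[] <- rep(M[1, ], each = nrow(M)); M
  })
  sc <- score_patients(model, const)
  expect_length(unique(round(sc, 12)), 1L)
  # permutation invariance
  perm <- sample(view$n)
  sc_perm <- score_patients(model, lapply(view$blocks, function(M) M[perm, ]))
  expect_equal(unname(sc_perm[order(perm)]), unname(score_patients(model, view)))
  expect_error(score_patients(model, matrix(0, 2, 3)), "columns")
  bad <- view$blocks
  bad$m1[1, 1] <- NA
  expect_error(score_patients(model, bad), "non-finite")
})

test_that("score matrix rows are min-max rescaled with the constant-row rule", {
  expect_equal(pathembed:::rescale_minmax(c(-1, 0, 1)), c(0, 0.5, 1))
  expect_equal(pathembed:::rescale_minmax(c(2, 2, 2)), c(0.5, 0.5, 0.5))
  view <- tiny_view()
  fits <- list(
    PW1 = train_pathway_autoencoder(view, config = training_config(
      mini_batch_size = 4, seed = 1, max_epochs = 5)),
    PW2 = train_pathway_autoencoder(view, config = training_config(
      mini_batch_size = 4, seed = 2, max_epochs = 5))
  )
  ps <- assemble_score_matrix(fits, list(PW1 = view, PW2 = view))
  expect_true(all(ps$scores >= 0 & ps$scores <= 1))
  expect_identical(dim(ps$scores), c(2L, as.integer(view$n)))
  td <- tidy(ps)
  expect_identical(nrow(td), as.integer(2L * view$n))
})
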