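test_that("training is deterministic given the seed", {
  view <- rank1_view()
  cfg <- training_config(mini_batch_size = 8, seed = 42, max_epochs = 40)
  f1 <- train_pathway_autoencoder(view, config = cfg)
  f2 <- train_pathway_autoencoder(view, config = cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training beats the constant-predictor baseline on rank-1 data", {
  view <- rank1_view(n = 20, p = 6)
  cfg <- training_config(mini_batch_size = 4, lambda = 0, p_keep = 1,
                         rho = 0.01, seed = 3, max_epochs = 200)
  fit <- train_pathway_autoencoder(view, config = cfg)
  baseline <- zero_weight_model(view)  # predicts the feature means
  stats <- baseline$stats
  Xs <- pathembed:::ae_standardize(view$blocks, stats)
  base_loss <- 0.5 * pathembed:::ae_sigma(baseline$params, baseline$architecture, Xs)
  expect_lt(fit$final_objective, base_loss)
})

test_that("loss trace is finite and the early stop waits out the patience", {
  view <- rank1_view()
  cfg <- training_config(mini_batch_size = 8, seed = 5, max_epochs = 400,
                         rho = 0.01, lambda = 0, p_keep = 1)
  fit <- train_pathway_autoencoder(view, config = cfg)
  tr <- fit$loss_trace
  expect_true(all(is.finite(tr)))
  expect_lte(length(tr), 400L)
  if (length(tr) < 400L) {
    # stopped early: exactly `patience` epochs after the last improvement
    run_min <- cummin(tr)
    improved <- c(TRUE, diff(run_min) < -1e-6 * pmax(head(run_min, -1), 1e-12))
    last_improvement <- max(which(improved))
    expect_identical(length(tr) - last_improvement, cfg$patience)
  }
  # running minimum is non-increasing by construction of the check above
  expect_true(all(diff(cummin(tr)) <= 0))
})

test_that("strong group penalty shrinks a pure-noise modality's input weights", {
  set.seed(8)
  n <- 40
  pats <- sprintf("P%02d", seq_len(n))
  u <- rnorm(n)
  signal <- outer(u, runif(6, 0.8, 1.2)) + matrix(rnorm(n * 6, sd = 0.05), n)
  noise <- matrix(rnorm(n * 6), n, 6)
  dimnames(signal) <- list(pats, sprintf("s%d", 1:6))
  dimnames(noise) <- list(pats, sprintf("n%d", 1:6))
  view <- structure(
    list(pathway_id = "PWs", blocks = list(sig = signal, noi = noise),
         patients = pats, p_j = c(sig = 6L, noi = 6L), k = 2L, n = n),
    class = "pathway_view"
  )
  fit <- train_pathway_autoencoder(view, config = training_config(
    mini_batch_size = 8, lambda = 10, alpha = 0, rho = 0.01, p_keep = 1,
    seed = 2, max_epochs = 300
  ))
  w_sig <- mean(abs(fit$model$params[["enc1.W.sig"]]))
  w_noi <- mean(abs(fit$model$params[["enc1.W.noi"]]))
  expect_lt(w_noi, w_sig)
})

test_that("tuner respects the search space and improves on a random draw", {
  view <- rank1_view(n = 20, p = 8, noise = 0.02)
  tuned <- tune_pathway_autoencoder(view, budget = 6, folds = 5, seed = 10,
                                    max_epochs = 40)
  hmax <- max(1L, view$p_j[["m1"]] %/% 2L)
  hs <- as.integer(tuned$history$hidden)
  expect_true(all(hs >= 1L & hs <= hmax))
  expect_identical(nrow(tuned$history), 6L)
  # best-of-search is no worse than the first (purely random) candidate
  expect_lte(tuned$cv_error, tuned$history$cv_error[1])

  one <- tune_pathway_autoencoder(view, budget = 1, folds = 5, seed = 1,
                                  max_epochs = 20)
  expect_identical(nrow(one$history), 1L)
  expect_identical(one$cv_error, one$history$cv_error[1])

  tiny <- rank1_view(n = 4)
  expect_error(tune_pathway_autoencoder(tiny, budget = 1, folds = 5),
               "fold")
})

test_that("training config validates its ranges", {
  expect_error(training_config(mini_batch_size = 7), "mini_batch_size")
  expect_error(training_config(alpha = 1.5), "alpha")
  expect_error(training_config(rho = 1), "rho")
  expect_error(training_config(p_keep = 0.2), "p_keep")
  expect_error(training_config(optimizer = "sgdx"))
})

test_that("all four SGD variants reduce the objective", {
  view <- rank1_view(n = 16, p = 6)
  for (opt in c("adam", "momentum", "rmsprop", "nadam")) {
    fit <- train_pathway_autoencoder(view, config = training_config(
      mini_batch_size = 8, optimizer = opt, rho = 0.01, lambda = 0,
      p_keep = 1, seed = 4, max_epochs = 60
    ))
    expect_lt(min(fit$loss_trace), fit$loss_trace[1])
  }
})
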