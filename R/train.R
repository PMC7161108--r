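#' Train the multi-modal sparse denoising autoencoder for one pathway
#'
#' Minimizes `F(W) = 0.5 * sigma(W) + sgl_penalty(W)` by mini-batch
#' stochastic gradient descent. Each mini-batch's standardized inputs are
#' corrupted by independent feature dropout (entries kept with probability
#' `p_keep`, otherwise set to the standardized zero); the reconstruction
#' target is the uncorrupted input. Training stops when the full-data
#' objective has not improved for `patience` consecutive epochs, or at
#' `max_epochs`; the parameters achieving the best objective are kept.
#' Fully deterministic given `config$seed`.
#'
#' @param view A `pathway_view` from [build_pathway_views()].
#' @param hidden Optional named vector of per-modality first-hidden sizes;
#'   defaults to the [ae_architecture()] default.
#' @param config A [training_config()].
#' @return An object of class `trained_pathway_model`: the fitted
#'   `ae_model` plus the training-loss trace, the config, and per-fold CV
#'   errors when produced by [tune_pathway_autoencoder()].
#' @export
train_pathway_autoencoder <- function(view, hidden = NULL,
                                      config = training_config()) {
  stopifnot(inherits(view, "pathway_view"))
  arch <- ae_architecture(view$p_j, hidden)
  stats <- ae_fit_stats(view$blocks)
  Xs <- ae_standardize(view$blocks, stats)
  fit <- ae_fit(arch, Xs, config)
  model <- new_ae_model(arch, fit$params, stats,
                        lapply(view$blocks, colnames), view$pathway_id)
  structure(
    list(
      model = model, loss_trace = fit$trace, config = config,
      cv_errors = NULL, epochs = length(fit$trace),
      final_objective = min(fit$trace)
    ),
    class = "trained_pathway_model"
  )
}

#' @export
print.trained_pathway_model <- function(x, ...) {
  cat(sprintf(
    "<trained_pathway_model> %s: %d epochs, objective %.5g\n",
    x$model$pathway_id, x$epochs, x$final_objective
  ))
  invisible(x)
}

#' @export
glance.trained_pathway_model <- function(x, ...) {
  tibble(
    pathway_id = x$model$pathway_id,
    epochs = x$epochs,
    objective = x$final_objective,
    cv_error = if (is.null(x$cv_errors)) NA_real_ else mean(x$cv_errors),
    lambda = x$config$lambda,
    alpha = x$config$alpha,
    optimizer = x$config$optimizer
  )
}

# core SGD loop (compiled); deterministic given config$seed.
# Weight init and all stochastic draws (shuffling, dropout masks) use the
# R RNG, so identical seeds give identical loss traces.
ae_fit <- function(arch, Xs, config) {
  set.seed(config$seed)
  params <- ae_init_params(arch)
  res <- tryCatch(
    ae_fit_cpp(
      unname(Xs[arch$modalities]), params, arch$modalities,
      unname(arch$p_j), unname(arch$h_j),
      config$mini_batch_size, config$lambda, config$alpha, config$rho,
      config$p_keep, config$optimizer, config$max_epochs, config$patience
    ),
    error = function(e) {
      if (grepl("diverged", conditionMessage(e))) {
        abort(conditionMessage(e), class = "pathembed_divergence_error")
      }
      stop(e)
    }
  )
  out <- res$params[names(params)]
  # restore vector/scalar shapes the R forward pass expects
  for (nm in names(out)) {
    if (is.matrix(params[[nm]]) && !is.matrix(out[[nm]])) {
      out[[nm]] <- matrix(out[[nm]], nrow(params[[nm]]), ncol(params[[nm]]))
    }
  }
  list(params = out, trace = res$trace)
}
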