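#' Multi-modal autoencoder architecture
#'
#' Defines the branch structure of the pathway autoencoder: each omics
#' modality j with p_j input features is encoded by a dense modality-private
#' layer into h_j units (1 <= h_j <= floor(p_j/2), h_j = 1 when p_j = 1),
#' all first-layer units are then densely combined into a single shared
#' bottleneck unit whose tanh activation is the pathway score. The decoder
#' mirrors the encoder laterally. Hidden activations are tanh; the final
#' reconstruction layer is linear on the standardized scale.
#'
#' @param p_j Named integer vector of per-modality input sizes.
#' @param h_j Named integer vector of per-modality first-hidden sizes;
#'   defaults to `pmax(1, floor(p_j/4))`.
#' @return An `ae_architecture` object.
#' @export
ae_architecture <- function(p_j, h_j = NULL) {
  if (is.null(names(p_j)) || any(!nzchar(names(p_j)))) {
    stop_input("p_j must be a named vector (one entry per modality)")
  }
  mods <- names(p_j)
  p_j <- setNames(as.integer(p_j), mods)
  if (any(p_j < 1L)) stop_input("all modalities need at least one feature")
  h_max <- pmax(1L, p_j %/% 2L)
  if (is.null(h_j)) h_j <- pmax(1L, p_j %/% 4L)
  if (length(h_j) != length(p_j)) stop_input("h_j must match p_j in length")
  if (!is.null(names(h_j)) && !identical(sort(names(h_j)), sort(mods))) {
    stop_input("h_j names must match p_j names")
  }
  if (!is.null(names(h_j))) h_j <- h_j[mods]
  h_j <- setNames(as.integer(h_j), mods)
  if (any(h_j < 1L) || any(h_j > h_max)) {
    stop_input("h_j must satisfy 1 <= h_j <= max(1, floor(p_j/2))")
  }
  structure(
    list(modalities = names(p_j), p_j = p_j, h_j = h_j, bottleneck = 1L),
    class = "ae_architecture"
  )
}

#' Training configuration for the pathway autoencoder
#'
#' @param mini_batch_size One of 4, 8, 16, 32.
#' @param lambda Sparse-group-lasso weight (>= 0; 0 switches the penalty
#'   off). The hyper-parameter search explores `[1e-9, 1e-1]`.
#' @param alpha Convex mix between the modality-group term (`alpha = 0`)
#'   and the per-weight lasso term (`alpha = 1`).
#' @param rho Learning rate, in `[1e-5, 1e-1]`.
#' @param p_keep Input retention probability of the denoising corruption,
#'   in `[0.5, 1]`; each mini-batch input entry is kept with probability
#'   `p_keep` and otherwise set to the standardized zero (feature mean).
#' @param optimizer One of `"adam"`, `"momentum"`, `"rmsprop"`, `"nadam"`.
#' @param max_epochs Maximum training epochs.
#' @param patience Early stopping: training stops once the full-data
#'   objective has not improved (relative decrease >= 1e-6) for this many
#'   consecutive epochs.
#' @param seed Integer seed; training is fully deterministic given it.
#' @return A `training_config` object.
#' @export
training_config <- function(mini_batch_size = 16, lambda = 1e-4, alpha = 0.5,
                            rho = 1e-2, p_keep = 0.9, optimizer = "adam",
                            max_epochs = 500, patience = 20, seed = 1) {
  if (!mini_batch_size %in% c(4, 8, 16, 32)) {
    stop_input("mini_batch_size must be one of 4, 8, 16, 32")
  }
  if (lambda < 0) stop_input("lambda must be >= 0")  # tuner searches [1e-9, 1e-1]
  if (alpha < 0 || alpha > 1) stop_input("alpha must lie in [0, 1]")
  if (rho < 1e-5 || rho > 1e-1) stop_input("rho must lie in [1e-5, 1e-1]")
  if (p_keep < 0.5 || p_keep > 1) stop_input("p_keep must lie in [0.5, 1]")
  optimizer <- match.arg(optimizer, c("adam", "momentum", "rmsprop", "nadam"))
  structure(
    list(
      mini_batch_size = as.integer(mini_batch_size), lambda = lambda,
      alpha = alpha, rho = rho, p_keep = p_keep, optimizer = optimizer,
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

# ---- parameters ------------------------------------------------------------

# params is a flat named list of matrices/vectors:
#   enc1.W.<mod> (p_j x h_j), enc1.b.<mod> (h_j)
#   enc2.W (H x 1), enc2.b (1)
#   dec1.W (1 x H), dec1.b (H)
#   dec2.W.<mod> (h_j x p_j), dec2.b.<mod> (p_j)
ae_init_params <- function(arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  uinit <- function(nr, nc) {
    r <- 1 / sqrt(nr)  # symmetric uniform fan-in scaling
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  params <- list()
  H <- sum(arch$h_j)
  for (mod in arch$modalities) {
    p <- arch$p_j[[mod]]; h <- arch$h_j[[mod]]
    params[[paste0("enc1.W.", mod)]] <- uinit(p, h)
    params[[paste0("enc1.b.", mod)]] <- numeric(h)
    params[[paste0("dec2.W.", mod)]] <- uinit(h, p)
    params[[paste0("dec2.b.", mod)]] <- numeric(p)
  }
  params[["enc2.W"]] <- uinit(H, 1L)
  params[["enc2.b"]] <- 0
  params[["dec1.W"]] <- uinit(1L, H)
  params[["dec1.b"]] <- numeric(H)
  params
}

ae_weight_names <- function(params) {
  names(params)[grepl("\\.W(\\.|$)", names(params))]
}

# column index ranges of each modality inside the concatenated hidden layer
ae_hidden_index <- function(arch) {
  ends <- cumsum(arch$h_j)
  starts <- c(1L, head(ends, -1L) + 1L)
  stats::setNames(Map(seq.int, starts, ends), arch$modalities)
}

# Forward pass on standardized per-modality matrices (each n x p_j).
# Returns activations needed for backprop.
ae_forward <- function(params, arch, Xs, encoder_only = FALSE) {
  n <- nrow(Xs[[1L]])
  A1 <- matrix(0, n, sum(arch$h_j))
  idx <- ae_hidden_index(arch)
  for (mod in arch$modalities) {
    S1 <- Xs[[mod]] %*% params[[paste0("enc1.W.", mod)]]
    S1 <- sweep(S1, 2L, params[[paste0("enc1.b.", mod)]], "+")
    A1[, idx[[mod]]] <- tanh(S1)
  }
  score <- tanh(A1 %*% params[["enc2.W"]] + params[["enc2.b"]])
  if (encoder_only) {
    return(list(score = drop(score), A1 = A1))
  }
  A3 <- tanh(score %*% params[["dec1.W"]] +
               matrix(params[["dec1.b"]], n, sum(arch$h_j), byrow = TRUE))
  Z <- list()
  for (mod in arch$modalities) {
    Zm <- A3[, idx[[mod]], drop = FALSE] %*% params[[paste0("dec2.W.", mod)]]
    Z[[mod]] <- sweep(Zm, 2L, params[[paste0("dec2.b.", mod)]], "+")
  }
  list(score = drop(score), A1 = A1, A3 = A3, Z = Z, score_mat = score)
}

# Mean over patients of summed per-modality squared reconstruction errors
# (standardized scale): sigma(W) of the training objective.
ae_sigma <- function(params, arch, Xs_in, Xs_target = Xs_in) {
  fw <- ae_forward(params, arch, Xs_in)
  n <- nrow(Xs_in[[1L]])
  s <- 0
  for (mod in arch$modalities) {
    s <- s + sum((fw$Z[[mod]] - Xs_target[[mod]])^2)
  }
  s / n
}

# Sparse group lasso penalty on a params list.
ae_penalty <- function(params, arch, lambda, alpha) {
  if (alpha < 0 || alpha > 1) stop_input("alpha must lie in [0, 1]")
  if (lambda < 0) stop_input("lambda must be >= 0")
  if (lambda == 0) return(0)
  group <- 0
  for (mod in arch$modalities) {
    W <- params[[paste0("enc1.W.", mod)]]
    group <- group + sqrt(arch$p_j[[mod]] * arch$h_j[[mod]]) * sum(W^2)
  }
  l1 <- sum(vapply(ae_weight_names(params), function(nm) sum(abs(params[[nm]])), 0))
  (lambda / 2) * ((1 - alpha) * group + alpha * l1)
}

# Full objective F(W) = 0.5 * sigma + penalty.
ae_objective <- function(params, arch, Xs_in, Xs_target, lambda, alpha) {
  0.5 * ae_sigma(params, arch, Xs_in, Xs_target) +
    ae_penalty(params, arch, lambda, alpha)
}

# Analytic gradient of the full objective with respect to every parameter.
# l1 term uses the subgradient sign(W) (0 at 0).
ae_gradient <- function(params, arch, Xs_in, Xs_target, lambda, alpha) {
  n <- nrow(Xs_in[[1L]])
  idx <- ae_hidden_index(arch)
  fw <- ae_forward(params, arch, Xs_in)
  g <- list()

  dA3 <- matrix(0, n, sum(arch$h_j))
  for (mod in arch$modalities) {
    dZ <- (fw$Z[[mod]] - Xs_target[[mod]]) / n
    A3m <- fw$A3[, idx[[mod]], drop = FALSE]
    g[[paste0("dec2.W.", mod)]] <- crossprod(A3m, dZ)
    g[[paste0("dec2.b.", mod)]] <- colSums(dZ)
    dA3[, idx[[mod]]] <- dZ %*% t(params[[paste0("dec2.W.", mod)]])
  }
  dS3 <- dA3 * (1 - fw$A3^2)
  g[["dec1.W"]] <- crossprod(fw$score_mat, dS3)
  g[["dec1.b"]] <- colSums(dS3)
  dscore <- dS3 %*% t(params[["dec1.W"]])
  dS2 <- dscore * (1 - fw$score_mat^2)
  g[["enc2.W"]] <- crossprod(fw$A1, dS2)
  g[["enc2.b"]] <- sum(dS2)
  dA1 <- dS2 %*% t(params[["enc2.W"]])
  dS1 <- dA1 * (1 - fw$A1^2)
  for (mod in arch$modalities) {
    dS1m <- dS1[, idx[[mod]], drop = FALSE]
    g[[paste0("enc1.W.", mod)]] <- crossprod(Xs_in[[mod]], dS1m)
    g[[paste0("enc1.b.", mod)]] <- colSums(dS1m)
  }

  if (lambda > 0) {
    for (mod in arch$modalities) {
      nm <- paste0("enc1.W.", mod)
      g[[nm]] <- g[[nm]] + lambda * (1 - alpha) *
        sqrt(arch$p_j[[mod]] * arch$h_j[[mod]]) * params[[nm]]
    }
    for (nm in ae_weight_names(params)) {
      g[[nm]] <- g[[nm]] + (lambda / 2) * alpha * sign(params[[nm]])
    }
  }
  g[names(params)]
}

# ---- standardization -------------------------------------------------------

# per-feature z-score statistics per modality; constant features get sd 1
ae_fit_stats <- function(blocks) {
  lapply(blocks, function(B) {
    mu <- colMeans(B)
    s <- apply(B, 2L, sd)
    s[!is.finite(s) | s < 1e-12] <- 1
    list(mean = mu, sd = s)
  })
}

ae_standardize <- function(blocks, stats) {
  out <- lapply(names(blocks), function(mod) {
    st <- stats[[mod]]
    sweep(sweep(blocks[[mod]], 2L, st$mean, "-"), 2L, st$sd, "/")
  })
  names(out) <- names(blocks)
  out
}

ae_destandardize <- function(blocks, stats) {
  out <- lapply(names(blocks), function(mod) {
    st <- stats[[mod]]
    sweep(sweep(blocks[[mod]], 2L, st$sd, "*"), 2L, st$mean, "+")
  })
  names(out) <- names(blocks)
  out
}

# ---- model surface ---------------------------------------------------------

new_ae_model <- function(arch, params, stats, features, pathway_id = NA_character_) {
  structure(
    list(
      architecture = arch, params = params, stats = stats,
      features = features, pathway_id = pathway_id
    ),
    class = "ae_model"
  )
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf(
    "<ae_model> pathway %s: modalities %s -> bottleneck 1\n",
    x$pathway_id,
    paste(sprintf("%s(%d->%d)", x$architecture$modalities,
                  x$architecture$p_j, x$architecture$h_j), collapse = ", ")
  ))
  invisible(x)
}

# coerce input (view / named list of matrices / concatenated matrix or
# vector) to the model's per-modality block list, validating features
ae_blocks_from_input <- function(model, x) {
  arch <- model$architecture
  if (inherits(x, "pathway_view")) x <- x$blocks
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.matrix(x)) {
    if (ncol(x) != sum(arch$p_j)) {
      stop_input("input has %d columns; model expects %d", ncol(x), sum(arch$p_j))
    }
    ends <- cumsum(arch$p_j); starts <- c(1L, head(ends, -1L) + 1L)
    x <- setNames(
      Map(function(a, b) x[, a:b, drop = FALSE], starts, ends),
      arch$modalities
    )
  }
  if (!setequal(names(x), arch$modalities)) {
    stop_input("input modalities do not match the model's (%s)",
               paste(arch$modalities, collapse = ", "))
  }
  for (mod in arch$modalities) {
    B <- x[[mod]]
    if (ncol(B) != arch$p_j[[mod]]) {
      stop_input("modality %s: %d features supplied, model expects %d",
                 mod, ncol(B), arch$p_j[[mod]])
    }
    if (!is.null(colnames(B)) && !is.null(model$features[[mod]]) &&
        !identical(colnames(B), model$features[[mod]])) {
      stop_input("modality %s: feature names/order differ from training", mod)
    }
    if (any(!is.finite(B))) stop_input("non-finite values in modality %s", mod)
  }
  x[arch$modalities]
}

#' Encode and decode patients through a pathway autoencoder
#'
#' Runs the full forward pass in evaluation mode (no input corruption):
#' inputs are standardized with the model's stored training statistics,
#' the bottleneck tanh activation is the pathway score, and the
#' reconstruction is mapped back to original units via the inverse
#' standardization.
#'
#' @param model An `ae_model` (e.g. from [train_pathway_autoencoder()]).
#' @param x A `pathway_view`, a named list of per-modality matrices, a
#'   concatenated numeric matrix, or a single concatenated feature vector.
#' @return List with `score` (numeric vector in (-1, 1)) and
#'   `reconstruction` (named list of per-modality matrices, original units).
#' @export
encode_decode <- function(model, x) {
  blocks <- ae_blocks_from_input(model, x)
  Xs <- ae_standardize(blocks, model$stats)
  fw <- ae_forward(model$params, model$architecture, Xs)
  rec <- ae_destandardize(fw$Z, model$stats)
  for (mod in names(rec)) dimnames(rec[[mod]]) <- dimnames(blocks[[mod]])
  list(score = setNames(fw$score, rownames(blocks[[1L]])), reconstruction = rec)
}

#' Reconstruction loss of a batch of patients
#'
#' Mean over patients of the summed per-modality squared reconstruction
#' errors, computed on the standardized scale so modalities with different
#' numeric ranges contribute comparably.
#'
#' @inheritParams encode_decode
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(model, x) {
  blocks <- ae_blocks_from_input(model, x)
  if (nrow(blocks[[1L]]) == 0L) stop_input("batch of patients is empty")
  Xs <- ae_standardize(blocks, model$stats)
  ae_sigma(model$params, model$architecture, Xs)
}

#' Sparse group lasso penalty of a model
#'
#' `(lambda/2) * ((1 - alpha) * sum_j sqrt(p_j * h_j) * sum(W_j^2) +
#' alpha * sum |W|)`, where the group term runs over the modality-private
#' input weight blocks and the lasso term over every encoder and decoder
#' weight matrix. Biases are unpenalized. `alpha = 1` recovers the plain
#' lasso, `alpha = 0` the group penalty.
#'
#' @param model An `ae_model`.
#' @param lambda Penalty weight (>= 0).
#' @param alpha Mixing parameter in `[0, 1]`.
#' @return Non-negative scalar.
#' @export
sgl_penalty <- function(model, lambda, alpha) {
  ae_penalty(model$params, model$architecture, lambda, alpha)
}

#' Pathway scores for a set of patients
#'
#' Bottleneck activations in evaluation mode (no dropout), one per patient.
#'
#' @inheritParams encode_decode
#' @return Named numeric vector of scores in (-1, 1).
#' @export
score_patients <- function(model, x) {
  blocks <- ae_blocks_from_input(model, x)
  Xs <- ae_standardize(blocks, model$stats)
  fw <- ae_forward(model$params, model$architecture, Xs, encoder_only = TRUE)
  setNames(fw$score, rownames(blocks[[1L]]))
}
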