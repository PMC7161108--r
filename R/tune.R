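# ---- search space ----------------------------------------------------------
# numeric dims are searched on a transformed scale (log10 for lambda/rho)

tune_space <- function(arch) {
  dims <- list(
    lambda = list(type = "num", lo = -9, hi = -1, trans = function(z) 10^z),
    rho    = list(type = "num", lo = -5, hi = -1, trans = function(z) 10^z),
    alpha  = list(type = "num", lo = 0, hi = 1, trans = identity),
    p_keep = list(type = "num", lo = 0.5, hi = 1, trans = identity),
    mini_batch_size = list(type = "cat", levels = c(4, 8, 16, 32)),
    optimizer = list(type = "cat", levels = c("adam", "momentum", "rmsprop", "nadam"))
  )
  for (mod in arch$modalities) {
    hmax <- max(1L, arch$p_j[[mod]] %/% 2L)
    dims[[paste0("h.", mod)]] <-
      list(type = "int", lo = 1, hi = hmax, trans = identity)
  }
  dims
}

tune_sample_prior <- function(space) {
  lapply(space, function(d) {
    switch(d$type,
      num = runif(1, d$lo, d$hi),
      int = sample(seq.int(d$lo, d$hi), 1L),
      cat = sample(seq_along(d$levels), 1L)
    )
  })
}

# Parzen-window density score of value z under observations obs (internal scale)
tpe_bw <- function(obs, lo, hi) {
  s <- if (length(obs) > 1L) stats::sd(obs) else 0
  max(s * 1.06 * length(obs)^(-0.2), (hi - lo) / 20, 1e-9)
}

tpe_kde_logd <- function(z, obs, lo, hi) {
  log(mean(stats::dnorm(z, mean = obs, sd = tpe_bw(obs, lo, hi))) + 1e-300)
}

tpe_propose <- function(space, hist_x, hist_y, n_cand = 24L) {
  gamma <- max(1L, ceiling(0.25 * length(hist_y)))
  ord <- order(hist_y)
  good <- ord[seq_len(gamma)]
  bad <- setdiff(seq_along(hist_y), good)
  if (length(bad) == 0L) bad <- good

  best_score <- -Inf
  best_x <- NULL
  for (cand in seq_len(n_cand)) {
    x <- list()
    score <- 0
    for (nm in names(space)) {
      d <- space[[nm]]
      og <- vapply(hist_x[good], function(h) as.numeric(h[[nm]]), 0)
      ob <- vapply(hist_x[bad], function(h) as.numeric(h[[nm]]), 0)
      if (d$type == "cat") {
        k <- length(d$levels)
        pg <- (tabulate(og, k) + 1) / (length(og) + k)
        pb <- (tabulate(ob, k) + 1) / (length(ob) + k)
        z <- sample.int(k, 1L, prob = pg)
        score <- score + log(pg[z]) - log(pb[z])
      } else {
        z <- stats::rnorm(1, mean = og[sample.int(length(og), 1L)],
                          sd = tpe_bw(og, d$lo, d$hi))
        z <- min(max(z, d$lo), d$hi)
        if (d$type == "int") z <- round(z)
        score <- score + tpe_kde_logd(z, og, d$lo, d$hi) -
          tpe_kde_logd(z, ob, d$lo, d$hi)
      }
      x[[nm]] <- z
    }
    if (score > best_score) {
      best_score <- score
      best_x <- x
    }
  }
  best_x
}

tune_decode <- function(space, x, arch, max_epochs, seed) {
  val <- function(nm) {
    d <- space[[nm]]
    if (d$type == "cat") d$levels[[x[[nm]]]] else d$trans(x[[nm]])
  }
  hidden <- vapply(arch$modalities, function(mod) {
    as.integer(round(val(paste0("h.", mod))))
  }, 1L)
  names(hidden) <- arch$modalities
  cfg <- training_config(
    mini_batch_size = as.numeric(val("mini_batch_size")),
    lambda = val("lambda"), alpha = val("alpha"), rho = val("rho"),
    p_keep = val("p_keep"), optimizer = as.character(val("optimizer")),
    max_epochs = max_epochs, seed = seed
  )
  list(config = cfg, hidden = hidden)
}

# mean held-out reconstruction error over CV folds (standardized scale,
# standardization statistics fitted on the training fold only)
tune_cv_error <- function(view, hidden, config, fold_id) {
  errs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    blocks_tr <- lapply(view$blocks, function(B) B[tr, , drop = FALSE])
    blocks_te <- lapply(view$blocks, function(B) B[te, , drop = FALSE])
    arch <- ae_architecture(view$p_j, hidden)
    stats <- ae_fit_stats(blocks_tr)
    fit <- ae_fit(arch, ae_standardize(blocks_tr, stats), config)
    ae_sigma(fit$params, arch, ae_standardize(blocks_te, stats))
  }, 0)
  mean(errs)
}

#' Bayesian hyper-parameter optimization for a pathway autoencoder
#'
#' Searches mini-batch size, the sparse-group-lasso weights `lambda` and
#' `alpha`, learning rate `rho`, input retention probability `p_keep`, the
#' SGD variant, and the per-modality first-hidden sizes (each in
#' `[1, floor(p_j/2)]`) with a tree-structured Parzen estimator. Each
#' candidate is scored by the mean held-out reconstruction error of a
#' k-fold cross-validation; `lambda` and `rho` are searched on a log scale.
#' Deterministic given `seed`.
#'
#' @param view A `pathway_view`.
#' @param budget Number of configurations to evaluate (default 50).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling fold splits, the sampler, and
#'   training seeds.
#' @param max_epochs Per-training epoch cap used during the search.
#' @param n_startup Random configurations before the Parzen model kicks in.
#' @return List with `config` (best [training_config()]), `hidden` (best
#'   per-modality hidden sizes), `cv_error`, and `history` (tibble of all
#'   evaluations).
#' @export
tune_pathway_autoencoder <- function(view, budget = 50L, folds = 5L, seed = 1L,
                                     max_epochs = 500L,
                                     n_startup = max(4L, budget %/% 4L)) {
  stopifnot(inherits(view, "pathway_view"))
  if (view$n < folds) {
    stop_input("n = %d patients < %d folds; use a smaller fold count",
               view$n, folds)
  }
  arch0 <- ae_architecture(view$p_j)
  space <- tune_space(arch0)

  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = view$n))

  hist_x <- list()
  hist_y <- numeric(0)
  rows <- vector("list", budget)
  for (i in seq_len(budget)) {
    x <- if (i <= n_startup || length(hist_y) < 2L) {
      tune_sample_prior(space)
    } else {
      tpe_propose(space, hist_x, hist_y)
    }
    dec <- tune_decode(space, x, arch0, max_epochs, seed = seed + i)
    err <- tryCatch(
      tune_cv_error(view, dec$hidden, dec$config, fold_id),
      pathembed_divergence_error = function(e) Inf
    )
    hist_x[[i]] <- x
    hist_y[i] <- err
    rows[[i]] <- tibble(
      eval = i, cv_error = err,
      lambda = dec$config$lambda, alpha = dec$config$alpha,
      rho = dec$config$rho, p_keep = dec$config$p_keep,
      mini_batch_size = dec$config$mini_batch_size,
      optimizer = dec$config$optimizer,
      hidden = paste(dec$hidden, collapse = ",")
    )
  }
  best <- which.min(hist_y)
  dec <- tune_decode(space, hist_x[[best]], arch0, max_epochs, seed = seed + best)
  list(
    config = dec$config, hidden = dec$hidden, cv_error = hist_y[best],
    history = dplyr::bind_rows(rows)
  )
}
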