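# Shared fixture builders. Everything is generated in code at test time.

# small deterministic two-modality view (n patients, p1 + p2 features)
tiny_view <- function(n = 12, p1 = 4, p2 = 3, seed = 1) {
  set.seed(seed)
  pats <- sprintf("P%02d", seq_len(n))
  b1 <- matrix(rnorm(n * p1), n, p1,
               dimnames = list(pats, sprintf("g%02d", seq_len(p1))))
  b2 <- matrix(rnorm(n * p2, mean = 5, sd = 2), n, p2,
               dimnames = list(pats, sprintf("h%02d", seq_len(p2))))
  structure(
    list(
      pathway_id = "PWx",
      blocks = list(m1 = b1, m2 = b2),
      patients = pats,
      p_j = c(m1 = p1, m2 = p2),
      k = 2L, n = n
    ),
    class = "pathway_view"
  )
}

# single-modality rank-1 view: x_i = u_i * v + small noise
rank1_view <- function(n = 20, p = 6, noise = 0.05, seed = 2) {
  set.seed(seed)
  pats <- sprintf("P%02d", seq_len(n))
  u <- rnorm(n)
  v <- runif(p, 0.5, 1.5)
  M <- outer(u, v) + matrix(rnorm(n * p, sd = noise), n, p)
  dimnames(M) <- list(pats, sprintf("f%02d", seq_len(p)))
  structure(
    list(pathway_id = "PWr", blocks = list(m1 = M), patients = pats,
         p_j = c(m1 = p), k = 1L, n = n),
    class = "pathway_view"
  )
}

# small synthetic study for module tests (fast)
small_study <- function(seed = 7) {
  generate_synthetic_study(synthetic_config(
    n = 60, m_true = 2, proportions = c(0.5, 0.5), P = 6, n_informative = 2,
    genes_per_pathway = 10,
    features = c(mrna = 8L, mirna = 4L, meth = 8L),
    noise_sd = c(mrna = 2, mirna = 1, meth = 1),
    location = c(mrna = 8, mirna = 4, meth = 0),
    effect_size = 4, hazard_ratios = c(1, 3), seed = seed
  ))
}

# hand-rolled zero-weight model over a view (standardization from the view)
zero_weight_model <- function(view) {
  arch <- pathembed:::ae_architecture(view$p_j)
  params <- pathembed:::ae_init_params(arch, seed = 1)
  for (nm in names(params)) params[[nm]][] <- 0
  stats <- pathembed:::ae_fit_stats(view$blocks)
  pathembed:::new_ae_model(arch, params, stats, lapply(view$blocks, colnames),
                           view$pathway_id)
}

# brute-force silhouette, straight from the definition (double loop)
oracle_silhouette <- function(labels, D) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  list(s = s, mean = mean(s))
}

# brute-force cophenetic distances by walking the merge tree
oracle_cophenetic_dist <- function(hc) {
  n <- length(hc$order)
  members <- lapply(seq_len(n), identity)
  D <- matrix(0, n, n)
  for (k in seq_len(nrow(hc$merge))) {
    left <- hc$merge[k, 1]
    right <- hc$merge[k, 2]
    a <- if (left < 0) -left else members[[n + left]]
    b <- if (right < 0) -right else members[[n + right]]
    for (i in a) for (j in b) D[i, j] <- D[j, i] <- hc$height[k]
    members[[n + k]] <- c(a, b)
  }
  D
}

# brute-force adjusted Rand index by enumerating all point pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# brute-force Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Kruskal-Wallis statistic from ranks (no-tie formula)
oracle_kruskal_stat <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri))^2)) - 3 * (n + 1)
}
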