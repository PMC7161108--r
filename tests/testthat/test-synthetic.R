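test_that("generation is byte-identical under a fixed seed", {
  s1 <- generate_synthetic_study(synthetic_config(n = 40, P = 4, n_informative = 2, seed = 5))
  s2 <- generate_synthetic_study(synthetic_config(n = 40, P = 4, n_informative = 2, seed = 5))
  expect_identical(s1, s2)
  s3 <- generate_synthetic_study(synthetic_config(n = 40, P = 4, n_informative = 2, seed = 6))
  expect_false(identical(s1$blocks$mrna$values, s3$blocks$mrna$values))
})

test_that("planted signal is strong enough for a k-means baseline", {
  study <- generate_synthetic_study(synthetic_config(seed = 2))
  drivers <- do.call(cbind, lapply(names(study$driver_features), function(k) {
    mod <- sub("\\..*$", "", k)
    study$blocks[[mod]]$values[, study$driver_features[[k]], drop = FALSE]
  }))
  km <- kmeans(scale(drivers), centers = 3, nstart = 10)
  expect_gte(adjusted_rand_index(km$cluster, study$labels), 0.9)
})

test_that("zero effect size carries no cluster signal", {
  study <- generate_synthetic_study(synthetic_config(
    n = 90, P = 4, n_informative = 2, effect_size = 0, seed = 3
  ))
  M <- scale(study$blocks$mrna$values)
  km <- kmeans(M, centers = 3, nstart = 5)
  expect_lt(abs(adjusted_rand_index(km$cluster, study$labels)), 0.05)
})

test_that("driver cluster means sit at the configured shifts", {
  cfg <- synthetic_config(seed = 8)
  study <- generate_synthetic_study(cfg)
  pw <- study$informative_pathways[1]
  drv <- study$driver_features[[paste0("mrna.", pw)]]
  M <- study$blocks$mrna$values[, drv, drop = FALSE]
  sdv <- cfg$noise_sd[["mrna"]]
  for (c in 1:3) {
    got <- mean(M[study$labels == c, ]) - cfg$location[["mrna"]]
    n_c <- sum(study$labels == c) * length(drv)
    # planted level is one of -1, 0, 1 (x effect x sd), unknown permutation
    lvl <- cfg$effect_size * sdv * c(-1, 0, 1)
    expect_lt(min(abs(got - lvl)), 3 * sdv / sqrt(n_c))
  }
})

test_that("modalities have heterogeneous ranges and meth is bounded", {
  study <- small_study()
  expect_true(all(study$blocks$meth$values >= 0 & study$blocks$meth$values <= 1))
  expect_gt(mean(study$blocks$mrna$values), mean(study$blocks$mirna$values))
})

test_that("censoring lands near its target across seeds", {
  fr <- vapply(1:5, function(s) {
    st <- generate_synthetic_study(synthetic_config(n = 200, P = 2,
                                                    n_informative = 1, seed = s))
    mean(st$clinical$os_event == 0)
  }, 0)
  expect_true(all(abs(fr - 0.3) < 0.1))
})

test_that("mutation enrichment raises the planted cluster-pathway rate", {
  study <- generate_synthetic_study(synthetic_config(seed = 4))
  pw <- study$informative_pathways[1]
  genes <- study$gene_sets[[pw]]
  in_rate <- mean(study$mutations[study$labels == 1, genes])
  out_rate <- mean(study$mutations[study$labels != 1, genes])
  expect_gt(in_rate, 3 * out_rate)
})

test_that("fixtures round-trip through the interchange files", {
  study <- small_study(seed = 10)
  dir <- withr::local_tempdir()
  write_fixture(study, dir)
  back <- read_fixture(dir)
  for (mod in names(study$blocks)) {
    expect_equal(back$blocks[[mod]]$values, study$blocks[[mod]]$values,
                 tolerance = 1e-12)
  }
  expect_identical(unclass(back$gene_sets)[seq_along(study$gene_sets)],
                   unclass(study$gene_sets)[seq_along(study$gene_sets)])
  expect_equal(back$mutations, study$mutations)
  for (mod in c("mirna", "meth")) {
    expect_identical(
      dplyr::arrange(back$maps[[mod]]$pairs, .data$feature_id, .data$gene_id),
      dplyr::arrange(study$maps[[mod]]$pairs, .data$feature_id, .data$gene_id)
    )
  }
  # truth labels exist on disk but are not among the pipeline-visible inputs
  expect_true(file.exists(file.path(dir, "truth_labels.tsv")))
  expect_false("truth" %in% names(back))
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(proportions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(synthetic_config(n_informative = 30), "n_informative")
  expect_error(synthetic_config(driver_fraction = 0), "driver_fraction")
  expect_error(synthetic_config(effect_size = -1), "effect_size")
  expect_error(
    synthetic_config(features = c(mrna = 40L, mirna = 15L, meth = 30L)),
    "genes per pathway"
  )
})
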