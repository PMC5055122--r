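test_that("generated counts match NB moments and the law of large numbers", {
  # Poisson limit: one type, flat means, no depth variation
  spec <- synthetic_spec(n_genes = 50, n_cells = 2000, n_types = 1,
                         base_mean = 5, marker_fold = 1, markers_per_type = 0,
                         libsize_cv = 0, dispersion = 0, mean_sdlog = 0,
                         seed = 42)
  sim <- make_clustered_counts(spec)
  gm <- rowMeans(sim$counts)
  se <- sqrt(5 / 2000)
  expect_true(all(abs(gm - 5) < 3 * se + 1e-12) || mean(abs(gm - 5) < 3 * se) > 0.95)

  # NB moments: variance = mu + mu^2 * phi within 4 SE of the sampling
  # distribution of the variance estimator
  spec2 <- synthetic_spec(n_genes = 40, n_cells = 3000, n_types = 1,
                          base_mean = 4, marker_fold = 1, markers_per_type = 0,
                          libsize_cv = 0, dispersion = 0.5, mean_sdlog = 0,
                          seed = 43)
  sim2 <- make_clustered_counts(spec2)
  v <- apply(sim2$counts, 1, var)
  v_expect <- 4 + 16 * 0.5
  # SE of sample variance ~ sqrt((kurtosis-1)/n) * var; NB excess kurtosis
  # bounded; use the empirical spread of the 40 replicate genes
  expect_lt(abs(mean(v) - v_expect), 4 * sd(v) / sqrt(length(v)))
})

test_that("marker fold-change is realized between types", {
  spec <- synthetic_spec(n_genes = 300, n_cells = 900, n_types = 3,
                         base_mean = 2, marker_fold = 10, markers_per_type = 20,
                         libsize_cv = 0, dispersion = 0.3, seed = 7)
  sim <- make_clustered_counts(spec)
  ty <- sim$truth$type_of_cell
  for (t in paste0("T", 1:3)) {
    mk <- sim$truth$marker_genes[[t]]
    own <- rowMeans(sim$counts[mk, ty == t, drop = FALSE])
    other <- rowMeans(sim$counts[mk, ty != t, drop = FALSE])
    ratio <- sum(own) / sum(other)
    expect_gt(ratio, 7)
    expect_lt(ratio, 13)
  }
})

test_that("mixture weights act linearly on expectations", {
  spec <- synthetic_spec(n_genes = 200, n_cells = 3000, n_types = 2,
                         base_mean = 3, marker_fold = 6, markers_per_type = 30,
                         libsize_cv = 0, dispersion = 0.2, seed = 9)
  W <- matrix(0.5, 3000, 2)
  sim <- make_clustered_counts(spec, mixture_weights = W)
  mm <- sim$truth$mean_matrix
  expected <- rowMeans(mm)
  got <- rowMeans(sim$counts)
  # each gene within 4 SE of the mixture mean
  se <- sqrt((expected + expected^2 * 0.2) / 3000)
  expect_gt(mean(abs(got - expected) < 4 * se), 0.95)

  expect_error(make_clustered_counts(spec, mixture_weights = W * 1.5),
               "sum to 1")
})

test_that("same seed gives bit-identical output, counts are integers", {
  spec <- synthetic_spec(n_genes = 100, n_cells = 50, seed = 13)
  a <- make_clustered_counts(spec)
  b <- make_clustered_counts(spec)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$type_of_cell, b$truth$type_of_cell)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == round(a$counts)))
})

test_that("parameter validation rejects bad specs", {
  expect_error(synthetic_spec(base_mean = -1), "base_mean")
  expect_error(synthetic_spec(marker_fold = 0.5), "marker_fold")
  expect_error(synthetic_spec(libsize_cv = -0.1), "libsize_cv")
  expect_error(synthetic_spec(n_genes = 10, n_types = 3,
                              markers_per_type = 20), "exceed")
  expect_error(synthetic_spec(base_mean = NaN), "finite")
})

test_that("species pair: homolog bijection, divergence behavior", {
  spec <- synthetic_spec(n_genes = 300, n_cells = 100, n_types = 6,
                         base_mean = 0.5, marker_fold = 10,
                         markers_per_type = 15, seed = 21)
  sp0 <- make_species_pair(spec, n_shared_types = 6, divergence = 0)
  hm <- sp0$truth$homolog_map
  # one-to-one round trip
  expect_false(any(duplicated(hm$gene1)))
  expect_false(any(duplicated(hm$gene2)))
  back <- hm$gene1[match(hm$gene2, hm$gene2)]
  expect_identical(back, hm$gene1)
  # divergence 0: matched-type mean vectors identical up to gene order
  m1 <- sp0$species1$truth$mean_matrix[hm$gene1, ]
  m2 <- sp0$species2$truth$mean_matrix[hm$gene2, ]
  for (k in seq_len(6))
    expect_equal(cor(m1[, k], m2[, k]), 1, tolerance = 1e-12)
  # correlation decreases with divergence
  sp5 <- make_species_pair(spec, n_shared_types = 6, divergence = 0.5)
  m1 <- sp5$species1$truth$mean_matrix[sp5$truth$homolog_map$gene1, ]
  m2 <- sp5$species2$truth$mean_matrix[sp5$truth$homolog_map$gene2, ]
  cors <- vapply(1:6, function(k) cor(log(m1[, k]), log(m2[, k])), numeric(1))
  expect_true(all(cors < 1 & cors > 0))
  expect_error(make_species_pair(spec, 6, divergence = 1.2), "divergence")
  expect_error(make_species_pair(spec, 9, divergence = 0.1), "n_shared_types")
})

test_that("trajectory genes follow their generating shapes", {
  spec <- synthetic_spec(n_genes = 100, n_cells = 1000, n_types = 1,
                         base_mean = 10, marker_fold = 10, markers_per_type = 0,
                         libsize_cv = 0, dispersion = 0.2, mean_sdlog = 0,
                         seed = 31)
  sim <- make_trajectory(spec, n_dynamic_genes = 10,
                         shapes = c("monotone-up", "transient"))
  tt <- sim$truth$latent_time
  q <- cut(tt, breaks = quantile(tt, seq(0, 1, 0.25)), include.lowest = TRUE,
           labels = FALSE)
  up_genes <- sim$truth$dynamic_genes$gene[sim$truth$dynamic_genes$shape ==
                                             "monotone-up"]
  for (g in up_genes) {
    bins <- tapply(sim$counts[g, ], q, mean)
    expect_true(all(diff(bins) > 0), info = g)
  }
  tr_genes <- sim$truth$dynamic_genes$gene[sim$truth$dynamic_genes$shape ==
                                             "transient"]
  for (g in tr_genes) {
    bins <- tapply(sim$counts[g, ], q, mean)
    expect_gt(min(bins[2:3]), max(bins[c(1, 4)]))
  }
  expect_error(make_trajectory(spec, 10, shapes = character(0)), "non-empty")
  expect_error(make_trajectory(spec, 200), "n_dynamic_genes")
})

test_that("cycle module plants the expected activation and flags", {
  spec <- synthetic_spec(n_genes = 200, n_cells = 400, n_types = 1,
                         base_mean = 1, marker_fold = 1, markers_per_type = 0,
                         seed = 15)
  sim <- make_clustered_counts(spec)
  cyc <- sprintf("G%04d", 1:40)

  # fold = 1: counts untouched
  same <- add_cycle_module(sim, cyc, frac_cycling = 0.5, fold = 1, seed = 3)
  expect_identical(same$counts, sim$counts)

  # frac 0: no flags
  none <- add_cycle_module(sim, cyc, frac_cycling = 0, fold = 8, seed = 3)
  expect_false(any(none$truth$cycling_flags))

  # fold 8: flagged cells express the module ~8x higher (within [6, 10])
  mod <- add_cycle_module(sim, cyc, frac_cycling = 0.5, fold = 8, seed = 3)
  fl <- mod$truth$cycling_flags
  hi <- mean(colSums(mod$counts[cyc, fl, drop = FALSE]))
  lo <- mean(colSums(mod$counts[cyc, !fl, drop = FALSE]))
  expect_gt(hi / lo, 6)
  expect_lt(hi / lo, 10)

  expect_error(add_cycle_module(sim, c("nope"), 0.5, 8), "subset")
  expect_error(add_cycle_module(sim, cyc, 1.5, 8), "frac_cycling")
})
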