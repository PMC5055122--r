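trajectory_fixture <- function(seed = 8, n_genes = 800, n_cells = 400,
                               n_dynamic = 40,
                               shapes = c("monotone-up", "monotone-down")) {
  spec <- synthetic_spec(n_genes = n_genes, n_cells = n_cells, n_types = 1,
                         base_mean = 3, marker_fold = 12,
                         markers_per_type = 0, dispersion = 0.3,
                         mean_sdlog = 0.5, seed = seed)
  sim <- make_trajectory(spec, n_dynamic_genes = n_dynamic, shapes = shapes)
  sim$ages <- 11 + round(sim$truth$latent_time * 7)
  sim
}

test_that("time-varying gene selection has power and controls the FDR", {
  sim <- trajectory_fixture()
  sel <- select_time_varying_genes(sim$counts, sim$ages, fdr = 0.01)
  dyn <- sim$truth$dynamic_genes$gene
  expect_gte(sum(dyn %in% sel), 0.9 * length(dyn))
  flat <- setdiff(rownames(sim$counts), dyn)
  expect_lte(sum(sel %in% flat), 0.01 * length(flat))

  # genes in the exclusion set are never returned
  sel2 <- select_time_varying_genes(sim$counts, sim$ages, fdr = 0.01,
                                    exclusion_set = dyn[1:5])
  expect_false(any(dyn[1:5] %in% sel2))

  expect_error(select_time_varying_genes(sim$counts, rep(12, ncol(sim$counts))),
               "distinct ages")
})

test_that("null trajectories yield empty selections at FDR 0.01", {
  empty <- 0
  n_seeds <- 8
  for (sd in seq_len(n_seeds)) {
    spec <- synthetic_spec(n_genes = 300, n_cells = 200, n_types = 1,
                           base_mean = 2, marker_fold = 8,
                           markers_per_type = 0, seed = 100 + sd)
    sim <- make_trajectory(spec, n_dynamic_genes = 0)
    ages <- 11 + round(sim$truth$latent_time * 7)
    sel <- select_time_varying_genes(sim$counts, ages, fdr = 0.01)
    if (length(sel) == 0) empty <- empty + 1
  }
  expect_gte(empty / n_seeds, 0.95 - 1e-9)
})

test_that("pseudotime equals position for collinear data and recovers the
           planted latent time", {
  # counts whose log1p profiles are collinear in t: a straight line in
  # the PCA space the curve is fitted in
  tt <- seq(0, 1, length.out = 120)
  counts <- rbind(g1 = expm1(3 * tt), g2 = expm1(2 * tt),
                  g3 = expm1(3 * (1 - tt)))
  colnames(counts) <- sprintf("c%03d", seq_along(tt))
  fit <- fit_principal_curve_pseudotime(counts, rownames(counts),
                                        ages = tt, pc_sd_cut = 0,
                                        normalize = FALSE)
  expect_gte(cor(fit$pseudotime, tt), 0.999)

  sim <- trajectory_fixture(seed = 9)
  fit2 <- fit_principal_curve_pseudotime(sim$counts,
                                         sim$truth$dynamic_genes$gene,
                                         ages = sim$ages)
  rho <- cor(fit2$pseudotime,
             sim$truth$latent_time[names(fit2$pseudotime)],
             method = "spearman")
  expect_gte(abs(rho), 0.9)
  # orientation anchored to age: positive correlation
  expect_gt(cor(fit2$pseudotime, sim$ages, method = "spearman"), 0)
  expect_true(all(fit2$pseudotime >= 0))
})

test_that("profile fits separate dynamic from flat genes", {
  sim <- trajectory_fixture(seed = 12, n_genes = 300, n_dynamic = 12)
  fit <- fit_principal_curve_pseudotime(sim$counts,
                                        sim$truth$dynamic_genes$gene,
                                        ages = sim$ages)
  dyn <- sim$truth$dynamic_genes$gene
  flat <- sprintf("G%04d", 200:240)
  prof <- fit_pseudotime_profiles(fit, sim$counts, genes = c(dyn, flat),
                                  seed = 2)
  # flat genes rarely cross the significance cut
  expect_lte(mean(prof$r2[flat] >= 0.35), 0.05)
  # a noiseless monotone gene is fit almost perfectly
  counts2 <- sim$counts
  pt <- fit$pseudotime[colnames(counts2)]
  counts2["G0250", ] <- as.integer(round(50 * pt / max(pt)))
  prof2 <- fit_pseudotime_profiles(fit, counts2, genes = "G0250", seed = 2)
  expect_gte(prof2$r2["G0250"], 0.99)
  # constant gene: R^2 = 0
  counts2["G0251", ] <- 7L
  prof3 <- fit_pseudotime_profiles(fit, counts2, genes = "G0251", seed = 2)
  expect_equal(unname(prof3$r2["G0251"]), 0)
  # profile prediction invariant to cell order permutation
  perm <- sample(ncol(counts2))
  fit_perm <- fit
  fit_perm$pseudotime <- fit$pseudotime
  prof4 <- fit_pseudotime_profiles(fit_perm, counts2[, perm],
                                   genes = "G0250", seed = 2)
  expect_equal(prof4$profiles["G0250", ], prof2$profiles["G0250", ],
               tolerance = 1e-3)
})

test_that("profile clustering separates planted shape families", {
  sim <- trajectory_fixture(seed = 15, n_genes = 200, n_dynamic = 40)
  dyn <- sim$truth$dynamic_genes
  fit <- fit_principal_curve_pseudotime(sim$counts, dyn$gene, ages = sim$ages)
  prof <- fit_pseudotime_profiles(fit, sim$counts, genes = dyn$gene, seed = 3)
  cl <- cluster_profiles(prof, r2_cut = 0.35)
  pass <- names(cl$labels)
  expect_gte(length(pass), 30)
  shapes <- setNames(dyn$shape, dyn$gene)
  expect_equal(adjusted_rand_index(cl$labels[pass], shapes[pass]), 1)

  # a constant offset added to every profile leaves labels unchanged
  prof_off <- prof
  prof_off$profiles <- prof$profiles + 5
  cl_off <- cluster_profiles(prof_off, r2_cut = 0.35)
  expect_identical(cl_off$labels, cl$labels)

  # single passing gene: its own exemplar
  prof1 <- prof
  prof1$r2 <- setNames(c(0.9, rep(0, length(prof$r2) - 1)), names(prof$r2))
  cl1 <- cluster_profiles(prof1, r2_cut = 0.35)
  expect_identical(unname(cl1$labels), names(cl1$labels))
  # nothing passing: empty result, no error
  prof0 <- prof
  prof0$r2[] <- 0
  cl0 <- cluster_profiles(prof0, r2_cut = 0.35)
  expect_length(cl0$exemplars, 0)
})

test_that("only-upregulated simulations produce no decreasing profiles", {
  sim <- trajectory_fixture(seed = 18, n_genes = 200, n_dynamic = 20,
                            shapes = "monotone-up")
  dyn <- sim$truth$dynamic_genes$gene
  fit <- fit_principal_curve_pseudotime(sim$counts, dyn, ages = sim$ages)
  prof <- fit_pseudotime_profiles(fit, sim$counts, genes = dyn, seed = 4)
  pass <- names(prof$r2)[prof$r2 >= 0.35]
  ends <- prof$profiles[pass, ncol(prof$profiles)] - prof$profiles[pass, 1]
  expect_true(all(ends > 0))
})

test_that("zero imputation is switchable and leaves non-zero entries alone", {
  sim <- trajectory_fixture(seed = 21, n_genes = 60, n_cells = 150,
                            n_dynamic = 6)
  fit <- fit_principal_curve_pseudotime(sim$counts,
                                        sim$truth$dynamic_genes$gene,
                                        ages = sim$ages)
  g <- sim$truth$dynamic_genes$gene[1]
  imp <- cellspin:::impute_zeros_lasso(sim$counts, g)
  raw <- log1p(sim$counts[g, ])
  nz <- sim$counts[g, ] > 0
  expect_equal(imp[nz], raw[nz])
  expect_true(all(imp[!nz] >= 0))
  prof <- fit_pseudotime_profiles(fit, sim$counts, genes = g,
                                  impute = TRUE, seed = 2)
  expect_true(is.finite(prof$r2[g]))
})
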