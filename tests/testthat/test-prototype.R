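# standard prototype simulation: 5 balanced reference types + an
# independent outgroup culture sharing the gene namespace
prototype_fixture <- function(seed = 17, n_cells = 500) {
  spec <- synthetic_spec(n_genes = 800, n_cells = n_cells, n_types = 5,
                         base_mean = 0.5, marker_fold = 8,
                         markers_per_type = 25, seed = seed)
  ref <- make_clustered_counts(spec)
  spec_o <- synthetic_spec(n_genes = 800, n_cells = 150, n_types = 5,
                           base_mean = 0.5, marker_fold = 8,
                           markers_per_type = 25, seed = seed + 1)
  out <- make_clustered_counts(spec_o)
  grouping <- setNames(paste0("Proto", 1:5), paste0("T", 1:5))
  list(ref = ref, out = out, labels = ref$truth$type_of_cell,
       grouping = grouping)
}

test_that("training-gene selection ranks planted markers highly", {
  fx <- prototype_fixture()
  panel <- select_training_genes(fx$ref$counts, fx$labels, fx$out$counts,
                                 n_initial = 600)
  markers <- unlist(fx$ref$truth$marker_genes)
  expect_gte(mean(markers %in% panel), 0.9)
  # zero-variance gene is never selected
  counts2 <- fx$ref$counts
  counts2["G0700", ] <- 0L
  out2 <- fx$out$counts
  out2["G0700", ] <- 0L
  panel2 <- select_training_genes(counts2, fx$labels, out2, n_initial = 600)
  expect_false("G0700" %in% panel2)
})

test_that("the panel is half of the post-filter list", {
  fx <- prototype_fixture(seed = 23)
  shared <- intersect(rownames(fx$ref$counts), rownames(fx$out$counts))
  combined <- cbind(fx$ref$counts[shared, ], fx$out$counts[shared, ])
  model <- fit_noise_model(combined)
  top <- select_variable_genes(model, 600)
  v_comb <- apply(log1p(combined[top, ]), 1, var)
  v_out <- apply(log1p(fx$out$counts[top, ]), 1, var)
  n_post <- sum(v_out >= 0.1 * v_comb & v_comb > 0)
  panel <- select_training_genes(fx$ref$counts, fx$labels, fx$out$counts,
                                 n_initial = 600)
  expect_lte(abs(length(panel) - ceiling(n_post / 2)), 1)
})

test_that("classifier separates prototypes and calibrates to the simplex", {
  fx <- prototype_fixture()
  panel <- select_training_genes(fx$ref$counts, fx$labels, fx$out$counts,
                                 n_initial = 600)
  model <- train_prototype_classifier(fx$ref$counts, fx$labels, fx$grouping,
                                      panel, C = 0.01, seed = 3)
  p <- score_cells(model, fx$ref$counts)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
  expect_true(all(p >= 0))
  pred <- colnames(p)[max.col(p, ties.method = "first")]
  truth <- unname(fx$grouping[fx$labels[rownames(p)]])
  expect_gte(mean(pred == truth), 0.99)

  # stratified 85/15 held-out accuracy
  set.seed(41)
  tr <- unlist(lapply(split(seq_len(ncol(fx$ref$counts)), fx$labels),
                      function(i) sample(i, round(0.85 * length(i)))))
  te <- setdiff(seq_len(ncol(fx$ref$counts)), tr)
  m_tr <- train_prototype_classifier(fx$ref$counts[, tr], fx$labels,
                                     fx$grouping, panel, C = 0.01, seed = 3)
  p_te <- score_cells(m_tr, fx$ref$counts[, te])
  pred_te <- colnames(p_te)[max.col(p_te, ties.method = "first")]
  truth_te <- unname(fx$grouping[fx$labels[rownames(p_te)]])
  expect_gte(mean(pred_te == truth_te), 0.95)

  # C -> 0: probabilities approach uniform
  m0 <- train_prototype_classifier(fx$ref$counts, fx$labels, fx$grouping,
                                   panel, C = 1e-7, seed = 3)
  p0 <- score_cells(m0, fx$ref$counts[, 1:20])
  expect_lt(max(abs(p0 - 0.2)), 0.02)

  # merged prototypes train too (several clusters -> one class)
  grouping2 <- setNames(c("AB", "AB", "C", "D", "E"), paste0("T", 1:5))
  m2 <- train_prototype_classifier(fx$ref$counts, fx$labels, grouping2,
                                   panel, C = 0.01, seed = 3)
  expect_setequal(m2$prototypes, c("AB", "C", "D", "E"))
  expect_error(train_prototype_classifier(
    fx$ref$counts[, 1:8], fx$labels, fx$grouping, panel, C = 0.01),
    "< 5 cells")
})

test_that("mixture cells score between their source prototypes", {
  fx <- prototype_fixture()
  panel <- select_training_genes(fx$ref$counts, fx$labels, fx$out$counts,
                                 n_initial = 600)
  model <- train_prototype_classifier(fx$ref$counts, fx$labels, fx$grouping,
                                      panel, C = 0.01, seed = 3)
  mix_spec <- synthetic_spec(n_genes = 800, n_cells = 60, n_types = 5,
                             base_mean = 0.5, marker_fold = 8,
                             markers_per_type = 25, seed = 19)
  W <- matrix(0, 60, 5)
  W[, 3] <- 0.5
  W[, 4] <- 0.5
  mix <- make_clustered_counts(mix_spec, mixture_weights = W)
  pm <- score_cells(model, mix$counts)
  top2 <- t(apply(pm, 1, function(x) sort(x, decreasing = TRUE)[1:2]))
  expect_lt(mean(top2[, 1] - top2[, 2]), 0.1)
  top_names <- t(apply(pm, 1, function(x)
    sort(names(sort(x, decreasing = TRUE))[1:2])))
  expect_gte(mean(top_names[, 1] == "Proto3" & top_names[, 2] == "Proto4"),
             0.9)
})

test_that("regularization choice returns the smallest C at the plateau", {
  fx <- prototype_fixture(seed = 29, n_cells = 250)
  panel <- select_training_genes(fx$ref$counts, fx$labels, fx$out$counts,
                                 n_initial = 400)
  res <- choose_regularization(fx$ref$counts, fx$labels, fx$grouping, panel,
                               C_grid = c(0.001, 0.01, 0.1), n_iters = 6,
                               seed = 5)
  expect_true(res$C %in% c(0.001, 0.01, 0.1))
  expect_true(all(res$curve$accuracy >= 0 & res$curve$accuracy <= 1))
  expect_equal(res$curve$C, c(0.001, 0.01, 0.1))
  # single-element grid returns that C
  res1 <- choose_regularization(fx$ref$counts, fx$labels, fx$grouping, panel,
                                C_grid = 0.05, n_iters = 3, seed = 5)
  expect_equal(res1$C, 0.05)
  # reproducible under a fixed seed
  res2 <- choose_regularization(fx$ref$counts, fx$labels, fx$grouping, panel,
                                C_grid = 0.05, n_iters = 3, seed = 5)
  expect_identical(res1$curve, res2$curve)
  expect_error(choose_regularization(fx$ref$counts, fx$labels, fx$grouping,
                                     panel, C_grid = c(1, 0.1)), "ascending")
})

test_that("scrambling destroys structure but preserves totals", {
  fx <- prototype_fixture()
  panel <- select_training_genes(fx$ref$counts, fx$labels, fx$out$counts,
                                 n_initial = 600)
  model <- train_prototype_classifier(fx$ref$counts, fx$labels, fx$grouping,
                                      panel, C = 0.01, seed = 3)
  sc <- scrambled_control(model, fx$ref$counts, seed = 9)
  expect_identical(colSums(sc$scrambled), colSums(fx$ref$counts))
  sc2 <- scrambled_control(model, fx$ref$counts, seed = 9)
  expect_identical(sc$scrambled, sc2$scrambled)
  sc3 <- scrambled_control(model, fx$ref$counts, seed = 10)
  expect_false(identical(sc$scrambled, sc3$scrambled))

  p <- score_cells(model, fx$ref$counts)
  wl <- wheel_layout(p)
  r_real <- mean(sqrt(rowSums(wl$coords^2)))
  r_scr <- mean(sqrt(rowSums(wheel_coordinates(sc$probabilities, wl)^2)))
  expect_lt(r_scr, 0.5 * r_real)
})

test_that("wheel geometry: vertices, center, bounds, order search", {
  P <- rbind(onehot = c(1, 0, 0, 0, 0),
             uniform = rep(0.2, 5),
             mixed = c(0.5, 0.5, 0, 0, 0))
  colnames(P) <- paste0("p", 1:5)
  wl <- wheel_layout(P)
  r <- sqrt(rowSums(wl$coords^2))
  expect_equal(unname(r["onehot"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["uniform"]), 0, tolerance = 1e-12)
  expect_true(all(r <= 1 + 1e-12))
  expect_error(wheel_layout(P * 2), "sum to 1")

  # exhaustive and greedy layouts agree on the minimized central count
  set.seed(31)
  Q <- matrix(rexp(300 * 6), 300, 6)
  Q <- Q / rowSums(Q)
  colnames(Q) <- paste0("p", 1:6)
  ex <- wheel_layout(Q, exhaustive_max = 8)
  gr <- wheel_layout(Q, exhaustive_max = 2)
  expect_lte(ex$n_central, gr$n_central)
})
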