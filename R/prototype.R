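# cluster mean / second-highest mean, with a small pseudocount
fold_increase_stats <- function(counts, labels, genes) {
  clusters <- sort(unique(labels[colnames(counts)]))
  means <- sapply(clusters, function(cl) {
    rowMeans(counts[genes, labels[colnames(counts)] == cl, drop = FALSE])
  })
  top_i <- max.col(means, ties.method = "first")
  top <- means[cbind(seq_along(genes), top_i)]
  second <- apply(means, 1, function(v) sort(v, decreasing = TRUE)[2])
  fold <- (top + 0.01) / (second + 0.01)
  frac_pos <- vapply(seq_along(genes), function(i) {
    cl <- clusters[top_i[i]]
    mean(counts[genes[i], labels[colnames(counts)] == cl] > 0)
  }, numeric(1))
  data.frame(gene = genes, fold = fold, frac_pos = frac_pos,
             stringsAsFactors = FALSE)
}

#' Select the prototype-classifier gene panel
#'
#' Starting from the `n_initial` most variable genes of the combined
#' reference + outgroup data (CV residual against the noise model):
#' (1) genes with minimal variability in the outgroup experiment relative
#' to the combined data are discarded (variance on `log1p` counts below
#' `min_outgroup_var_frac` of the combined variance), so cell-culture-only
#' features are not learned; (2) the list is halved by keeping the top
#' genes under three cell-type-specificity heuristics — fold-increase,
#' fold-increase x fraction-positive, and
#' fold-increase x sqrt(fraction-positive) — each gene scored by its best
#' rank across the three.
#'
#' @param reference genes x cells reference count matrix.
#' @param labels named cell -> cluster assignment for the reference.
#' @param outgroup genes x cells outgroup matrix (same gene namespace).
#' @param n_initial initial variable-gene count (default 4500).
#' @param min_outgroup_var_frac variability-filter cutoff (default 0.1).
#' @param min_panel error below this final panel size (default 100).
#' @return character vector: the gene panel (half of the post-filter
#'   list, rounded up).
#' @export
select_training_genes <- function(reference, labels, outgroup,
                                  n_initial = 4500,
                                  min_outgroup_var_frac = 0.1,
                                  min_panel = 100) {
  shared <- intersect(rownames(reference), rownames(outgroup))
  combined <- cbind(reference[shared, , drop = FALSE],
                    outgroup[shared, , drop = FALSE])
  model <- fit_noise_model(combined)
  top <- select_variable_genes(model, min(n_initial, nrow(model$table)))
  v_comb <- apply(log1p(combined[top, , drop = FALSE]), 1, var)
  v_out <- apply(log1p(outgroup[top, , drop = FALSE]), 1, var)
  keep <- top[v_out >= min_outgroup_var_frac * v_comb & v_comb > 0]
  st <- fold_increase_stats(reference, labels, keep)
  h <- cbind(st$fold,
             st$fold * st$frac_pos,
             st$fold * sqrt(st$frac_pos))
  ranks <- apply(-h, 2, rank, ties.method = "min")
  best_rank <- apply(ranks, 1, min)
  n_half <- ceiling(length(keep) / 2)
  panel <- st$gene[order(best_rank, -st$fold)][seq_len(n_half)]
  if (length(panel) < min_panel)
    stop("prototype gene panel has fewer than ", min_panel, " genes")
  panel
}

# log1p counts scaled by the recorded per-gene max; genes missing from
# the matrix contribute zeros.
max_normalized_features <- function(counts, genes, gene_max,
                                    warn_missing = TRUE) {
  missing <- setdiff(genes, rownames(counts))
  if (length(missing) == length(genes))
    stop("no panel genes present in the query matrix")
  if (length(missing) > 0) {
    if (warn_missing)
      warning(length(missing), " panel genes missing from matrix; set to 0")
    pad <- matrix(0L, length(missing), ncol(counts),
                  dimnames = list(missing, colnames(counts)))
    counts <- rbind(counts, pad)
  }
  m <- t(log1p(counts[genes, , drop = FALSE]))
  sweep(m, 2, pmax(gene_max, .Machine$double.eps), `/`)
}

#' Train the multinomial prototype classifier
#'
#' Learns idealized cell-type prototypes — each either a single reference
#' cluster or a group of biologically related clusters — with a
#' multinomial logistic regression under an L2 penalty, on
#' log-transformed max-normalized data (the per-gene max over the
#' training set is recorded and reused for queries).
#'
#' The penalty is parameterized like scikit-learn's `C`
#' (`lambda = 1 / (n_cells * C)` in glmnet's 1/n-scaled deviance).
#'
#' @param reference genes x cells reference count matrix.
#' @param labels named cell -> cluster assignment.
#' @param grouping named character vector or list mapping cluster label ->
#'   prototype name; every labeled cluster must appear.
#' @param panel gene panel from [select_training_genes()].
#' @param C regularization strength (default 0.01).
#' @param min_cells error if a prototype has fewer cells (default 5).
#' @param seed RNG seed.
#' @return object of class `prototype_model`: `panel`, `prototypes`,
#'   `grouping`, `gene_max`, `fit` (glmnet), `C`, `lambda`.
#' @export
train_prototype_classifier <- function(reference, labels, grouping, panel,
                                       C = 0.01, min_cells = 5, seed = 1L) {
  grouping <- unlist(grouping)
  lab <- labels[colnames(reference)]
  if (!all(unique(lab) %in% names(grouping)))
    stop("every labeled cluster must appear in the grouping")
  proto <- factor(unname(grouping[lab]), levels = sort(unique(unname(grouping))))
  small <- table(proto) < min_cells
  if (any(small))
    stop("prototype(s) with < ", min_cells, " cells: ",
         paste(names(which(small)), collapse = ", "))
  gene_max <- apply(log1p(reference[panel, , drop = FALSE]), 1, max)
  X <- max_normalized_features(reference, panel, gene_max)
  set.seed(seed)
  lambda <- 1 / (nrow(X) * C)
  fit <- glmnet::glmnet(X, proto, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  structure(list(panel = panel, prototypes = levels(proto),
                 grouping = grouping, gene_max = gene_max, fit = fit,
                 C = C, lambda = lambda),
            class = "prototype_model")
}

#' Score query cells against the prototypes
#'
#' Applies the training normalization (the recorded per-gene max; query
#' values may exceed 1, never clipped) and returns softmax class
#' probabilities. Panel genes missing from the query are set to 0 with a
#' warning.
#'
#' @param model a `prototype_model`.
#' @param query genes x cells count matrix.
#' @return cells x prototypes matrix of probabilities (rows sum to 1).
#' @export
score_cells <- function(model, query) {
  X <- max_normalized_features(query, model$panel, model$gene_max)
  p <- predict(model$fit, X, type = "response")[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                   dimnames = list(colnames(query), names(p)))
  p[, model$prototypes, drop = FALSE]
}

#' Choose the regularization strength by repeated stratified splits
#'
#' For each `C` in the grid, the reference is split `n_iters` times into
#' a stratified 85% training / 15% test partition; mean held-out accuracy
#' is recorded. Returns the smallest `C` whose mean accuracy is within
#' one standard error of the grid maximum — the "maximum accuracy before
#' the plateau" read deterministically.
#'
#' @inheritParams train_prototype_classifier
#' @param C_grid ascending grid of candidate strengths.
#' @param n_iters random splits per C (default 35).
#' @param train_frac training fraction (default 0.85).
#' @return list: `C` (chosen), `curve` (data.frame C, mean accuracy, se).
#' @export
choose_regularization <- function(reference, labels, grouping, panel,
                                  C_grid, n_iters = 35, train_frac = 0.85,
                                  seed = 1L) {
  if (is.unsorted(C_grid)) stop("C_grid must be sorted ascending")
  grouping <- unlist(grouping)
  proto <- factor(unname(grouping[labels[colnames(reference)]]))
  acc <- matrix(NA_real_, n_iters, length(C_grid))
  for (it in seq_len(n_iters)) {
    set.seed(derive_seed(seed, it))
    tr <- unlist(lapply(split(seq_along(proto), proto), function(idx)
      sample(idx, size = max(1, round(train_frac * length(idx))))))
    te <- setdiff(seq_along(proto), tr)
    ref_tr <- reference[, tr, drop = FALSE]
    for (j in seq_along(C_grid)) {
      m <- train_prototype_classifier(ref_tr, labels, grouping, panel,
                                      C = C_grid[j], min_cells = 1,
                                      seed = derive_seed(seed, it * 100 + j))
      p <- score_cells(m, reference[, te, drop = FALSE])
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      acc[it, j] <- mean(pred == as.character(proto[te]))
    }
  }
  mean_acc <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(n_iters)
  best <- which.max(mean_acc)
  ok <- which(mean_acc >= mean_acc[best] - se[best])
  list(C = C_grid[min(ok)],
       curve = data.frame(C = C_grid, accuracy = mean_acc, se = se))
}

#' Scrambled-gene negative control
#'
#' Permutes the gene values independently within each query cell (so each
#' cell's total molecule count is exactly preserved) and scores the
#' scrambled cells; structureless cells should fall near the wheel
#' center.
#'
#' @param model a `prototype_model`.
#' @param query genes x cells count matrix.
#' @param seed RNG seed.
#' @return list: `probabilities` (as [score_cells()]), `scrambled`
#'   (the permuted matrix).
#' @export
scrambled_control <- function(model, query, seed = 1L) {
  set.seed(seed)
  scr <- apply(query, 2, sample)
  dimnames(scr) <- dimnames(query)
  list(probabilities = score_cells(model, scr), scrambled = scr)
}
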