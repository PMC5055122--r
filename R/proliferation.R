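#' Select the correlated core of cell-cycle annotation genes
#'
#' Restricts to the supplied cell-cycle/proliferation annotation genes
#' that are present with at least `min_total` molecules in the dataset,
#' computes their pairwise Pearson correlation matrix — on `log1p` of
#' depth-normalized counts (each cell scaled to the median total), so
#' library-size variation does not masquerade as co-expression — takes
#' the 99th percentile of the off-diagonal entries as the "strongly
#' correlated" threshold, and keeps genes with at least `min_partners`
#' partners above it: the coherently co-varying cycle module.
#'
#' @param counts genes x cells count matrix.
#' @param annotation_genes non-empty character vector (e.g. genes under GO
#'   terms such as DNA metabolic process, DNA replication, mitosis, ...).
#' @param min_total strict lower bound on dataset-wide molecules
#'   (default 10: genes with fewer than 10 are removed).
#' @param min_partners required number of strongly correlated partners
#'   (default 12).
#' @param corr_quantile percentile defining "strongly correlated"
#'   (default 0.99, over off-diagonal entries only).
#' @return character vector of selected genes.
#' @export
select_cycle_genes <- function(counts, annotation_genes, min_total = 10,
                               min_partners = 12, corr_quantile = 0.99) {
  if (length(annotation_genes) == 0) stop("annotation_genes must be non-empty")
  present <- intersect(annotation_genes, rownames(counts))
  present <- present[rowSums(counts[present, , drop = FALSE]) >= min_total]
  if (length(present) < min_partners + 1)
    stop("fewer than ", min_partners + 1,
         " annotation genes survive the molecule filter; the ",
         min_partners, "-partner rule cannot be satisfied")
  tot <- colSums(counts)
  norm <- sweep(counts[present, , drop = FALSE], 2, tot / median(tot), `/`)
  cc <- suppressWarnings(cor(t(log1p(norm))))
  cc[!is.finite(cc)] <- 0
  off <- cc[upper.tri(cc)]
  thr <- quantile(off, corr_quantile, names = FALSE)
  partners <- rowSums(cc >= thr) - 1          # exclude self
  sel <- present[partners >= min_partners]
  if (length(sel) < min_partners + 1)
    stop("fewer than ", min_partners + 1, " genes pass the partner rule")
  sel
}

# log1p counts, per-gene mean-centered; cells x genes
log_centered <- function(counts, genes) {
  m <- t(log1p(counts[genes, , drop = FALSE]))
  scale(m, center = TRUE, scale = FALSE)
}

#' Learn the proliferation score
#'
#' In the cycle-gene subspace, K-means with k = 2 on log-centered data
#' splits cells into a cycling and a non-cycling group (the cluster with
#' the higher mean total panel expression is cycling). An L1-regularized
#' linear regression of the 0/1 cycling label on the log-centered panel
#' expression then generalizes the split into a continuous score; the
#' regularization is deliberately strong (default `alpha = 0.01`, several
#' times the cross-validated optimum) to avoid overfitting the first-pass
#' clusters.
#'
#' @param counts genes x cells count matrix.
#' @param panel gene panel from [select_cycle_genes()].
#' @param alpha L1 penalty (glmnet gaussian `lambda`; identical scale to
#'   scikit-learn's Lasso `alpha`).
#' @param seed RNG seed (K-means initialization).
#' @return object of class `cycle_score_model`: `genes`, `weights`,
#'   `intercept` (with the training centering folded in, so the score is
#'   affine in `log1p` counts), `alpha`, `training_labels` (0/1 per
#'   training cell).
#' @export
learn_cycle_score <- function(counts, panel, alpha = 0.01, seed = 1L) {
  m <- log_centered(counts, panel)
  centers <- attr(m, "scaled:center")
  set.seed(seed)
  km <- NULL
  for (attempt in 1:10) {
    km <- kmeans(m, centers = 2, nstart = 1)
    if (all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("K-means failed to produce two non-empty clusters")
  panel_total <- colSums(counts[panel, , drop = FALSE])
  mean_total <- tapply(panel_total, km$cluster, mean)
  cycling_cluster <- as.integer(names(which.max(mean_total)))
  y <- as.numeric(km$cluster == cycling_cluster)
  fit <- glmnet::glmnet(m, y, alpha = 1, lambda = alpha,
                        standardize = FALSE)
  w <- as.numeric(coef(fit))
  weights <- setNames(w[-1], panel)
  # fold the training centering into the intercept so the score is a plain
  # affine function of log1p counts (the all-zero cell scores the intercept)
  intercept <- w[1] - sum(centers * weights)
  structure(list(genes = panel, weights = weights,
                 intercept = intercept, alpha = alpha,
                 training_labels = setNames(y, rownames(m))),
            class = "cycle_score_model")
}

#' Score cells for proliferation
#'
#' Applies a learned [learn_cycle_score()] model to any count matrix
#' (e.g. a stem-cell culture scored with the model learned on the
#' embryonic reference). Panel genes missing from the matrix are imputed
#' as zero counts with a warning.
#'
#' @param model a `cycle_score_model`.
#' @param counts genes x cells count matrix.
#' @param cutoff binary-call threshold on the score (default 0.5).
#' @return data.frame with `cell`, `score`, `cycling` (logical).
#' @export
score_proliferation <- function(model, counts, cutoff = 0.5) {
  missing <- setdiff(model$genes, rownames(counts))
  if (length(missing) > 0) {
    warning(length(missing), " panel genes missing from matrix; imputed as 0")
    pad <- matrix(0L, length(missing), ncol(counts),
                  dimnames = list(missing, colnames(counts)))
    counts <- rbind(counts, pad)
  }
  m <- t(log1p(counts[model$genes, , drop = FALSE]))
  score <- as.numeric(m %*% model$weights) + model$intercept
  data.frame(cell = colnames(counts), score = score,
             cycling = score > cutoff, stringsAsFactors = FALSE)
}
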