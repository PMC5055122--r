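#' Select genes varying significantly with sampling age
#'
#' Conceptually an ANOVA for overdispersed counts: the top `n_top` genes
#' by CV residual are tested gene-by-gene with a likelihood ratio test of
#' a negative-binomial GLM with categorical age against the intercept-only
#' null. The dispersion is estimated by maximum likelihood under the
#' null (intercept-only) fit and shared by both models of the LRT;
#' estimating it under the alternative is anticonservative in the far
#' tail, exactly where the FDR correction operates, while the null-based
#' estimate is calibrated on NB null data. P-values are Benjamini-Hochberg
#' adjusted
#' and genes pass at `FDR < fdr`; genes in `exclusion_set` (e.g. genes
#' significant in other cell types) are removed.
#'
#' @param counts genes x cells count matrix (one lineage).
#' @param ages per-cell sampling age (>= 2 distinct values).
#' @param fdr FDR threshold (default 0.01).
#' @param exclusion_set genes never to return.
#' @param n_top genes entering the test, ranked by noise-model residual
#'   (default 5000).
#' @return character vector of selected genes; attribute `"table"` holds
#'   the per-gene p-values and FDR.
#' @export
select_time_varying_genes <- function(counts, ages, fdr = 0.01,
                                      exclusion_set = character(0),
                                      n_top = 5000) {
  if (length(unique(ages)) < 2) stop("need >= 2 distinct ages")
  model <- fit_noise_model(counts)
  top <- select_variable_genes(model, min(n_top, nrow(model$table)))
  age_f <- factor(ages)
  res <- lapply(top, function(g) {
    y <- counts[g, ]
    p <- tryCatch({
      null <- suppressWarnings(MASS::glm.nb(y ~ 1))
      alt <- suppressWarnings(
        glm(y ~ age_f, family = MASS::negative.binomial(theta = null$theta)))
      ll_alt <- as.numeric(logLik(alt))
      ll_null <- as.numeric(logLik(null))
      stat <- max(2 * (ll_alt - ll_null), 0)
      pchisq(stat, df = nlevels(age_f) - 1, lower.tail = FALSE)
    }, error = function(e) NA_real_)
    p
  })
  pvals <- unlist(res)
  dropped <- is.na(pvals)
  if (any(dropped))
    warning(sum(dropped), " genes dropped: NB fit failure")
  tab <- data.frame(gene = top[!dropped], p = pvals[!dropped],
                    stringsAsFactors = FALSE)
  tab$fdr <- p.adjust(tab$p, method = "BH")
  sel <- setdiff(tab$gene[tab$fdr < fdr], exclusion_set)
  attr(sel, "table") <- tab
  sel
}

# Project points onto a polyline; returns arc-length position and distance.
project_polyline <- function(points, curve) {
  n_seg <- nrow(curve) - 1
  seg_start <- curve[-nrow(curve), , drop = FALSE]
  seg_vec <- curve[-1, , drop = FALSE] - seg_start
  seg_len2 <- rowSums(seg_vec^2)
  seg_len <- sqrt(seg_len2)
  cum_len <- c(0, cumsum(seg_len))
  lambda <- numeric(nrow(points))
  dist2 <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    # t along each segment, clamped to [0, 1]
    tproj <- rowSums(sweep(seg_start, 2, p, function(s, pp) -(s - pp)) * seg_vec) /
      pmax(seg_len2, .Machine$double.eps)
    tproj <- pmin(pmax(tproj, 0), 1)
    proj <- seg_start + seg_vec * tproj
    d2 <- rowSums(sweep(proj, 2, p)^2)
    j <- which.min(d2)
    lambda[i] <- cum_len[j] + tproj[j] * seg_len[j]
    dist2[i] <- d2[j]
  }
  list(lambda = lambda, dist2 = dist2, total_length = cum_len[n_seg + 1])
}

# One-dimensional spectral (Laplacian eigenmap) ordering: the second
# eigenvector of the normalized Gaussian-kernel affinity unfolds curved
# one-dimensional manifolds (e.g. the horseshoe a trajectory with
# transient genes traces in PC space), where a straight principal
# component cannot.
spectral_order <- function(X, k = 15) {
  d <- as.matrix(dist(X))
  kth <- apply(d, 1, function(r) sort(r)[min(k + 1, length(r))])
  sigma <- median(kth)
  if (sigma <= 0) return(seq_len(nrow(X)))
  A <- exp(-d^2 / (2 * sigma^2))
  diag(A) <- 0
  w <- 1 / sqrt(pmax(rowSums(A), .Machine$double.eps))
  L <- w * t(w * A)
  ev <- tryCatch(eigen(L, symmetric = TRUE), error = function(e) NULL)
  if (is.null(ev) || ncol(ev$vectors) < 2) return(seq_len(nrow(X)))
  ev$vectors[, 2] / ev$vectors[, 1]
}

# Principal-curve iteration: project onto the current polyline, then
# smooth each coordinate against arc length (spline), until the total
# squared point-to-curve distance stabilizes. Initialized with the
# spectral ordering above.
principal_curve_fit <- function(X, tol = 1e-4, max_iter = 50, df = 6) {
  lambda <- rank(spectral_order(X), ties.method = "first")
  converged <- FALSE
  ss_old <- Inf
  for (iter in seq_len(max_iter)) {
    ord <- order(lambda)
    us <- sort(lambda)
    dfj <- max(4, min(df, length(unique(round(us, 8))) - 1))
    curve <- sapply(seq_len(ncol(X)), function(j) {
      fit <- tryCatch(
        smooth.spline(lambda, X[, j], df = dfj),
        error = function(e) NULL)
      if (is.null(fit)) {
        approx(lambda[ord], X[ord, j], xout = us, rule = 2)$y
      } else {
        predict(fit, us)$y
      }
    })
    curve <- curve[!duplicated(us), , drop = FALSE]
    pr <- project_polyline(X, curve)
    lambda <- pr$lambda
    ss <- sum(pr$dist2)
    if (is.finite(ss_old) && abs(ss_old - ss) <= tol * ss_old) {
      converged <- TRUE
      break
    }
    ss_old <- ss
  }
  list(lambda = lambda, curve = curve, converged = converged, iter = iter)
}

scale_unit <- function(x) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

#' Principal-curve pseudotime
#'
#' PCA on `log1p` of depth-normalized counts (cells scaled to the median
#' total) of the selected genes, keeping components whose per-gene RMS
#' standard deviation — `sdev / sqrt(n_genes)`, a scale-free measure of
#' how much log-expression variation per gene a component carries —
#' exceeds `pc_sd_cut`; this places the cut in the gap between the
#' signal components and the sampling-noise bulk. A principal curve — a
#' smooth one-dimensional curve through the middle of the cloud — is
#' then fitted by iterated projection and per-coordinate spline
#' smoothing, initialized from a spectral (Laplacian eigenmap) ordering
#' that can unfold curved trajectories. Each cell's pseudotime is the
#' arc length from the start of the curve to its projection. The curve
#' is oriented so pseudotime correlates positively with sampling age
#' when ages are supplied.
#'
#' @param counts genes x cells count matrix.
#' @param genes time-relevant genes (from [select_time_varying_genes()]).
#' @param ages optional per-cell ages, used only to orient the curve.
#' @param pc_sd_cut keep principal components with per-gene RMS SD above
#'   this (default 0.25 log-units).
#' @param normalize depth-normalize cells to the median total before the
#'   log transform (default TRUE).
#' @param tol,max_iter convergence control of the curve iteration.
#' @param seed RNG seed (PCA sign conventions are deterministic; the seed
#'   is recorded for provenance).
#' @return object of class `pseudotime_fit`: `pseudotime` (named, >= 0),
#'   `pcs` (retained scores), `curve`, `converged`, `genes`.
#' @export
fit_principal_curve_pseudotime <- function(counts, genes, ages = NULL,
                                           pc_sd_cut = 0.25, tol = 1e-4,
                                           max_iter = 50, normalize = TRUE,
                                           seed = 1L) {
  set.seed(seed)
  norm <- counts[genes, , drop = FALSE]
  if (normalize) {
    tot <- colSums(counts)
    norm <- sweep(norm, 2, tot / median(tot), `/`)
  }
  X <- t(log1p(norm))
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  keep <- which(pca$sdev / sqrt(length(genes)) > pc_sd_cut)
  if (length(keep) < 2)
    keep <- seq_len(min(2, ncol(pca$x)))
  scores <- pca$x[, keep, drop = FALSE]
  fit <- principal_curve_fit(scores, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    warning("principal curve did not converge in ", max_iter,
            " iterations; returning last iterate")
  pt <- fit$lambda - min(fit$lambda)
  if (!is.null(ages)) {
    rho <- suppressWarnings(cor(pt, ages, method = "spearman"))
    if (is.finite(rho) && rho < 0) pt <- max(pt) - pt
  }
  structure(list(pseudotime = setNames(pt, colnames(counts)),
                 pcs = scores, curve = fit$curve,
                 converged = fit$converged, genes = genes),
            class = "pseudotime_fit")
}

# L1 imputation of technical zeros: regress the gene on its most
# correlated partners and replace zero entries with the (non-negative)
# prediction. A documented stand-in for the external reference method.
impute_zeros_lasso <- function(counts, gene, n_partners = 30) {
  y <- log1p(counts[gene, ])
  zero <- counts[gene, ] == 0
  if (!any(zero) || all(zero)) return(y)
  lg <- log1p(t(counts[setdiff(rownames(counts), gene), , drop = FALSE]))
  cors <- suppressWarnings(cor(lg, y))
  cors[!is.finite(cors)] <- 0
  top <- order(-abs(cors))[seq_len(min(n_partners, ncol(lg)))]
  xx <- lg[, top, drop = FALSE]
  fit <- tryCatch(glmnet::cv.glmnet(xx[!zero, , drop = FALSE], y[!zero],
                                    alpha = 1, nfolds = 5),
                  error = function(e) NULL)
  if (is.null(fit)) return(y)
  pred <- as.numeric(predict(fit, xx[zero, , drop = FALSE], s = "lambda.min"))
  y[zero] <- pmax(pred, 0)
  y
}

# stratified fold assignment over pseudotime quantile bins; deterministic
# given (pt values, seed) and invariant to the order cells are supplied in
stratified_folds <- function(pt, k, seed) {
  set.seed(seed)
  labels <- sample(k)                 # seeded rotation of fold labels
  ord <- order(pt, names(pt) %||% seq_along(pt))
  fold <- integer(length(pt))
  fold[ord] <- labels[(seq_along(pt) - 1L) %% k + 1L]
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Smooth pseudotime expression profiles by SVR
#'
#' Per gene: optionally impute technical zeros with an L1 regression on
#' the 30 most-correlated genes, then fit an RBF support vector
#' regression of `log1p` expression on pseudotime. Hyperparameters are
#' chosen by stratified k-fold cross-validation (folds stratified on
#' pseudotime quantile bins) and the out-of-fold R-squared is reported;
#' constant genes get R-squared 0.
#'
#' @param fit a [fit_principal_curve_pseudotime()] result.
#' @param counts genes x cells count matrix.
#' @param genes genes to profile (default: the fit's genes).
#' @param cv_folds folds (default 5).
#' @param impute impute technical zeros first (default FALSE).
#' @param cost_grid,gamma_grid SVR hyperparameter grids.
#' @param grid_points profile sampling grid size (default 50).
#' @param seed RNG seed.
#' @return object of class `pseudotime_profiles`: `profiles` (genes x
#'   `grid_points` matrix sampled on an even pseudotime grid), `r2`
#'   (named out-of-fold R-squared), `grid`.
#' @export
fit_pseudotime_profiles <- function(fit, counts, genes = fit$genes,
                                    cv_folds = 5, impute = FALSE,
                                    cost_grid = c(1, 10),
                                    gamma_grid = c(0.5, 2),
                                    grid_points = 50, seed = 1L) {
  stopifnot(inherits(fit, "pseudotime_fit"))
  pt <- fit$pseudotime[colnames(counts)]
  span <- max(pt) - min(pt)
  ptn <- if (span > 0) (pt - min(pt)) / span else pt * 0
  grid <- seq(0, 1, length.out = grid_points)
  folds <- stratified_folds(ptn, cv_folds, seed)
  profiles <- matrix(NA_real_, length(genes), grid_points,
                     dimnames = list(genes, NULL))
  r2 <- setNames(rep(0, length(genes)), genes)
  for (g in genes) {
    y <- if (impute) impute_zeros_lasso(counts, g) else log1p(counts[g, ])
    if (sd(y) < .Machine$double.eps) {
      profiles[g, ] <- rep(mean(y), grid_points)
      next
    }
    best <- NULL
    for (cost in cost_grid) for (gam in gamma_grid) {
      pred_oof <- numeric(length(y))
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        m <- e1071::svm(x = matrix(ptn[tr], ncol = 1), y = y[tr],
                        cost = cost, gamma = gam)
        pred_oof[!tr] <- predict(m, matrix(ptn[!tr], ncol = 1))
      }
      rr <- 1 - sum((y - pred_oof)^2) / sum((y - mean(y))^2)
      if (is.null(best) || rr > best$r2)
        best <- list(r2 = rr, cost = cost, gamma = gam)
    }
    r2[g] <- best$r2
    m <- e1071::svm(x = matrix(ptn, ncol = 1), y = y,
                    cost = best$cost, gamma = best$gamma)
    profiles[g, ] <- predict(m, matrix(grid, ncol = 1))
  }
  structure(list(profiles = profiles, r2 = r2, grid = grid * span + min(pt)),
            class = "pseudotime_profiles")
}

#' Cluster pseudotime profiles into prototypical dynamics
#'
#' Profiles with R-squared below `r2_cut` are considered not significant
#' and excluded. Passing profiles are standardized (so adding a constant
#' to a profile changes nothing) and clustered by affinity propagation
#' with similarity the negative squared distance and preference the
#' median similarity; exemplars are the prototypical dynamics.
#'
#' @param prof a [fit_pseudotime_profiles()] result.
#' @param r2_cut minimum out-of-fold R-squared (default 0.35).
#' @return list: `labels` (named by gene; exemplar gene names as values),
#'   `exemplars` (gene names), `exemplar_profiles` (standardized
#'   profiles), or all empty when nothing passes.
#' @export
cluster_profiles <- function(prof, r2_cut = 0.35) {
  stopifnot(inherits(prof, "pseudotime_profiles"))
  pass <- names(prof$r2)[prof$r2 >= r2_cut]
  if (length(pass) == 0)
    return(list(labels = setNames(character(0), character(0)),
                exemplars = character(0),
                exemplar_profiles = matrix(numeric(0), 0, 0)))
  P <- prof$profiles[pass, , drop = FALSE]
  Z <- t(apply(P, 1, function(x) {
    s <- sd(x)
    if (s < .Machine$double.eps) x - mean(x) else (x - mean(x)) / s
  }))
  if (length(pass) == 1) {
    return(list(labels = setNames(pass, pass), exemplars = pass,
                exemplar_profiles = Z))
  }
  S <- -as.matrix(dist(Z))^2
  ap <- affinity_propagation(S)
  labels <- setNames(pass[ap$exemplar_of], pass)
  list(labels = labels, exemplars = pass[ap$exemplars],
       exemplar_profiles = Z[pass[ap$exemplars], , drop = FALSE])
}
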