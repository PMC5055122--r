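#' Thresholds for binarizing marker posteriors
#'
#' @param prob_cut posterior probability that a cell-type coefficient
#'   exceeds the Baseline coefficient (default 0.998; 0.95 is the adult
#'   dataset's relaxed setting).
#' @param theta_frac a cluster's posterior-median extra molecules must be
#'   at least this fraction of the highest cluster's (default 0.35).
#' @param min_top_median the highest cluster's posterior-median extra
#'   molecules must exceed this (default 0.4 molecules/cell).
#' @return object of class `binarization_thresholds`.
#' @export
binarization_thresholds <- function(prob_cut = 0.998, theta_frac = 0.35,
                                    min_top_median = 0.4) {
  if (prob_cut <= 0 || prob_cut > 1) stop("prob_cut must be in (0, 1]")
  if (theta_frac < 0 || theta_frac > 1) stop("theta_frac must be in [0, 1]")
  if (min_top_median < 0) stop("min_top_median must be >= 0")
  structure(list(prob_cut = prob_cut, theta_frac = theta_frac,
                 min_top_median = min_top_median),
            class = "binarization_thresholds")
}

#' Binarize one gene's posterior into a cell-type enrichment pattern
#'
#' Cluster `k` is called 1 iff (1) its coefficient exceeds the Baseline
#' coefficient with posterior probability at least `prob_cut`, (2) its
#' posterior-median extra molecules reach `theta_frac` of the top
#' cluster's, and (3) the top cluster's posterior median exceeds
#' `min_top_median`. "Median posterior" is read as the median of the
#' posterior distribution on the extra-molecules scale (beta - 1).
#'
#' @param post a `gene_posterior` from [fit_gene_glm()].
#' @param thr a [binarization_thresholds()].
#' @return named integer 0/1 vector over clusters.
#' @export
binarize_gene <- function(post, thr = binarization_thresholds()) {
  stopifnot(inherits(post, "gene_posterior"))
  med <- post$median_extra[post$clusters]
  top <- max(med)
  cond1 <- post$prob_gt_baseline[post$clusters] >= thr$prob_cut
  cond2 <- med >= thr$theta_frac * top
  cond3 <- top > thr$min_top_median
  setNames(as.integer(cond1 & cond2 & cond3), post$clusters)
}

#' Fit the marker model for every gene and binarize
#'
#' Runs [fit_gene_glm()] per gene (per-gene seeds derived from `seed`) and
#' assembles the MAP expression profile and the binary pattern matrix.
#' Genes whose sampler fails the split-Rhat <= 1.1 check are flagged and
#' excluded from binarization (their pattern row is NA).
#'
#' @param counts genes x cells count matrix.
#' @param labels named cell -> cluster assignment.
#' @param thr a [binarization_thresholds()].
#' @param n_warmup,n_draws MCMC sizes per gene.
#' @param seed master seed.
#' @param genes optional subset of genes to fit (default all).
#' @return object of class `marker_fit`: `binary` (genes x clusters 0/1,
#'   NA rows for non-converged genes), `map_profile` (genes x clusters
#'   expected molecules for a typical cell of the cluster:
#'   MAP(beta_k - 1) + MAP(beta_Baseline - 1) * mean cluster baseline),
#'   `median_extra`, `prob_gt_baseline`, `converged`, `clusters`, `design`.
#' @export
fit_markers <- function(counts, labels, thr = binarization_thresholds(),
                        n_warmup = 600, n_draws = 600, seed = 1L,
                        genes = rownames(counts)) {
  design <- marker_design(counts, labels)
  clusters <- design$clusters
  cl_baseline <- vapply(clusters, function(cl)
    mean(design$x[design$x[, cl] == 1, 1]), numeric(1))
  n_g <- length(genes)
  binary <- matrix(NA_integer_, n_g, length(clusters),
                   dimnames = list(genes, clusters))
  map_profile <- matrix(NA_real_, n_g, length(clusters),
                        dimnames = list(genes, clusters))
  median_extra <- map_profile
  probs <- map_profile
  converged <- setNames(logical(n_g), genes)
  for (i in seq_len(n_g)) {
    g <- genes[i]
    post <- fit_gene_glm(counts[g, ], design, n_warmup = n_warmup,
                         n_draws = n_draws, seed = derive_seed(seed, i))
    converged[i] <- post$converged
    map_extra <- post$map[clusters] - 1
    map_profile[i, ] <- map_extra + (post$map["Baseline"] - 1) * cl_baseline
    median_extra[i, ] <- post$median_extra[clusters]
    probs[i, ] <- post$prob_gt_baseline[clusters]
    if (post$converged) binary[i, ] <- binarize_gene(post, thr)
  }
  structure(list(binary = binary, map_profile = map_profile,
                 median_extra = median_extra, prob_gt_baseline = probs,
                 converged = converged, clusters = clusters,
                 thresholds = thr),
            class = "marker_fit")
}

#' Group transcription factors by their binarized expression pattern
#'
#' Genes sharing an identical 0/1 pattern over clusters mark the same set
#' of cell populations; restricting to an input transcription-factor list
#' yields candidate regulators per pattern. The all-zero pattern is
#' reported separately, and TFs absent from the binary matrix (or without
#' a converged fit) are listed as unassessed.
#'
#' @param binary genes x clusters 0/1 matrix (NA rows allowed).
#' @param tf_list character vector of transcription-factor gene IDs.
#' @return list: `groups` (pattern string -> TF gene vector, excluding the
#'   all-zero pattern), `all_zero` (TFs with the all-zero pattern),
#'   `unassessed` (TFs missing or non-converged).
#' @export
tf_pattern_groups <- function(binary, tf_list) {
  present <- intersect(tf_list, rownames(binary))
  ok <- present[stats::complete.cases(binary[present, , drop = FALSE])]
  unassessed <- setdiff(tf_list, ok)
  if (length(ok) == 0)
    return(list(groups = list(), all_zero = character(0),
                unassessed = unassessed))
  pat <- apply(binary[ok, , drop = FALSE], 1, paste, collapse = "")
  zero <- paste(rep("0", ncol(binary)), collapse = "")
  groups <- split(ok, pat)
  all_zero <- if (zero %in% names(groups)) groups[[zero]] else character(0)
  groups[[zero]] <- NULL
  list(groups = groups, all_zero = all_zero, unassessed = unassessed)
}
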