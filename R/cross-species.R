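#' Filter homolog pairs informative for cross-species comparison
#'
#' A naive transcriptome-wide correlation between cell types of two
#' species is biased upward by depth and breadth confounders, so the
#' feature space is cut to genes with significant, type-restricted
#' variation. A homolog pair survives when: (1) it is significantly
#' expressed (binarized call) in at least one cell type in *both*
#' species; (2) it is significant in fewer than `max_sig_types` cell
#' types in at least one species; (3) within at least one species its
#' maximal MAP expression exceeds `min_max_expr` and its minimal MAP
#' expression falls below `max_min_expr` molecules per cell. Non-bijective
#' homolog rows are dropped and counted.
#'
#' @param mapA,mapB gene x cluster MAP expression matrices (per species).
#' @param binA,binB gene x cluster 0/1 binarized matrices.
#' @param homologs data.frame with columns `gene1` (species A), `gene2`
#'   (species B).
#' @param max_sig_types strict upper bound on significant types (default 6).
#' @param min_max_expr molecules/cell (default 1.5).
#' @param max_min_expr molecules/cell (default 0.25).
#' @return list: `pairs` (data.frame gene1, gene2 surviving the filter),
#'   `n_dropped_non_bijective`.
#' @export
filter_comparison_genes <- function(mapA, mapB, binA, binB, homologs,
                                    max_sig_types = 6, min_max_expr = 1.5,
                                    max_min_expr = 0.25) {
  dup <- duplicated(homologs$gene1) | duplicated(homologs$gene1, fromLast = TRUE) |
         duplicated(homologs$gene2) | duplicated(homologs$gene2, fromLast = TRUE)
  n_dropped <- sum(dup)
  hom <- homologs[!dup, , drop = FALSE]
  hom <- hom[hom$gene1 %in% rownames(mapA) & hom$gene2 %in% rownames(mapB), ,
             drop = FALSE]
  keep <- vapply(seq_len(nrow(hom)), function(i) {
    a <- hom$gene1[i]; b <- hom$gene2[i]
    sa <- binA[a, ]; sb <- binB[b, ]
    if (anyNA(sa) || anyNA(sb)) return(FALSE)
    nA <- sum(sa); nB <- sum(sb)
    if (nA < 1 || nB < 1) return(FALSE)                       # (1)
    if (!(nA < max_sig_types || nB < max_sig_types)) return(FALSE)  # (2)
    ea <- mapA[a, ]; eb <- mapB[b, ]
    rangeOK <- (max(ea) > min_max_expr && min(ea) < max_min_expr) ||
               (max(eb) > min_max_expr && min(eb) < max_min_expr)   # (3)
    rangeOK
  }, logical(1))
  list(pairs = hom[keep, , drop = FALSE],
       n_dropped_non_bijective = n_dropped)
}

#' Cross-species cell-type similarity matrix
#'
#' Pearson correlation between every pair of cell types of the two
#' species, computed over the filtered homologous gene panel.
#'
#' @param mapA,mapB gene x cluster MAP expression matrices.
#' @param gene_pairs data.frame (`gene1`, `gene2`) from
#'   [filter_comparison_genes()].
#' @return list of class `similarity_matrix`: `S` (types of A x types of
#'   B), `n_genes`, `undefined` (count of entries undefined because a
#'   profile was constant; such entries are NA).
#' @export
similarity_matrix <- function(mapA, mapB, gene_pairs) {
  if (nrow(gene_pairs) < 10) stop("need >= 10 gene pairs")
  A <- mapA[gene_pairs$gene1, , drop = FALSE]
  B <- mapB[gene_pairs$gene2, , drop = FALSE]
  S <- suppressWarnings(cor(A, B))
  undefined <- sum(!is.finite(S))
  S[!is.finite(S)] <- NA_real_
  structure(list(S = S, n_genes = nrow(gene_pairs), undefined = undefined),
            class = "similarity_matrix")
}

#' Mutual best matches between cell types of two species
#'
#' A pair `(m, n)` is reported when `S[m, n]` is the maximum of both its
#' row and its column; ties produce multiple pairs.
#'
#' @param sim a [similarity_matrix()] result (or a bare matrix).
#' @return data.frame with `typeA`, `typeB`, `correlation`.
#' @export
mutual_best_matches <- function(sim) {
  S <- if (inherits(sim, "similarity_matrix")) sim$S else as.matrix(sim)
  row_max <- apply(S, 1, max, na.rm = TRUE)
  col_max <- apply(S, 2, max, na.rm = TRUE)
  hits <- which(!is.na(S) & S >= row_max[row(S)] & S >= rep(col_max, each = nrow(S)),
                arr.ind = TRUE)
  out <- data.frame(typeA = rownames(S)[hits[, 1]],
                    typeB = colnames(S)[hits[, 2]],
                    correlation = S[hits], stringsAsFactors = FALSE)
  out[order(out$typeA, out$typeB), , drop = FALSE]
}

#' Half-sampling time of a cell type
#'
#' Fits a Gaussian kernel density to the per-cell sampling ages of one
#' cluster and returns the age `t*` at which the area under the smooth
#' curve reaches half the total — the time by which half of the cluster's
#' cells had been observed.
#'
#' @param ages numeric vector of per-cell ages (>= 5 values unless all
#'   identical).
#' @param bw kernel bandwidth; the default is the standard `bw.nrd0` rule.
#' @param n_boot optional bootstrap replicates for a 95% CI (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return the half-sampling time; when `n_boot > 0`, a `ci` attribute
#'   carries the percentile interval.
#' @export
half_sampling_time <- function(ages, bw = "nrd0", n_boot = 0, seed = 1L) {
  ages <- ages[is.finite(ages)]
  if (length(unique(ages)) == 1) return(unique(ages))
  if (length(ages) < 5) stop("need >= 5 cells with ages")
  point <- function(a) {
    d <- density(a, bw = bw)
    cdf <- cumsum(d$y)
    cdf <- cdf / cdf[length(cdf)]
    # bisection via monotone interpolation of the empirical smooth CDF
    approx(cdf, d$x, xout = 0.5, ties = "ordered")$y
  }
  t_star <- point(ages)
  if (n_boot > 0) {
    set.seed(seed)
    reps <- replicate(n_boot, point(sample(ages, replace = TRUE)))
    attr(t_star, "ci") <- quantile(reps, c(0.025, 0.975), names = FALSE)
  }
  t_star
}
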