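#' Fit the CV-vs-mean noise model by support vector regression
#'
#' Regresses `log2(CV)` on `log2(mean)` across all genes with positive
#' mean, using an RBF support vector regression (defaults, `gamma = 0.06`).
#' Genes whose observed CV exceeds the prediction carry biological
#' variation beyond the technical (sampling + depth) noise floor; their
#' residual (observed - predicted log2 CV) ranks them.
#'
#' @param counts genes x cells matrix of raw counts.
#' @param gamma RBF kernel width of the SVR (default 0.06).
#' @return object of class `noise_model`: the fitted SVR, the per-gene
#'   table (`gene`, `mean`, `cv`, `residual`) over positive-mean genes.
#' @export
fit_noise_model <- function(counts, gamma = 0.06) {
  mu <- rowMeans(counts)
  pos <- mu > 0
  if (sum(pos) < 50) stop("need >= 50 genes with positive mean")
  sdg <- apply(counts[pos, , drop = FALSE], 1, sd)
  if (all(sdg == 0)) stop("degenerate input: all genes constant")
  cv <- sdg / mu[pos]
  ok <- cv > 0
  lx <- log2(mu[pos][ok])
  ly <- log2(cv[ok])
  fit <- e1071::svm(x = matrix(lx, ncol = 1), y = ly, gamma = gamma)
  resid <- ly - as.numeric(predict(fit, matrix(lx, ncol = 1)))
  tab <- data.frame(gene = rownames(counts)[pos][ok], mean = mu[pos][ok],
                    cv = cv[ok], residual = resid,
                    stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab, gamma = gamma),
            class = "noise_model")
}

#' Select the most variable genes under a fitted noise model
#'
#' Returns the `n` genes with the largest CV residual; ties broken by
#' higher mean, then lexicographic gene ID. A pure function of its inputs.
#'
#' @param model a [fit_noise_model()] result.
#' @param n number of genes to select.
#' @return character vector of gene IDs, length `min(n, nrow(table))`.
#' @export
select_variable_genes <- function(model, n) {
  stopifnot(inherits(model, "noise_model"))
  if (n <= 0) stop("n must be positive")
  tab <- model$table
  ord <- order(-tab$residual, -tab$mean, tab$gene)
  tab$gene[ord][seq_len(min(n, nrow(tab)))]
}

#' Genes to exclude before re-clustering a sibling cluster
#'
#' After a BackSPIN split into clusters A and B, genes peculiar to B would
#' produce spurious sub-clusters of A through carryover or contamination.
#' Starting from the genes assigned to B: (1) a core set is kept — sibling
#' genes whose mean pairwise correlation with the other sibling genes is at
#' least `core_corr`; (2) the core is expanded with every gene correlated
#' at least `expand_corr` with at least `core_fraction` of the core; the
#' union is returned as the exclusion list.
#'
#' Correlation is Pearson on `log1p(count)` profiles across the cells
#' provided. The study quantifies none of the thresholds; the defaults are
#' exposed here.
#'
#' @param counts genes x cells count matrix (cells of the cluster being
#'   re-clustered, or the parent).
#' @param sibling_genes non-empty character vector of sibling genes.
#' @param core_corr core membership threshold (default 0.5).
#' @param expand_corr expansion correlation threshold (default 0.3).
#' @param core_fraction fraction of core genes an expansion candidate must
#'   be correlated with (default 0.5).
#' @return character vector of genes to exclude (always a superset of the
#'   core). If no core can be formed, the input set is returned with a
#'   warning.
#' @export
exclude_sibling_genes <- function(counts, sibling_genes, core_corr = 0.5,
                                  expand_corr = 0.3, core_fraction = 0.5) {
  if (length(sibling_genes) == 0) stop("sibling_genes must be non-empty")
  sibling_genes <- intersect(sibling_genes, rownames(counts))
  lg <- log1p(t(counts))                       # cells x genes
  sib <- lg[, sibling_genes, drop = FALSE]
  csib <- suppressWarnings(cor(sib))
  csib[!is.finite(csib)] <- 0
  if (length(sibling_genes) == 1) {
    core <- sibling_genes
  } else {
    mean_corr <- (rowSums(csib) - 1) / (ncol(csib) - 1)
    core <- sibling_genes[mean_corr >= core_corr]
  }
  if (length(core) == 0) {
    warning("no core set at core_corr = ", core_corr,
            "; returning sibling set unchanged")
    return(sibling_genes)
  }
  call <- suppressWarnings(cor(lg, lg[, core, drop = FALSE]))
  call[!is.finite(call)] <- 0
  frac <- rowMeans(call >= expand_corr)
  expansion <- rownames(call)[frac >= core_fraction]
  sort(union(core, expansion))
}
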