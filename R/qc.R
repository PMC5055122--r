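#' Quality-control thresholds for cells and genes
#'
#' @param min_molecules lower bound on total molecules per cell (inclusive).
#' @param max_molecules upper bound on total molecules per cell (inclusive).
#'   The defaults are the mouse-embryo bounds (2000-26000 molecules); human
#'   embryo, adult and stem-cell datasets use their own bounds.
#' @param min_gene_total genes detected at fewer than this many molecules
#'   across the whole dataset are dropped (strict `<`; default 4).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_molecules = 2000, max_molecules = 26000,
                          min_gene_total = 4) {
  if (min_molecules < 0 || min_molecules >= max_molecules)
    stop("need 0 <= min_molecules < max_molecules")
  if (min_gene_total < 0) stop("min_gene_total must be >= 0")
  structure(list(min_molecules = min_molecules,
                 max_molecules = max_molecules,
                 min_gene_total = min_gene_total),
            class = "qc_thresholds")
}

#' Filter cells by total molecule count
#'
#' Retains exactly the cells whose total molecule count `t` satisfies
#' `min_molecules <= t <= max_molecules` (both bounds inclusive). The low
#' bound removes broken cells; the high bound removes putative doublets.
#'
#' @param counts genes x cells matrix of non-negative integer counts.
#' @param thr a [qc_thresholds()].
#' @return the filtered matrix, with a `"qc_report"` attribute recording
#'   per-cell totals and the min/median/max of retained cells.
#' @export
filter_cells_by_molecules <- function(counts, thr) {
  stopifnot(inherits(thr, "qc_thresholds"))
  totals <- colSums(counts)
  keep <- totals >= thr$min_molecules & totals <= thr$max_molecules
  if (!any(keep)) stop("no cells pass QC")
  out <- counts[, keep, drop = FALSE]
  kept <- totals[keep]
  attr(out, "qc_report") <- list(
    n_in = ncol(counts), n_out = ncol(out), totals = totals,
    retained_min = min(kept), retained_median = median(kept),
    retained_max = max(kept))
  out
}

#' Drop genes detected below a dataset-wide molecule total
#'
#' Removes genes whose total count across all (QC-passing) cells is
#' strictly below `min_gene_total`; the cell set is unchanged. Applied
#' after the cell filter, so "the whole dataset" is the post-QC dataset.
#'
#' @inheritParams filter_cells_by_molecules
#' @return the filtered matrix with a `"qc_report"` attribute.
#' @export
filter_low_count_genes <- function(counts, thr) {
  stopifnot(inherits(thr, "qc_thresholds"))
  totals <- rowSums(counts)
  keep <- totals >= thr$min_gene_total
  out <- counts[keep, , drop = FALSE]
  attr(out, "qc_report") <- list(n_in = nrow(counts), n_out = nrow(out),
                                 gene_totals = totals)
  out
}

#' Optional consistency filter against two alternative clusterings
#'
#' The source study additionally excluded cells whose cluster assignment
#' was inconsistent across BackSPIN parameter settings and that had low
#' molecule counts; the exact rule is unspecified there. This hook matches
#' the two labelings greedily by overlap and drops cells whose matched
#' labels disagree AND whose molecule total is below the dataset median.
#' OFF by default in [run_pipeline()].
#'
#' @param counts genes x cells count matrix.
#' @param labels1,labels2 named cluster assignments (per cell) from two
#'   parameter settings.
#' @return the filtered matrix.
#' @export
filter_inconsistent_cells <- function(counts, labels1, labels2) {
  cells <- colnames(counts)
  l1 <- labels1[cells]; l2 <- labels2[cells]
  # greedy label matching by overlap
  tab <- table(l1, l2)
  matched <- character(0)
  pairs <- list()
  for (i in order(-tab)) {
    r <- rownames(tab)[(i - 1) %% nrow(tab) + 1]
    c <- colnames(tab)[(i - 1) %/% nrow(tab) + 1]
    if (!(r %in% names(pairs)) && !(c %in% matched)) {
      pairs[[r]] <- c; matched <- c(matched, c)
    }
  }
  consistent <- !is.na(l1) & !is.na(l2) &
    vapply(seq_along(l1), function(i)
      identical(pairs[[l1[i]]], unname(l2[i])), logical(1))
  totals <- colSums(counts)
  drop <- !consistent & totals < median(totals)
  counts[, !drop, drop = FALSE]
}
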