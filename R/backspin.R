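#' Assign genes to the daughter blocks of a split by center of mass
#'
#' For each gene, the center of mass of its expression over the parent's
#' sorted cell positions `1..n` is `cm(g) = sum(pos * A[g, ]) / sum(A[g, ])`;
#' the gene goes to the left daughter `K` if `cm(g) <= x_s`, else to `L`.
#' The center of mass exploits the correlation-based ordering: a gene
#' expressed in a tight subset of cells pulls its mass toward that
#' subset's position even when a broad low-level expression exists on the
#' other side, anticipating clusters found at later iterations. All-zero
#' genes (undefined center) go to `K`. The assignment is invariant to
#' scaling any gene by a positive factor.
#'
#' @param A genes x cells matrix whose columns already follow the sorted
#'   cell order.
#' @param x_s the split position (left-block size).
#' @return list with character vectors `K` and `L` of gene IDs.
#' @export
assign_genes_center_of_mass <- function(A, x_s) {
  n <- ncol(A)
  pos <- seq_len(n)
  tot <- rowSums(A)
  cm <- ifelse(tot > 0, as.numeric(A %*% pos) / tot, 1)
  list(K = rownames(A)[cm <= x_s], L = rownames(A)[cm > x_s])
}

# Pearson correlation matrix of cells over the selected genes, on
# log1p counts. The SPIN dissimilarity is 1 - this matrix.
cell_correlation <- function(counts, genes) {
  lg <- log1p(counts[genes, , drop = FALSE])
  C <- suppressWarnings(cor(lg))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

# default per-node feature selection: CV-residual ranking with sibling
# exclusion
default_feature_selector <- function(counts, exclude, n_features) {
  keep <- setdiff(rownames(counts), exclude)
  sub <- counts[keep, , drop = FALSE]
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]
  if (nrow(sub) < 50) return(rownames(sub))
  model <- tryCatch(fit_noise_model(sub), error = function(e) NULL)
  if (is.null(model)) return(rownames(sub))
  select_variable_genes(model, min(n_features, nrow(model$table)))
}

#' Recursive BackSPIN biclustering of cells and genes
#'
#' Alternates feature selection and SPIN-based splitting. At each node:
#' select features among the node's cells (excluding genes flagged by
#' [exclude_sibling_genes()] for the sibling branch), compute the cell
#' correlation matrix on `log1p` counts over those features, sort it with
#' [spin_sort()], find the best split with [find_split()], and recurse
#' when the split is strong enough. Genes of the node are co-assigned to
#' the daughters by [assign_genes_center_of_mass()], so the leaves
#' partition both the cells and the genes.
#'
#' The stopping rule: recursion continues only while
#' `f(x_s) > stop_const * max(mean off-diagonal of C, 0)` and
#' `depth < numLevels`; the raw rule `f(x_s) > stop_const` is available
#' via `normalize_stop = FALSE`. Nodes with fewer than `min_cells` cells
#' become leaves.
#'
#' @param counts genes x cells matrix (after QC).
#' @param params a [backspin_params()].
#' @param n_features number of variable genes selected per node.
#' @param feature_selector optional function
#'   `(counts, exclude, n_features) -> gene IDs`; the default re-runs the
#'   CV-residual selection per node.
#' @param seed RNG seed (per-node seeds derived from it).
#' @param min_cells below this, a node becomes a leaf (default 4).
#' @param normalize_stop compare `f(x_s)` against
#'   `stop_const * mean off-diagonal correlation` (default) instead of the
#'   raw `stop_const`.
#' @param sibling_exclusion apply [exclude_sibling_genes()] between
#'   daughters before re-clustering (default TRUE).
#' @return object of class `cluster_tree`; see [cluster_tree_leaves()] and
#'   [cluster_tree_labels()].
#' @export
backspin <- function(counts, params = backspin_params(), n_features = 500,
                     feature_selector = default_feature_selector,
                     seed = 1L, min_cells = 4, normalize_stop = TRUE,
                     sibling_exclusion = TRUE) {
  node_counter <- new.env()
  node_counter$i <- 0L
  build <- function(cells, genes, depth, exclude) {
    node_counter$i <- node_counter$i + 1L
    id <- node_counter$i
    sub <- counts[genes, cells, drop = FALSE]
    node <- list(id = id, cells = cells, genes = genes, depth = depth,
                 children = NULL, split = NULL)
    if (length(cells) < max(min_cells, 2) || depth >= params$numLevels)
      return(finish_leaf(node, sub, seed))
    feats <- feature_selector(sub, exclude, n_features)
    feats <- intersect(feats, genes)
    if (length(feats) < 2) return(finish_leaf(node, sub, seed))
    C <- cell_correlation(sub, feats)
    sorted <- spin_sort(C, params, seed = derive_seed(seed, id))
    sp <- find_split(sorted)
    off <- (sum(C) - length(cells)) / (length(cells)^2 - length(cells))
    threshold <- if (normalize_stop) params$stop_const * max(off, 0)
                 else params$stop_const
    if (sp$f <= threshold ||
        sp$x_s < min_cells || (sp$n - sp$x_s) < min_cells)
      return(finish_leaf(node, sub, seed))
    ord_cells <- cells[sorted$order]
    ga <- assign_genes_center_of_mass(
      counts[genes, ord_cells, drop = FALSE], sp$x_s)
    cells_K <- ord_cells[seq_len(sp$x_s)]
    cells_L <- ord_cells[(sp$x_s + 1):sp$n]
    excl_for_K <- excl_for_L <- character(0)
    if (sibling_exclusion) {
      if (length(ga$L) > 0)
        excl_for_K <- suppressWarnings(
          exclude_sibling_genes(counts[genes, cells_K, drop = FALSE], ga$L))
      if (length(ga$K) > 0)
        excl_for_L <- suppressWarnings(
          exclude_sibling_genes(counts[genes, cells_L, drop = FALSE], ga$K))
    }
    node$split <- sp
    node$order <- ord_cells
    node$children <- list(
      build(cells_K, ga$K, depth + 1, union(exclude, excl_for_K)),
      build(cells_L, ga$L, depth + 1, union(exclude, excl_for_L)))
    node
  }
  tree <- build(colnames(counts), rownames(counts), 0L, character(0))
  tree <- label_leaves(tree)
  structure(list(root = tree, params = params, seed = seed),
            class = "cluster_tree")
}

# Leaf post-processing: SPIN-sort the node's gene correlation matrix
# (the within-cluster gene view of the sorted submatrix).
finish_leaf <- function(node, sub, seed) {
  expressed <- rownames(sub)[rowSums(sub) > 0]
  if (length(expressed) >= 2 && length(expressed) <= 2000 && ncol(sub) >= 3) {
    G <- suppressWarnings(cor(t(log1p(sub[expressed, , drop = FALSE]))))
    G[!is.finite(G)] <- 0
    diag(G) <- 1
    gs <- tryCatch(spin_sort(G, seed = derive_seed(seed, node$id + 100000L)),
                   error = function(e) NULL)
    if (!is.null(gs)) node$gene_order <- expressed[gs$order]
  }
  node
}

label_leaves <- function(root) {
  counter <- new.env(); counter$i <- 0L
  walk <- function(node) {
    if (is.null(node$children)) {
      counter$i <- counter$i + 1L
      node$label <- sprintf("cluster_%02d", counter$i)
    } else {
      node$children <- lapply(node$children, walk)
    }
    node
  }
  walk(root)
}

#' Leaves of a cluster tree
#' @param tree a `cluster_tree`.
#' @return list of leaf nodes (each with `cells`, `genes`, `label`).
#' @export
cluster_tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (is.null(node$children)) out[[length(out) + 1]] <<- node
    else lapply(node$children, walk)
    invisible(NULL)
  }
  walk(tree$root)
  out
}

#' Per-cell cluster labels from a cluster tree
#' @param tree a `cluster_tree`.
#' @return named character vector, cell -> leaf label.
#' @export
cluster_tree_labels <- function(tree) {
  leaves <- cluster_tree_leaves(tree)
  labs <- unlist(lapply(leaves, function(l) setNames(rep(l$label,
    length(l$cells)), l$cells)))
  labs[colnames_of_tree(tree)]
}

colnames_of_tree <- function(tree) tree$root$cells

#' Serialize a cluster tree to JSON
#' @param tree a `cluster_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_tree_json <- function(tree, path) {
  strip <- function(node) {
    out <- list(id = node$id, depth = node$depth, cells = node$cells,
                genes = node$genes)
    if (!is.null(node$label)) out$label <- node$label
    if (!is.null(node$split))
      out$split <- list(x_s = node$split$x_s, f = node$split$f,
                        f_curve = node$split$f_curve, n = node$split$n)
    if (!is.null(node$children)) out$children <- lapply(node$children, strip)
    out
  }
  jsonlite::write_json(strip(tree$root), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Within-species cluster-correlation summary on the binarized matrix
#'
#' Pearson correlation between cluster columns of the 0/1 binarized
#' gene x cluster matrix, restricted to genes significant in at least one
#' cluster and detected at a mean of at least 1 molecule per cell in at
#' least one cluster. Rows/columns are ordered by [spin_sort()] for
#' display.
#'
#' @param counts genes x cells count matrix.
#' @param labels named cell -> cluster assignment.
#' @param binary genes x clusters 0/1 matrix from [binarize_genes()].
#' @param params a [backspin_params()] for the SPIN ordering.
#' @param seed RNG seed for the SPIN ordering.
#' @return list: `S` (clusters x clusters correlation, SPIN-ordered),
#'   `genes_used`.
#' @export
cluster_correlation_matrix <- function(counts, labels, binary,
                                       params = backspin_params(),
                                       seed = 1L) {
  clusters <- colnames(binary)
  if (length(clusters) < 2) stop("need >= 2 clusters")
  cells <- intersect(colnames(counts), names(labels))
  means <- sapply(clusters, function(cl) {
    in_cl <- cells[labels[cells] == cl]
    rowMeans(counts[rownames(binary), in_cl, drop = FALSE])
  })
  keep <- rowSums(binary, na.rm = TRUE) >= 1 & apply(means, 1, max) >= 1
  if (sum(keep) < 2) stop("fewer than 2 genes pass the correlation filter")
  B <- binary[keep, , drop = FALSE]
  S <- suppressWarnings(cor(B))
  S[!is.finite(S)] <- 0
  diag(S) <- 1
  ord <- spin_sort(S, params, seed = seed)$order
  list(S = S[ord, ord], genes_used = rownames(B))
}

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between two partitions of the same
#' items; 1 = identical partitions, ~0 = random agreement.
#'
#' @param a,b label vectors of equal length.
#' @return the ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
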