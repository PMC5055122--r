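#' Specification of a synthetic UMI count experiment
#'
#' Bundles the parameters of the negative-binomial count generator used
#' throughout the test suite and the analysis scripts. Counts are drawn from
#' a negative binomial with mean \eqn{\mu} and variance
#' \eqn{\mu + \mu^2 \phi}, where \eqn{\phi} is `dispersion` (so
#' `dispersion = 0` is the Poisson limit). In the overdispersion notation of
#' the marker model (variance \eqn{\mu (1 + rv)}) this corresponds to
#' \eqn{rv = \mu \phi}.
#'
#' @param n_genes number of genes.
#' @param n_cells number of cells.
#' @param n_types number of cell types.
#' @param base_mean baseline expected molecules per cell per gene (> 0).
#' @param marker_fold fold-change of a type's marker genes in that type
#'   (>= 1).
#' @param markers_per_type number of marker genes per type. Marker panels
#'   are contiguous, disjoint gene blocks assigned deterministically: type
#'   `t` owns genes `(t-1)*markers_per_type + 1 .. t*markers_per_type`.
#' @param libsize_cv coefficient of variation of the per-cell library-size
#'   factor (>= 0). Factors are log-normal with expectation 1, a strictly
#'   positive heavy-ish tailed model of sequencing depth.
#' @param dispersion NB overdispersion \eqn{\phi} (>= 0; 0 = Poisson).
#' @param mean_sdlog spread (log scale SD) of per-gene baseline means
#'   around `base_mean` (default 1). Real UMI data span orders of
#'   magnitude in gene abundance; this heterogeneity is what gives
#'   cell-cell correlation profiles their positive baseline. 0 makes all
#'   non-marker genes share `base_mean` exactly.
#' @param seed integer RNG seed.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000, n_cells = 500, n_types = 5,
                           base_mean = 0.5, marker_fold = 10,
                           markers_per_type = 20, libsize_cv = 0.3,
                           dispersion = 0.5, mean_sdlog = 1, seed = 1L) {
  num <- list(n_genes = n_genes, n_cells = n_cells, n_types = n_types,
              base_mean = base_mean, marker_fold = marker_fold,
              markers_per_type = markers_per_type, libsize_cv = libsize_cv,
              dispersion = dispersion, mean_sdlog = mean_sdlog, seed = seed)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (length(v) != 1 || !is.numeric(v) || !is.finite(v))
      stop("synthetic_spec: `", nm, "` must be a single finite number")
  }
  if (n_genes < 1 || n_cells < 1 || n_types < 1 || markers_per_type < 0)
    stop("synthetic_spec: counts must be >= 1 (markers_per_type >= 0)")
  if (base_mean <= 0) stop("synthetic_spec: base_mean must be > 0")
  if (marker_fold < 1) stop("synthetic_spec: marker_fold must be >= 1")
  if (libsize_cv < 0) stop("synthetic_spec: libsize_cv must be >= 0")
  if (dispersion < 0) stop("synthetic_spec: dispersion must be >= 0")
  if (mean_sdlog < 0) stop("synthetic_spec: mean_sdlog must be >= 0")
  if (n_types * markers_per_type > n_genes)
    stop("synthetic_spec: marker panels exceed n_genes")
  num$seed <- as.integer(seed)
  structure(num, class = "synthetic_spec")
}

# Log-normal library-size factors with expectation 1 and the requested CV.
libsize_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# NB sampler in the mean/dispersion parameterization; phi = 0 -> Poisson.
rnb <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

# genes x types matrix of expected molecules per cell. Per-gene baseline
# means are log-normal around base_mean (expectation base_mean); markers
# multiply their gene's own baseline by marker_fold in their type.
type_mean_matrix <- function(spec) {
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  type_ids <- sprintf("T%d", seq_len(spec$n_types))
  base <- if (spec$mean_sdlog > 0)
    spec$base_mean * rlnorm(spec$n_genes, -spec$mean_sdlog^2 / 2,
                            spec$mean_sdlog)
  else rep(spec$base_mean, spec$n_genes)
  mm <- matrix(base, spec$n_genes, spec$n_types,
               dimnames = list(gene_ids, type_ids))
  if (spec$markers_per_type > 0) {
    for (t in seq_len(spec$n_types)) {
      block <- ((t - 1) * spec$markers_per_type + 1):(t * spec$markers_per_type)
      mm[block, t] <- mm[block, t] * spec$marker_fold
    }
  }
  mm
}

#' Simulate a clustered UMI count matrix
#'
#' Draws a genes x cells count matrix with `n_types` planted cell types.
#' Each cell's expected counts are
#' `libsize_factor * (mixture_weights %*% t(mean_matrix))`; pure cells use
#' one-hot weights over the types. Optional convex mixture weights emulate
#' cells of intermediate identity (e.g. stem-cell-derived cultures that
#' interpolate between in vivo types).
#'
#' @param spec a [synthetic_spec()].
#' @param mixture_weights optional `n_cells x n_types` matrix of convex
#'   weights (rows sum to 1 within 1e-9). `NULL` assigns pure types in
#'   equal contiguous blocks.
#' @return A list with class `synthetic_counts`:
#'   `counts` (genes x cells integer matrix), `cell_meta` (data.frame with
#'   `cell`, `type`), and `truth` — a ground-truth list with
#'   `type_of_cell`, `mean_matrix`, `libsize`, `marker_genes` (list per
#'   type), `cycling_flags`, `latent_time`, `mixture_weights`.
#' @export
make_clustered_counts <- function(spec, mixture_weights = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  mm <- type_mean_matrix(spec)
  n <- spec$n_cells
  types <- sort(rep_len(seq_len(spec$n_types), n))
  if (is.null(mixture_weights)) {
    W <- matrix(0, n, spec$n_types)
    W[cbind(seq_len(n), types)] <- 1
  } else {
    W <- as.matrix(mixture_weights)
    if (nrow(W) != n || ncol(W) != spec$n_types)
      stop("mixture_weights must be n_cells x n_types")
    if (any(!is.finite(W)) || any(W < 0))
      stop("mixture_weights must be finite and non-negative")
    if (any(abs(rowSums(W) - 1) > 1e-9))
      stop("mixture_weights rows must sum to 1")
    types <- max.col(W, ties.method = "first")
  }
  lib <- libsize_factors(n, spec$libsize_cv)
  mu <- mm %*% t(W)                      # genes x cells expectation, lib = 1
  mu <- sweep(mu, 2, lib, `*`)
  counts <- matrix(rnb(length(mu), as.vector(mu), spec$dispersion),
                   nrow = spec$n_genes, dimnames = dimnames(mu))
  cell_ids <- sprintf("C%04d", seq_len(n))
  colnames(counts) <- cell_ids
  marker_genes <- if (spec$markers_per_type > 0) {
    lapply(seq_len(spec$n_types), function(t)
      rownames(mm)[((t - 1) * spec$markers_per_type + 1):(t * spec$markers_per_type)])
  } else rep(list(character(0)), spec$n_types)
  names(marker_genes) <- colnames(mm)
  truth <- list(type_of_cell = setNames(colnames(mm)[types], cell_ids),
                mean_matrix = mm, libsize = setNames(lib, cell_ids),
                marker_genes = marker_genes,
                cycling_flags = setNames(rep(FALSE, n), cell_ids),
                latent_time = NULL, mixture_weights = W, spec = spec)
  structure(list(counts = counts,
                 cell_meta = data.frame(cell = cell_ids,
                                        type = colnames(mm)[types],
                                        stringsAsFactors = FALSE),
                 truth = truth),
            class = "synthetic_counts")
}

#' Simulate a pair of "species" with homologous genes and matched types
#'
#' Generates two count matrices over homologous gene panels. The first
#' `n_shared_types` types of each species are planted correspondences:
#' their log mean vectors are equal at `divergence = 0` and acquire
#' independent additive Gaussian jitter of SD
#' `divergence * sd(log means)` as `divergence` grows — expression levels
#' drift between species without erasing marker structure, and the
#' Pearson correlation of matched-type profiles decreases in
#' `divergence`. Remaining types are species-specific (independent
#' marker blocks).
#'
#' @param spec a [synthetic_spec()]; `n_types` is the per-species type count.
#' @param n_shared_types number of planted type correspondences
#'   (<= `n_types`).
#' @param divergence in `[0, 1]`; 0 = identical matched means.
#' @return list with class `synthetic_species_pair`: `species1`, `species2`
#'   (each a `synthetic_counts`), and `truth` containing `homolog_map`
#'   (data.frame gene1, gene2; one-to-one) and `planted_matches`
#'   (data.frame type1, type2).
#' @export
make_species_pair <- function(spec, n_shared_types, divergence) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(divergence) != 1 || !is.finite(divergence) ||
      divergence < 0 || divergence > 1)
    stop("divergence must be in [0, 1]")
  if (n_shared_types > spec$n_types)
    stop("n_shared_types must be <= n_types")
  set.seed(spec$seed)

  s1 <- make_clustered_counts(spec)
  # Species 2: blend shared-type log means with independent noise.
  mm1 <- s1$truth$mean_matrix
  mm2 <- mm1
  if (divergence > 0 && n_shared_types > 0) {
    lm <- log(mm1[, seq_len(n_shared_types), drop = FALSE])
    jitter <- matrix(rnorm(length(lm), 0, divergence * stats::sd(lm)),
                     nrow = nrow(lm))
    mm2[, seq_len(n_shared_types)] <- exp(lm + jitter)
  }
  if (n_shared_types < spec$n_types) {
    # species-specific types get fresh marker blocks drawn from the tail
    # genes so they do not collide with species 1's panels
    free <- setdiff(seq_len(spec$n_genes),
                    seq_len(spec$n_types * spec$markers_per_type))
    for (t in (n_shared_types + 1):spec$n_types) {
      mm2[, t] <- spec$base_mean
      if (spec$markers_per_type > 0 && length(free) >= spec$markers_per_type) {
        pick <- free[seq_len(spec$markers_per_type)]
        free <- setdiff(free, pick)
        mm2[pick, t] <- spec$base_mean * spec$marker_fold
      }
    }
  }
  seed2 <- derive_seed(spec$seed, 2L)
  spec2 <- spec
  spec2$seed <- seed2
  s2 <- make_clustered_counts(spec2)
  # redraw species 2 counts from its own mean matrix
  set.seed(seed2)
  types2 <- sort(rep_len(seq_len(spec$n_types), spec$n_cells))
  lib2 <- libsize_factors(spec$n_cells, spec$libsize_cv)
  mu2 <- sweep(mm2[, types2, drop = FALSE], 2, lib2, `*`)
  s2$counts <- matrix(rnb(length(mu2), as.vector(mu2), spec$dispersion),
                      nrow = spec$n_genes)
  # species-2 gene namespace: same underlying genes, shuffled order
  perm <- sample.int(spec$n_genes)
  s2$counts <- s2$counts[perm, , drop = FALSE]
  g2_ids <- sprintf("H%04d", seq_len(spec$n_genes))
  rownames(s2$counts) <- g2_ids
  colnames(s2$counts) <- sprintf("D%04d", seq_len(spec$n_cells))
  s2$truth$mean_matrix <- mm2[perm, , drop = FALSE]
  rownames(s2$truth$mean_matrix) <- g2_ids
  colnames(s2$truth$mean_matrix) <- sprintf("U%d", seq_len(spec$n_types))
  cells2 <- colnames(s2$counts)
  s2$truth$type_of_cell <- setNames(colnames(s2$truth$mean_matrix)[types2], cells2)
  s2$truth$libsize <- setNames(lib2, cells2)
  s2$cell_meta <- data.frame(cell = cells2,
                             type = unname(s2$truth$type_of_cell),
                             stringsAsFactors = FALSE)
  homolog_map <- data.frame(gene1 = rownames(s1$counts)[perm],
                            gene2 = g2_ids, stringsAsFactors = FALSE)
  planted <- data.frame(type1 = colnames(mm1)[seq_len(n_shared_types)],
                        type2 = colnames(s2$truth$mean_matrix)[seq_len(n_shared_types)],
                        stringsAsFactors = FALSE)
  structure(list(species1 = s1, species2 = s2,
                 truth = list(homolog_map = homolog_map,
                              planted_matches = planted,
                              divergence = divergence)),
            class = "synthetic_species_pair")
}

# Smooth mean curves for trajectory genes, amplitude base_mean * fold at peak.
trajectory_mean <- function(shape, t, base_mean, fold) {
  lo <- 0.1
  switch(shape,
    "monotone-up"   = base_mean * (lo + (fold - lo) * t),
    "monotone-down" = base_mean * (lo + (fold - lo) * (1 - t)),
    "transient"     = base_mean * (lo + (fold - lo) * exp(-((t - 0.5) / 0.18)^2)),
    stop("unknown trajectory shape: ", shape))
}

#' Simulate genes varying smoothly along a latent trajectory
#'
#' Cells get a latent time uniform on `[0, 1]`; the first `n_dynamic_genes`
#' genes follow smooth NB mean curves of latent time (cycled through
#' `shapes`), the rest stay flat at `base_mean`. Emulates a maturing
#' neuronal lineage sampled across developmental ages.
#'
#' @param spec a [synthetic_spec()] (`n_types` is ignored; one lineage).
#' @param n_dynamic_genes number of trajectory-dependent genes
#'   (<= `n_genes`).
#' @param shapes character subset of
#'   `c("monotone-up", "monotone-down", "transient")`.
#' @return a `synthetic_counts` list; `truth$latent_time` holds the per-cell
#'   latent time and `truth$dynamic_genes` a data.frame (gene, shape).
#' @export
make_trajectory <- function(spec, n_dynamic_genes,
                            shapes = c("monotone-up", "monotone-down", "transient")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(shapes) == 0) stop("shapes must be a non-empty set")
  shapes <- match.arg(shapes, c("monotone-up", "monotone-down", "transient"),
                      several.ok = TRUE)
  if (n_dynamic_genes > spec$n_genes)
    stop("n_dynamic_genes must be <= n_genes")
  set.seed(spec$seed)
  n <- spec$n_cells
  tt <- runif(n)
  lib <- libsize_factors(n, spec$libsize_cv)
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  cell_ids <- sprintf("C%04d", seq_len(n))
  base <- if (spec$mean_sdlog > 0)
    spec$base_mean * rlnorm(spec$n_genes, -spec$mean_sdlog^2 / 2,
                            spec$mean_sdlog)
  else rep(spec$base_mean, spec$n_genes)
  mu <- matrix(base, spec$n_genes, n, dimnames = list(gene_ids, cell_ids))
  shape_of <- character(0)
  if (n_dynamic_genes > 0) {
    shape_of <- rep_len(shapes, n_dynamic_genes)
    for (g in seq_len(n_dynamic_genes))
      mu[g, ] <- trajectory_mean(shape_of[g], tt, base[g], spec$marker_fold)
  }
  mu <- sweep(mu, 2, lib, `*`)
  counts <- matrix(rnb(length(mu), as.vector(mu), spec$dispersion),
                   nrow = spec$n_genes, dimnames = dimnames(mu))
  truth <- list(type_of_cell = setNames(rep("T1", n), cell_ids),
                mean_matrix = NULL, libsize = setNames(lib, cell_ids),
                cycling_flags = setNames(rep(FALSE, n), cell_ids),
                latent_time = setNames(tt, cell_ids),
                dynamic_genes = data.frame(gene = gene_ids[seq_len(n_dynamic_genes)],
                                           shape = shape_of,
                                           stringsAsFactors = FALSE),
                spec = spec)
  structure(list(counts = counts,
                 cell_meta = data.frame(cell = cell_ids, type = "T1",
                                        latent_time = tt,
                                        stringsAsFactors = FALSE),
                 truth = truth),
            class = "synthetic_counts")
}

#' Plant a correlated cell-cycle module into a count matrix
#'
#' Flags a random fraction of cells as cycling and redraws their counts for
#' the given cycle genes from NB means multiplied by `fold`. With
#' `fold = 1` the counts are returned untouched (bit-identical), only the
#' flags are drawn.
#'
#' @param sim a `synthetic_counts` object (needs `truth$libsize`; per-gene
#'   base means are taken from `truth$mean_matrix` or inferred as the gene's
#'   library-size-adjusted mean).
#' @param cycle_genes character vector of gene IDs (subset of the matrix).
#' @param frac_cycling fraction of cells to flag, in `[0, 1]`.
#' @param fold mean multiplier for cycle genes in cycling cells (>= 1).
#' @param seed RNG seed.
#' @return the modified `synthetic_counts`, with `truth$cycling_flags`
#'   updated and `truth$cycle_genes`, `truth$cycle_fold` recorded.
#' @export
add_cycle_module <- function(sim, cycle_genes, frac_cycling, fold, seed = 1L) {
  stopifnot(inherits(sim, "synthetic_counts"))
  if (!all(cycle_genes %in% rownames(sim$counts)))
    stop("cycle_genes must be a subset of the matrix genes")
  if (frac_cycling < 0 || frac_cycling > 1)
    stop("frac_cycling must be in [0, 1]")
  if (fold < 1) stop("fold must be >= 1")
  set.seed(seed)
  n <- ncol(sim$counts)
  flagged <- sample.int(n, size = round(frac_cycling * n))
  flags <- rep(FALSE, n)
  flags[flagged] <- TRUE
  spec <- sim$truth$spec
  if (fold > 1 && length(flagged) > 0 && length(cycle_genes) > 0) {
    lib <- sim$truth$libsize
    mm <- sim$truth$mean_matrix
    if (!is.null(mm)) {
      base_mu <- mm[cycle_genes, sim$truth$type_of_cell[flagged], drop = FALSE]
    } else {
      gmean <- rowMeans(sweep(sim$counts[cycle_genes, , drop = FALSE], 2, lib, `/`))
      base_mu <- matrix(gmean, length(cycle_genes), length(flagged))
    }
    mu <- sweep(base_mu * fold, 2, lib[flagged], `*`)
    sim$counts[cycle_genes, flagged] <-
      rnb(length(mu), as.vector(mu), spec$dispersion)
  }
  sim$truth$cycling_flags <- setNames(flags, colnames(sim$counts))
  sim$truth$cycle_genes <- cycle_genes
  sim$truth$cycle_fold <- fold
  sim
}
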