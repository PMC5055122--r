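#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analysis scripts:
# a 5-type clustered UMI matrix (the "reference tissue"), a matched pair of
# species, a maturing lineage, and a cycling subpopulation. Writes MTX +
# sidecars and ground-truth JSON under results/data/.

suppressMessages(library(cellspin))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20160926L

spec <- synthetic_spec(n_genes = 1000, n_cells = 500, n_types = 5,
                       base_mean = 0.5, marker_fold = 10,
                       markers_per_type = 20, seed = seed)
tissue <- make_clustered_counts(spec)
write_counts_mtx(tissue$counts, "results/data/tissue", tissue$cell_meta)
write_truth_json(tissue$truth, "results/data/tissue_truth.json")
message(sprintf("tissue: %d genes x %d cells, %d types, median %d molecules/cell",
                nrow(tissue$counts), ncol(tissue$counts), spec$n_types,
                median(colSums(tissue$counts))))

pair <- make_species_pair(
  synthetic_spec(n_genes = 600, n_cells = 300, n_types = 10,
                 base_mean = 0.5, marker_fold = 10, markers_per_type = 20,
                 seed = seed + 1),
  n_shared_types = 10, divergence = 0.3)
write_counts_mtx(pair$species1$counts, "results/data/species1",
                 pair$species1$cell_meta)
write_counts_mtx(pair$species2$counts, "results/data/species2",
                 pair$species2$cell_meta)
write.table(pair$truth$homolog_map, "results/data/homologs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("species pair written (divergence 0.3, 10 planted correspondences)")

traj <- make_trajectory(
  synthetic_spec(n_genes = 800, n_cells = 500, n_types = 1, base_mean = 3,
                 marker_fold = 12, markers_per_type = 0, dispersion = 0.3,
                 mean_sdlog = 0.5, seed = seed + 2),
  n_dynamic_genes = 50)
write_counts_mtx(traj$counts, "results/data/trajectory", traj$cell_meta)
write_truth_json(traj$truth, "results/data/trajectory_truth.json")
message("trajectory: 50 dynamic genes over 500 cells")

cyc_spec <- synthetic_spec(n_genes = 800, n_cells = 400, n_types = 1,
                           base_mean = 0.8, marker_fold = 1,
                           markers_per_type = 0, seed = seed + 3)
cycling <- add_cycle_module(make_clustered_counts(cyc_spec),
                            sprintf("G%04d", 1:40), frac_cycling = 0.5,
                            fold = 8, seed = seed + 4)
write_counts_mtx(cycling$counts, "results/data/cycling", cycling$cell_meta)
write_truth_json(cycling$truth, "results/data/cycling_truth.json")
message(sprintf("cycling dataset: %d of %d cells flagged cycling",
                sum(cycling$truth$cycling_flags), ncol(cycling$counts)))
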