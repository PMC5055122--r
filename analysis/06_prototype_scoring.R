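#!/usr/bin/env Rscript
# Train the prototype classifier on the synthetic reference, score mixed
# "in vitro"-like cells, and lay everything out on the wheel plot,
# including the scrambled negative control.

suppressMessages(library(cellspin))
seed <- 20160926L
ref <- read_counts_mtx("results/data/tissue")
labels <- setNames(ref$cell_meta$type, ref$cell_meta$cell)

out_spec <- synthetic_spec(n_genes = 1000, n_cells = 150, n_types = 5,
                           base_mean = 0.5, marker_fold = 10,
                           markers_per_type = 20, seed = seed + 5)
outgroup <- make_clustered_counts(out_spec)

panel <- select_training_genes(ref$counts, labels, outgroup$counts,
                               n_initial = 800)
grouping <- setNames(paste0("Proto", 1:5), paste0("T", 1:5))
choice <- choose_regularization(ref$counts, labels, grouping, panel,
                                C_grid = c(0.001, 0.01, 0.1), n_iters = 10,
                                seed = seed)
message(sprintf("panel: %d genes; accuracy plateau reached at C = %g",
                length(panel), choice$C))
print(choice$curve, row.names = FALSE)

model <- train_prototype_classifier(ref$counts, labels, grouping, panel,
                                    C = 0.01, seed = seed)
# mixed-identity query cells: convex blends of two prototypes
mix_spec <- synthetic_spec(n_genes = 1000, n_cells = 100, n_types = 5,
                           base_mean = 0.5, marker_fold = 10,
                           markers_per_type = 20, seed = seed + 6)
W <- matrix(0, 100, 5)
W[, 2] <- seq(0, 1, length.out = 100)
W[, 4] <- 1 - W[, 2]
mix <- make_clustered_counts(mix_spec, mixture_weights = W)

p_ref <- score_cells(model, ref$counts)
p_mix <- score_cells(model, mix$counts)
wl <- wheel_layout(p_ref)
coords_mix <- wheel_coordinates(p_mix, wl)
scr <- scrambled_control(model, ref$counts, seed = seed + 7)
coords_scr <- wheel_coordinates(scr$probabilities, wl)

r_real <- mean(sqrt(rowSums(wl$coords^2)))
r_scr <- mean(sqrt(rowSums(coords_scr^2)))
message(sprintf("mean wheel radius: reference %.3f, scrambled %.3f (ratio %.2f)",
                r_real, r_scr, r_scr / r_real))
message("vertex order: ", paste(wl$vertex_order, collapse = " -> "))

write.csv(cbind(as.data.frame(p_ref), wl$coords),
          "results/wheel_reference.csv")
write.csv(cbind(as.data.frame(p_mix), coords_mix),
          "results/wheel_mixtures.csv")
write.csv(as.data.frame(coords_scr), "results/wheel_scrambled.csv")
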