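#!/usr/bin/env Rscript
# Pseudotime over the synthetic lineage: select time-varying genes by the
# NB likelihood-ratio test, fit the principal curve, smooth per-gene
# profiles with SVR, and cluster the significant profiles.

suppressMessages(library(cellspin))
d <- read_counts_mtx("results/data/trajectory")
truth <- jsonlite::fromJSON("results/data/trajectory_truth.json")
latent <- unlist(truth$latent_time)
ages <- 11 + round(latent * 7)

sel <- select_time_varying_genes(d$counts, ages, fdr = 0.01)
dyn <- vapply(truth$dynamic_genes$gene, identity, character(1))
message(sprintf("selected %d time-varying genes (%d of %d planted recovered)",
                length(sel), sum(dyn %in% sel), length(dyn)))

fit <- fit_principal_curve_pseudotime(d$counts, sel, ages = ages)
rho <- cor(fit$pseudotime, latent[names(fit$pseudotime)], method = "spearman")
message(sprintf("pseudotime vs planted latent time: Spearman rho = %.3f", rho))
write.csv(data.frame(cell = names(fit$pseudotime),
                     pseudotime = unname(fit$pseudotime)),
          "results/pseudotime.csv", row.names = FALSE)

prof <- fit_pseudotime_profiles(fit, d$counts, genes = sel, seed = 11)
cl <- cluster_profiles(prof, r2_cut = 0.35)
message(sprintf("%d genes pass R^2 >= 0.35; %d prototypical dynamics",
                length(cl$labels), length(cl$exemplars)))
write.csv(prof$profiles, "results/pseudotime_profiles.csv")
write.table(data.frame(gene = names(cl$labels), cluster = unname(cl$labels)),
            "results/profile_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
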