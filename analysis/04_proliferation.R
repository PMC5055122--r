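#!/usr/bin/env Rscript
# Learn the proliferation index on the cycling dataset and evaluate it
# against the planted cycling flags.

suppressMessages(library(cellspin))
d <- read_counts_mtx("results/data/cycling")
truth <- jsonlite::fromJSON("results/data/cycling_truth.json")
flags <- unlist(truth$cycling_flags)

panel <- select_cycle_genes(d$counts, sprintf("G%04d", 1:500))
message(sprintf("cycle panel: %d genes (40 planted)", length(panel)))
model <- learn_cycle_score(d$counts, panel, alpha = 0.01, seed = 7)
sc <- score_proliferation(model, d$counts)
acc <- mean(sc$cycling == flags[sc$cell])
message(sprintf("proliferation call accuracy vs planted flags: %.3f", acc))
message(sprintf("%d of %d panel genes carry nonzero weight",
                sum(model$weights != 0), length(model$weights)))
write.csv(sc, "results/proliferation_scores.csv", row.names = FALSE)
write.csv(data.frame(gene = names(model$weights), weight = model$weights),
          "results/proliferation_weights.csv", row.names = FALSE)
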