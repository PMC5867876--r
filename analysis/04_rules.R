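#!/usr/bin/env Rscript
# Step 4: rough-set rule learning on the optimal feature set.
#
# Discretizes the optimal genes (entropy/MDL), builds the discernibility
# function over generalized decisions, extracts a Johnson reduct, runs
# RIPPER on the continuous values restricted to the reduct, and exports
# the ordered rule set plus the rule-interaction network edges. Writes
# results/rules.json and results/rule_edges.tsv.

suppressPackageStartupMessages(library(xenorules))

m <- load_matrix("results/data/matrix_imputed.csv", "class",
                 id_column = "cell_id")
features <- readLines("results/optimal_features.txt")

ds <- build_decision_system(m, features, discretize = "mdl")
dm <- discernibility_matrix(ds, keep_pairs = FALSE)
reduct <- if (length(dm$g) > 0) johnson_reduct(dm) else features
cat("Johnson reduct (", length(reduct), " of ", length(features),
    " optimal genes): ", paste(reduct, collapse = ", "), "\n", sep = "")

rules <- ripper(ds, reduct = reduct, params = ripper_params(seed = 31))
write_rules(rules, "results/rules.json")
print(rules)

pred <- predict(rules, m$values)
acc <- mean(pred == as.character(m$labels))
cat(sprintf("Training accuracy of the rule set: %.3f\n", acc))

edges <- rule_network_edges(rules)
utils::write.table(edges, "results/rule_edges.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("Wrote results/rules.json and results/rule_edges.tsv (",
    nrow(edges), " edges)\n", sep = "")
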