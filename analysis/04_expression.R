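#!/usr/bin/env Rscript
# Stage 4: gene expression. Housekeeping stability check, geometric-mean
# normalization, and the per-gene zone test (expression ~ zone + (1|trial)).

suppressPackageStartupMessages(library(stressphen))

out_dir <- "results/expression"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

qpcr <- utils::read.csv("results/data/qpcr.csv", check.names = FALSE)
hk <- suppressWarnings(housekeeping_stability(qpcr))
message("housekeeping stability (zone effect should be null):")
print(hk, digits = 3)

expr <- expression_table(qpcr)
summ <- zone_expression_summary(expr)
print(summ, digits = 3)

genes <- suppressWarnings(analyze_gene(expr))
message("per-gene zone tests:")
print(genes, digits = 3)

utils::write.csv(expr, file.path(out_dir, "relative_expression.csv"),
                 row.names = FALSE)
utils::write.csv(summ, file.path(out_dir, "zone_summary.csv"),
                 row.names = FALSE)
utils::write.csv(genes, file.path(out_dir, "gene_zone_tests.csv"),
                 row.names = FALSE)
utils::write.csv(hk, file.path(out_dir, "housekeeping_stability.csv"),
                 row.names = FALSE)
message("wrote ", out_dir, "/*.csv")
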