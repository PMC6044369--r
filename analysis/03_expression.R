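#!/usr/bin/env Rscript
# Outlier-expression calls for the case sample, ssGSEA signature scoring
# across all samples, category-fraction summaries, and score-based sample
# clustering.
suppressPackageStartupMessages(library(polypomics))

sim_dir <- "results/simulated"
out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mat <- read_matrix_tsv(file.path(sim_dir, "log2_fpkm.tsv"))
truth <- utils::read.table(file.path(sim_dir, "outlier_truth.tsv"),
                           header = TRUE, stringsAsFactors = FALSE)
case <- colnames(mat)[1]

calls <- detect_sample_outliers(mat, case)
utils::write.table(calls, file.path(out, "outlier_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
hit <- length(intersect(calls$gene, truth$gene))
message(sprintf(
  "outliers in %s: %d high, %d low; %d/%d planted recovered, %d false calls",
  case, sum(calls$direction == "high"), sum(calls$direction == "low"),
  hit, nrow(truth), length(setdiff(calls$gene, truth$gene))))

# signatures built from the planted outlier directions: the case sample
# should score top for the upregulated set and bottom for the downregulated
sets <- list(
  up_in_case = truth$gene[truth$direction == "high"],
  down_in_case = truth$gene[truth$direction == "low"])
write_gmt(sets, file.path(out, "signatures.gmt"))
scores <- ssgsea_matrix(mat, sets)
utils::write.table(
  data.frame(sample = rownames(scores), scores, check.names = FALSE),
  file.path(out, "ssgsea_scores.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("ssGSEA: case sample ranks %d/%d for the up-signature",
                match(case, rownames(scores)[order(-scores[, "up_in_case"])]),
                nrow(scores)))

cl <- cluster_by_scores(scores, k = 2)
writeLines(cl$newick, file.path(out, "sample_clustering.nwk"))
solo <- names(cl$groups)[cl$groups == cl$groups[[case]]]
message(sprintf("clustering: case group holds %d sample(s): %s",
                length(solo), paste(solo, collapse = ", ")))

# category fractions as printed in gene-list summaries, e.g. 474/528 -> 90%
set.seed(20260924L)
background <- rownames(mat)
high_genes <- calls$gene[calls$direction == "high"]
coding <- sample(background, length(background) * 0.9)
cf <- category_fraction(high_genes, coding, background)
message(sprintf("of %d highly expressed genes, %d (%d%%) are annotated (p = %.3g)",
                length(high_genes), cf$count, cf$percent, cf$p_value))
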