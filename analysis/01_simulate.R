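#!/usr/bin/env Rscript
# Generate every synthetic input for the downstream analyses, with planted
# ground truth: a candidate-variant table shaped like the tumor/normal x
# WGS/RNA study design, a 28-sample expression matrix, a host/microbial
# read-pair stream, and case/control window densities.
suppressPackageStartupMessages(library(polypomics))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- sim_config(seed = 20260924L)
print(config)

sim <- sim_variant_table(config)
write_variants_tsv(sim$variants, file.path(out, "variants.tsv"))
write_variants_vcf(sim$variants, file.path(out, "variants.vcf"))
writeLines(c(sim$panel_keys), file.path(out, "panel_keys.txt"))
writeLines(c(sim$snp_keys), file.path(out, "snp_keys.txt"))
jsonlite::write_json(sim$truth, file.path(out, "variant_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)
jsonlite::write_json(sim$profiles, file.path(out, "conservation_profiles.json"),
                     pretty = FALSE)
message(sprintf("variants: %d candidates (1 planted survivor, %d decoys)",
                nrow(sim$variants), nrow(sim$truth$decoys)))

expr <- sim_expression(config)
write_matrix_tsv(expr$log2_fpkm, file.path(out, "log2_fpkm.tsv"))
utils::write.table(expr$truth, file.path(out, "outlier_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("expression: %d genes x %d samples, %d planted outliers",
                nrow(expr$log2_fpkm), ncol(expr$log2_fpkm), nrow(expr$truth)))

db <- gen_microbial_db(config)
utils::write.table(db$taxonomy, file.path(out, "taxonomy.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
pairs <- sim_metagenome_pairs(config, db, n_pairs = 50000L)
# stage a 2,000-pair excerpt on disk (the full 50k stream is regenerated
# deterministically from the shared config where it is consumed)
excerpt <- polypomics:::subset_pairs(pairs, pairs$pairs$pair_id[1:2000])
write_alignments_tsv(excerpt, file.path(out, "metagenome_hits.tsv"))
jsonlite::write_json(pairs$truth[c("fractions", "cassette_pairs")],
                     file.path(out, "metagenome_truth.json"),
                     auto_unbox = TRUE)
message(sprintf("metagenome: %d pairs (%d cassette, %d host-flagged)",
                nrow(pairs$pairs), length(pairs$truth$cassette_pairs),
                sum(pairs$pairs$host_r1 | pairs$pairs$host_r2)))

cnv <- sim_cnv(config)
utils::write.table(cnv$case, file.path(out, "cnv_case.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cnv$control, file.path(out, "cnv_control.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(cnv$truth, file.path(out, "cnv_truth.txt"))
message(sprintf("cnv: %d chromosomes x %d windows, gains planted on %s",
                config$cnv_chroms, config$cnv_windows,
                paste(cnv$truth, collapse = ", ")))
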