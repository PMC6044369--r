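cfg <- sim_config(seed = 11)

test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_reference(cfg), gen_reference(cfg))
  expect_identical(gen_microbial_db(cfg), gen_microbial_db(cfg))
  expect_identical(sim_variant_table(cfg), sim_variant_table(cfg))
  expect_identical(sim_expression(cfg), sim_expression(cfg))
  expect_identical(sim_cnv(cfg), sim_cnv(cfg))
  db <- gen_microbial_db(cfg)
  expect_identical(sim_metagenome_pairs(cfg, db, 500),
                   sim_metagenome_pairs(cfg, db, 500))
  expect_false(identical(sim_expression(cfg),
                         sim_expression(sim_config(seed = 12))))
})

test_that("reference generator honours chromosome layout and base composition", {
  one <- sim_config(seed = 3, chrom_lengths = c(chr1 = 10000))
  ref <- gen_reference(one)
  expect_length(ref$genome, 1L)
  expect_equal(nchar(ref$genome[["chr1"]]), 10000)
  expect_true(all(strsplit(ref$genome[["chr1"]], "")[[1]] %in%
                    c("A", "C", "G", "T")))
  # exon models never overlap within a transcript
  for (tx in unique(ref$genes$transcript)) {
    ex <- ref$genes[ref$genes$transcript == tx, ]
    ex <- ex[order(ex$start), ]
    expect_true(all(diff(ex$start) > (ex$end[-nrow(ex)] - ex$start[-nrow(ex)])))
  }
  # 100 kb chromosome: each base frequency within 3 binomial SE of 1/4
  big <- gen_reference(sim_config(seed = 3, chrom_lengths = c(chr1 = 100000)))
  counts <- table(strsplit(big$genome[["chr1"]], "")[[1]])
  se <- sqrt(100000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 25000) < 3 * se))
})

test_that("configuration validation rejects degenerate inputs", {
  expect_error(sim_config(chrom_lengths = c(chr1 = -5)), "length")
  expect_error(sim_config(chrom_lengths = numeric()), "chromosome")
  expect_error(sim_config(mixture = c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(sim_config(n_samples = 2), "n_samples")
  expect_error(sim_config(window_lambda = 0), "window_lambda")
  expect_warning(sim_config(outlier_effect = 0.5), "effect size")
})

test_that("microbial db carries the cassette into strains of both phyla", {
  db <- gen_microbial_db(cfg)
  expect_equal(nrow(db$taxonomy), length(db$sequences))
  cs <- db$cassette$strains
  expect_gte(length(unique(db$taxonomy$phylum[db$taxonomy$strain %in% cs])), 2L)
  cas_seq <- substr(db$sequences[[cs[1]]], db$cassette$start,
                    db$cassette$start + db$cassette$length - 1L)
  for (s in cs[-1]) {
    expect_identical(substr(db$sequences[[s]], db$cassette$start,
                            db$cassette$start + db$cassette$length - 1L),
                     cas_seq)
  }
  # without a cassette, a 2-strain db has 2 distinct sequences
  tiny_tax <- data.frame(strain = c("s1", "s2"), species = c("spA", "spB"),
                         family = c("fA", "fB"), phylum = c("pA", "pB"))
  db2 <- gen_microbial_db(cfg, tiny_tax, cassette_strains = character(0))
  expect_length(db2$sequences, 2L)
  expect_error(
    gen_microbial_db(cfg, data.frame(strain = "s", species = "sp",
                                     family = "f", phylum = NA)),
    "phylum")
})

test_that("metagenome mixture and cassette fractions converge at 3 binomial SE", {
  db <- gen_microbial_db(cfg)
  n <- 50000L
  pa <- sim_metagenome_pairs(cfg, db, n)
  src <- pa$truth$source
  non_cas <- src[src$kind != "cassette", ]
  for (tx in names(cfg$mixture)) {
    p <- cfg$mixture[[tx]]
    obs <- sum(non_cas$taxon == tx)
    expect_lt(abs(obs - nrow(non_cas) * p), 3 * sqrt(nrow(non_cas) * p * (1 - p)))
  }
  n_cas <- length(pa$truth$cassette_pairs)
  se <- sqrt(n * 0.05 * 0.95)
  expect_lt(abs(n_cas - n * 0.05), 3 * se)
  # single-taxon mixture: all non-cassette pairs hit only that taxon
  solo <- sim_config(seed = 5, mixture = c(Firmicutes = 1), cassette_fraction = 0,
                     multimap_fraction = 0, noise_fraction = 0, host_fraction = 0)
  pa1 <- sim_metagenome_pairs(solo, db, 100)
  phyla <- db$taxonomy$phylum[match(pa1$hits$target, db$taxonomy$strain)]
  expect_true(all(phyla == "Firmicutes"))
  expect_error(sim_metagenome_pairs(cfg, db, 0), "n_pairs")
  expect_error(
    sim_metagenome_pairs(sim_config(seed = 1, mixture = c(NoSuch = 1)), db, 10),
    "absent")
})

test_that("variant table plants one survivor and per-step decoys", {
  sim <- sim_variant_table(cfg)
  expect_length(sim$truth$survivor_keys, 1L)
  expect_setequal(unique(sim$truth$decoys$step),
                  c("concordance", "uniqueness", "annotation", "support",
                    "selection", "conservation", "structure"))
  # support decoys include the WGS-normal depth-9 boundary family
  v <- sim$variants
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  support_keys <- sim$truth$decoys$key[sim$truth$decoys$step == "support"]
  expect_true(any(v$dp_wgs_n[key %in% support_keys] == 9L))
  # survivor reproduces the exemplar VAF pattern
  s <- v[key == sim$truth$survivor_keys, ]
  expect_equal(s$ad_wgs_n / s$dp_wgs_n, 0.67, tolerance = 0.03)
  expect_equal(s$ad_wgs_p / s$dp_wgs_p, 0.82, tolerance = 0.03)
  expect_equal(s$ad_rna_n / s$dp_rna_n, 0.50, tolerance = 0.03)
  expect_equal(s$ad_rna_p / s$dp_rna_p, 0.70, tolerance = 0.03)
})

test_that("expression simulator plants the requested outliers", {
  ex <- sim_expression(cfg)
  expect_equal(dim(ex$log2_fpkm), c(cfg$n_genes, cfg$n_samples))
  expect_equal(nrow(ex$truth), cfg$n_high + cfg$n_low)
  expect_equal(sum(ex$truth$direction == "high"), cfg$n_high)
  expect_equal(ex$case_sample, colnames(ex$log2_fpkm)[1])
})

test_that("cnv simulator plants the configured depth ratio", {
  cn <- sim_cnv(cfg)
  lam <- cfg$window_lambda
  for (chrom in unique(cn$case$chrom)) {
    mc <- mean(cn$case$count[cn$case$chrom == chrom])
    nw <- sum(cn$case$chrom == chrom)
    target <- if (chrom %in% cn$truth) cfg$trisomy_ratio * lam else lam
    expect_lt(abs(mc - target), 3 * sqrt(target / nw))
  }
  flat <- sim_cnv(sim_config(seed = 2, trisomy_ratio = 1.0))
  for (chrom in unique(flat$case$chrom)) {
    mc <- mean(flat$case$count[flat$case$chrom == chrom])
    expect_lt(abs(mc - 100), 3 * sqrt(100 / 1000))
  }
})
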