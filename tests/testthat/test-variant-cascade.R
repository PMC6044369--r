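# One in-memory variant row builder used across cascade tests.
mk_variant <- function(chrom = "chr1", pos = 100, ref = "G", alt = "A",
                       gene = "g1", flags = "", destab = NA,
                       dp = c(20, 20, 40, 40), ad = c(10, 12, 20, 24)) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             flags = flags, structure_destabilizing = destab,
             dp_wgs_n = dp[1], ad_wgs_n = ad[1],
             dp_wgs_p = dp[2], ad_wgs_p = ad[2],
             dp_rna_n = dp[3], ad_rna_n = ad[3],
             dp_rna_p = dp[4], ad_rna_p = ad[4],
             stringsAsFactors = FALSE)
}

test_that("vaf is alt over depth and rejects zero depth", {
  expect_equal(vaf(10, 20), 0.5)
  expect_equal(vaf(0, 30), 0)
  expect_error(vaf(5, 0), "depth")
  expect_error(vaf(25, 20), "alt_count")
})

test_that("concordance keeps variants found in all four contexts", {
  v <- rbind(
    mk_variant(pos = 1, ad = c(5, 8, 4, 9)),
    mk_variant(pos = 2, ad = c(5, 8, 0, 9)),   # absent in RNA normal
    mk_variant(pos = 3, ad = c(5, 8, 1, 9)))   # one alt read: below presence
  kept <- step_concordance(v)
  expect_equal(kept$pos, 1)
  # a missing context record counts as absent
  v2 <- mk_variant(pos = 4)
  v2$dp_rna_p <- NA
  expect_equal(nrow(step_concordance(v2)), 0)
})

test_that("uniqueness removes panel and SNP keys and is identity on empty sets", {
  v <- rbind(mk_variant(pos = 1), mk_variant(pos = 2), mk_variant(pos = 3))
  k <- paste("chr1", 1:3, "G", "A", sep = ":")
  expect_equal(step_uniqueness(v, panel_keys = k[1])$pos, 2:3)
  expect_equal(step_uniqueness(v, snp_keys = k[2])$pos, c(1, 3))
  expect_equal(step_uniqueness(v), v)
})

test_that("annotation blacklist removes flagged genes, validates vocabulary", {
  v <- rbind(mk_variant(pos = 1, flags = "retrogene"),
             mk_variant(pos = 2, flags = "pseudogene"),
             mk_variant(pos = 3, flags = ""))
  expect_equal(step_annotation(v)$pos, 3)
  all_flagged <- v[1:2, ]
  expect_equal(nrow(step_annotation(all_flagged)), 0)
  bad <- mk_variant(flags = "oncogene")
  expect_error(step_annotation(bad), "unknown annotation flag")
})

test_that("support thresholds are inclusive and applied per clause", {
  # boundary case: WGS 10/10, RNA 30 in one tissue, polyp WGS VAF exactly 0.5
  at_boundary <- mk_variant(dp = c(10, 10, 30, 25), ad = c(4, 5, 15, 10))
  expect_equal(nrow(step_support(at_boundary)), 1)
  low_wgs <- mk_variant(dp = c(9, 10, 30, 25), ad = c(4, 5, 15, 10))
  expect_equal(nrow(step_support(low_wgs)), 0)
  low_rna <- mk_variant(dp = c(10, 10, 29, 25), ad = c(4, 5, 15, 10))
  expect_equal(nrow(step_support(low_rna)), 0)
  low_vaf <- mk_variant(dp = c(20, 100, 40, 100), ad = c(8, 49, 16, 49))
  expect_equal(nrow(step_support(low_vaf)), 0)
})

test_that("polyp selection flags strict VAF increase in every observed assay", {
  sel <- mk_variant(dp = c(21, 22, 100, 110),
                    ad = c(14, 18, 50, 77))          # 0.67->0.82, 0.50->0.70
  out <- rank_polyp_selection(sel)
  expect_true(out$selected)
  eq <- mk_variant(dp = c(20, 20, 40, 40), ad = c(12, 12, 24, 24))
  expect_false(rank_polyp_selection(eq)$selected)
  hom <- mk_variant(dp = c(20, 20, 40, 40), ad = c(19, 20, 38, 40))
  out_hom <- rank_polyp_selection(hom)
  expect_false(out_hom$selected)
  expect_equal(out_hom$zygosity, "hom")
  expect_equal(nrow(rank_polyp_selection(hom,
                                         cascade_config(selection_as_filter = TRUE))),
               1)  # rule is scoped to heterozygous variants
  # mixed: up in WGS only
  mixed <- mk_variant(dp = c(20, 20, 40, 40), ad = c(10, 16, 24, 24))
  expect_false(rank_polyp_selection(mixed)$selected)
  expect_true(rank_polyp_selection(
    mixed, cascade_config(selection_scope = "any_assay"))$selected)
})

test_that("conservation removes variants whose alt allele occurred in evolution", {
  v <- rbind(mk_variant(pos = 1), mk_variant(pos = 2))
  k <- paste("chr1", 1:2, "G", "A", sep = ":")
  profiles <- list(rep("G", 100), c(rep("G", 19), "A"))
  names(profiles) <- k
  kept <- step_conservation(v, profiles)
  expect_equal(kept$pos, 1)
  expect_warning(out <- step_conservation(mk_variant(pos = 9), list()),
                 "without a conservation profile")
  expect_equal(nrow(out), 1)
})

test_that("structure annotation prioritizes but never filters", {
  v <- rbind(mk_variant(pos = 1, destab = TRUE),
             mk_variant(pos = 2, destab = FALSE),
             mk_variant(pos = 3, destab = NA))
  out <- annotate_structure(v)
  expect_equal(out$priority, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(out), nrow(v))
})

test_that("filter steps are monotone and uniqueness/annotation commute", {
  cfg <- sim_config(seed = 21)
  sim <- sim_variant_table(cfg)
  v <- sim$variants
  expect_lte(nrow(step_concordance(v)), nrow(v))
  expect_lte(nrow(step_support(v)), nrow(v))
  a_then_u <- step_uniqueness(step_annotation(v), sim$panel_keys, sim$snp_keys)
  u_then_a <- step_annotation(step_uniqueness(v, sim$panel_keys, sim$snp_keys))
  expect_equal(a_then_u[order(a_then_u$pos), ], u_then_a[order(u_then_a$pos), ],
               ignore_attr = TRUE)
})

test_that("run_cascade matches the brute-force enumeration oracle", {
  for (seed in c(5, 17)) {
    sim <- sim_variant_table(sim_config(seed = seed))
    rep <- run_cascade(sim$variants, sim$panel_keys, sim$snp_keys,
                       sim$profiles, cascade_config())
    orc <- oracle_cascade(sim$variants, sim$panel_keys, sim$snp_keys,
                          sim$profiles)
    # per-step removal counts agree exactly
    removed <- with(rep$steps, stats::setNames(n_in - n_out, step))
    fate_counts <- table(orc$fate)
    for (s in c("concordance", "uniqueness", "annotation", "support",
                "conservation")) {
      expect_equal(unname(removed[s]), unname(fate_counts[s]),
                   ignore_attr = TRUE, label = paste(s, "removals"))
    }
    expect_setequal(rep$surviving_keys$conservation, orc$surviving_keys)
    expect_setequal(rep$top_keys, orc$top_keys)
  }
})

test_that("cascade counts are non-increasing and empty input yields zero report", {
  sim <- sim_variant_table(sim_config(seed = 8))
  rep <- run_cascade(sim$variants, sim$panel_keys, sim$snp_keys, sim$profiles)
  expect_true(all(diff(rep$steps$n_out) <= 0 | rep$steps$n_in[-1] ==
                    rep$steps$n_out[-1]))
  expect_true(all(rep$steps$n_out <= rep$steps$n_in))
  empty <- sim$variants[0, ]
  rep0 <- run_cascade(empty, config = cascade_config())
  expect_true(all(rep0$steps$n_in == 0) && all(rep0$steps$n_out == 0))
})

test_that("truncation mode skips conservation and structure", {
  sim <- sim_variant_table(sim_config(seed = 9))
  rep <- run_cascade(sim$variants, sim$panel_keys, sim$snp_keys, sim$profiles,
                     cascade_config(mode = "truncation"))
  expect_false(any(c("conservation", "structure") %in% rep$steps$step))
})

test_that("planted survivor is recovered with precision and recall 1", {
  sim <- sim_variant_table(sim_config(seed = 33))
  rep <- run_cascade(sim$variants, sim$panel_keys, sim$snp_keys, sim$profiles)
  rec <- cascade_recovery(rep, sim$truth)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  expect_equal(rep$top_keys, sim$truth$survivor_keys)
})
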