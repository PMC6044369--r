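# In-memory pair/hit builders.
mk_pa <- function(hits, host = NULL) {
  ids <- unique(hits$pair_id)
  if (is.null(host)) {
    host <- data.frame(pair_id = ids, host_r1 = FALSE, host_r2 = FALSE,
                       stringsAsFactors = FALSE)
  }
  polypomics:::as_pair_alignments(host, hits)
}

mk_hit <- function(pair_id, read, target, pos, strand = "+", mapq = 60L) {
  data.frame(pair_id = pair_id, read = read, target = target, pos = pos,
             strand = strand, mapq = mapq, stringsAsFactors = FALSE)
}

tax <- default_taxonomy()

test_that("host depletion keeps only pairs with both reads unmapped to host", {
  hits <- rbind(mk_hit("p1", 1, "BU_A", 100), mk_hit("p1", 2, "BU_A", 400, "-"),
                mk_hit("p2", 1, "BU_A", 100), mk_hit("p2", 2, "BU_A", 400, "-"))
  host <- data.frame(pair_id = c("p1", "p2"),
                     host_r1 = c(TRUE, FALSE), host_r2 = c(FALSE, FALSE))
  out <- host_deplete(polypomics:::as_pair_alignments(host, hits))
  expect_equal(out$pairs$pair_id, "p2")
  empty <- polypomics:::as_pair_alignments(host[0, ], hits[0, ])
  expect_equal(nrow(host_deplete(empty)$pairs), 0)
})

test_that("pair selection: unique-read quality branch", {
  uniq_good <- mk_pa(rbind(mk_hit("p1", 1, "BU_A", 100, "+", 30L),
                           mk_hit("p1", 2, "BU_A", 400, "-", 30L)))
  expect_true(select_pair(uniq_good)[["p1"]])
  uniq_q0 <- mk_pa(rbind(mk_hit("p2", 1, "BU_A", 100, "+", 0L),
                         mk_hit("p2", 2, "BU_A", 400, "-", 0L)))
  expect_false(select_pair(uniq_q0)[["p2"]])
  no_hits <- polypomics:::as_pair_alignments(
    data.frame(pair_id = "p3", host_r1 = FALSE, host_r2 = FALSE),
    mk_hit("p9", 1, "BU_A", 1))
  expect_error(select_pair(no_hits), "without any hit")
})

test_that("pair selection: multi-hit proper-pair branch", {
  # both reads multi-hit; one combination convergent on the same target
  proper <- mk_pa(rbind(
    mk_hit("p1", 1, "BU_A", 100, "+", 0L), mk_hit("p1", 1, "BF_A", 900, "+", 0L),
    mk_hit("p1", 2, "BU_A", 400, "-", 0L), mk_hit("p1", 2, "EC_A", 50, "-", 0L)))
  expect_true(select_pair(proper)[["p1"]])
  # same orientation only -> rejected
  ff <- mk_pa(rbind(
    mk_hit("p2", 1, "BU_A", 100, "+", 0L), mk_hit("p2", 1, "BU_A", 600, "+", 0L),
    mk_hit("p2", 2, "BU_A", 400, "+", 0L), mk_hit("p2", 2, "BU_A", 900, "+", 0L)))
  expect_false(select_pair(ff)[["p2"]])
  # convergent but span outside the insert window
  far <- mk_pa(rbind(
    mk_hit("p3", 1, "BU_A", 100, "+", 0L), mk_hit("p3", 1, "BU_A", 110, "+", 0L),
    mk_hit("p3", 2, "BU_A", 5000, "-", 0L), mk_hit("p3", 2, "BU_A", 5100, "-", 0L)))
  expect_false(select_pair(far)[["p3"]])
  expect_true(select_pair(far, insert_max = 6000)[["p3"]])
})

test_that("rank-exclusive assignment counts single-taxon pairs once", {
  # three strain hits all within Bacteroidetes
  multi_in_phylum <- mk_pa(rbind(
    mk_hit("p1", 1, "BU_A", 100, "+", 0L), mk_hit("p1", 1, "BU_B", 150, "+", 0L),
    mk_hit("p1", 2, "BF_A", 400, "-", 0L)))
  expect_equal(unname(assign_rank(multi_in_phylum, tax, "phylum")),
               "Bacteroidetes")
  # two phyla -> discarded
  cross <- mk_pa(rbind(mk_hit("p2", 1, "BU_A", 100, "+", 0L),
                       mk_hit("p2", 2, "CP_A", 400, "-", 0L)))
  expect_equal(unname(assign_rank(cross, tax, "phylum")), "DISCARDED")
  # two strains of one species: species rank assigns, strain rank discards
  sibs <- mk_pa(rbind(mk_hit("p3", 1, "BU_A", 100, "+", 0L),
                      mk_hit("p3", 2, "BU_B", 400, "-", 0L)))
  expect_equal(unname(assign_rank(sibs, tax, "species")),
               "Bacteroides uniformis")
  expect_equal(unname(assign_rank(sibs, tax, "strain")), "DISCARDED")
  unknown <- mk_pa(mk_hit("p4", 1, "NOPE", 1))
  expect_error(assign_rank(unknown, tax, "phylum"), "absent from taxonomy")
})

test_that("rank monotonicity: a strain-assigned pair is assigned at all coarser ranks", {
  cfg <- sim_config(seed = 6)
  db <- gen_microbial_db(cfg)
  pa <- host_deplete(sim_metagenome_pairs(cfg, db, 2000))
  sel <- select_pair(pa)
  selected <- polypomics:::subset_pairs(pa, names(sel)[sel])
  by_rank <- lapply(c(strain = "strain", species = "species",
                      family = "family", phylum = "phylum"),
                    function(r) assign_rank(selected, db$taxonomy, r))
  strain_ok <- by_rank$strain != "DISCARDED"
  for (r in c("species", "family", "phylum")) {
    expect_true(all(by_rank[[r]][strain_ok] != "DISCARDED"))
  }
  # and the coarse assignment is the ancestor of the strain assignment
  anc <- db$taxonomy$phylum[match(by_rank$strain[strain_ok],
                                  db$taxonomy$strain)]
  expect_equal(unname(by_rank$phylum[strain_ok]), anc)
})

test_that("profile matches the literal-rule oracle and keeps full accounting", {
  cfg <- sim_config(seed = 16)
  db <- gen_microbial_db(cfg)
  pa <- host_deplete(sim_metagenome_pairs(cfg, db, 600))
  for (rank in c("phylum", "species")) {
    prof <- profile_taxa(pa, db$taxonomy, rank)
    orc <- oracle_profile(pa, db$taxonomy, rank)
    expect_equal(prof$assigned + prof$discarded + prof$unselected, prof$total)
    expect_equal(prof$discarded, orc$discarded)
    expect_equal(prof$unselected, orc$unselected)
    got <- stats::setNames(prof$table$pairs, prof$table$taxon)
    expect_equal(got[sort(names(got))], orc$counts[sort(names(orc$counts))],
                 ignore_attr = TRUE)
    expect_equal(sum(prof$table$percent), 100, tolerance = 1e-6)
  }
  # all pairs from one taxon -> 100%
  solo_cfg <- sim_config(seed = 2, mixture = c(`Escherichia coli` = 1),
                         cassette_fraction = 0, multimap_fraction = 0,
                         noise_fraction = 0, host_fraction = 0)
  solo <- profile_taxa(sim_metagenome_pairs(solo_cfg, db, 300),
                       db$taxonomy, "species")
  expect_equal(solo$table$taxon, "Escherichia coli")
  expect_equal(solo$table$percent, 100)
})

test_that("enrichment ratio is computed per million host-depleted pairs", {
  expect_equal(enrichment_ratio(700, 1e6, 1, 1e6), 700)
  expect_equal(enrichment_ratio(70, 1e5, 2, 2e5), 70)
})

test_that("bacterial gene counts require full containment and break ties by id", {
  genes <- data.frame(gene = c("gX", "gY", "gZ"),
                      target = "BU_A",
                      start = c(0, 1000, 2000), end = c(900, 1900, 2900),
                      stringsAsFactors = FALSE)
  hits <- rbind(
    mk_hit("p1", 1, "BU_A", 100), mk_hit("p1", 2, "BU_A", 500, "-"),   # in gX
    mk_hit("p2", 1, "BU_A", 850), mk_hit("p2", 2, "BU_A", 1200, "-"),  # straddles
    mk_hit("p3", 1, "BU_A", 1100), mk_hit("p3", 2, "BU_A", 1500, "-"), # in gY
    mk_hit("p4", 1, "BU_A", 1150), mk_hit("p4", 2, "BU_A", 1550, "-")) # in gY
  out <- bacterial_gene_counts(mk_pa(hits), genes, read_length = 100)
  expect_equal(out$counts$pairs[out$counts$gene == "gX"], 1L)
  expect_equal(out$counts$pairs[out$counts$gene == "gY"], 2L)
  expect_equal(out$ambiguous, 1L)
  expect_equal(out$counts$gene[1], "gY")     # descending count order
  # tie on counts resolves alphabetically
  tie_counts <- out$counts[order(-out$counts$pairs, out$counts$gene), ]
  expect_equal(tie_counts$gene, out$counts$gene)
  expect_error(
    bacterial_gene_counts(mk_pa(hits),
                          data.frame(gene = "g", target = "BU_A",
                                     start = 10, end = 10)),
    "annotation error")
})
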