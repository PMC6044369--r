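# Host-depleted metagenomic profiling.
#
# Pair records are a list of class `pair_alignments` with `pairs`
# (pair_id, host_r1, host_r2) and `hits` (pair_id, read, target, pos,
# strand, mapq).  A read is "uniquely mapped" when it has exactly one
# reported hit; "duplicatedly" (multi-) mapped with two or more.

RANKS <- c("phylum", "family", "species", "strain")

as_pair_alignments <- function(pairs, hits, truth = NULL) {
  structure(list(pairs = pairs, hits = hits, truth = truth),
            class = "pair_alignments")
}

subset_pairs <- function(pa, keep_ids) {
  as_pair_alignments(
    pa$pairs[pa$pairs$pair_id %in% keep_ids, , drop = FALSE],
    pa$hits[pa$hits$pair_id %in% keep_ids, , drop = FALSE],
    pa$truth)
}

#' Host depletion
#'
#' Keeps read pairs of which neither read mapped to the host genome.
#'
#' @param pa A `pair_alignments` object.
#' @return The host-depleted `pair_alignments`.
#' @export
host_deplete <- function(pa) {
  keep <- pa$pairs$pair_id[!pa$pairs$host_r1 & !pa$pairs$host_r2]
  subset_pairs(pa, keep)
}

#' Pair selection: unique-read quality or proper-pair geometry
#'
#' Two branches: (1) pairs with at least one uniquely mapped read are
#' selected iff a uniquely mapped read has mapping quality strictly above
#' 0; (2) pairs with both reads multi-mapped are selected iff some
#' combination of their hits lies on the same target in convergent
#' forward/reverse orientation with a span inside `[insert_min,
#' insert_max]`.  Pairs with hits on only one multi-mapped read are not
#' selectable.
#'
#' @param pa A `pair_alignments` object; every pair must have at least one
#'   hit.
#' @param insert_min,insert_max Bounds (bp) on the "reasonable genomic
#'   distance" between convergent mates.
#' @return Named logical vector (by pair_id): selected or not.
#' @export
select_pair <- function(pa, insert_min = 50, insert_max = 1000) {
  hits <- pa$hits
  ids <- pa$pairs$pair_id
  if (!all(ids %in% hits$pair_id))
    stop_input("selection error: pair(s) without any hit")

  nh <- stats::aggregate(list(n = hits$pos),
                         by = list(pair_id = hits$pair_id, read = hits$read),
                         FUN = length)
  # branch 1: any uniquely mapped read with Q > 0
  uq <- merge(hits, nh[nh$n == 1L, c("pair_id", "read")],
              by = c("pair_id", "read"))
  has_unique <- unique(uq$pair_id)
  sel1 <- unique(uq$pair_id[uq$mapq > 0])

  # branch 2: both reads multi-mapped, proper combination exists
  multi_only <- setdiff(ids, has_unique)
  sel2 <- character()
  if (length(multi_only)) {
    h <- hits[hits$pair_id %in% multi_only, , drop = FALSE]
    h1 <- h[h$read == 1L, c("pair_id", "target", "pos", "strand")]
    h2 <- h[h$read == 2L, c("pair_id", "target", "pos", "strand")]
    comb <- merge(h1, h2, by = c("pair_id", "target"),
                  suffixes = c("_1", "_2"))
    if (nrow(comb)) {
      span <- abs(comb$pos_2 - comb$pos_1)
      fwd1 <- comb$strand_1 == "+" & comb$strand_2 == "-" &
        comb$pos_2 >= comb$pos_1
      fwd2 <- comb$strand_2 == "+" & comb$strand_1 == "-" &
        comb$pos_1 >= comb$pos_2
      proper <- (fwd1 | fwd2) & span >= insert_min & span <= insert_max
      sel2 <- unique(comb$pair_id[proper])
    }
  }
  stats::setNames(ids %in% c(sel1, sel2), ids)
}

map_rank <- function(targets, taxonomy, rank) {
  rank <- match.arg(rank, RANKS)
  i <- match(targets, taxonomy$strain)
  if (anyNA(i))
    stop_input("taxonomy error: hit target(s) absent from taxonomy: %s",
               paste(unique(targets[is.na(i)]), collapse = ", "))
  taxonomy[[rank]][i]
}

#' Rank-exclusive taxon assignment
#'
#' A read pair is assigned to a taxon at the requested rank — and counted
#' once — iff all of its hits (both reads) fall under a single taxon at
#' that rank, no matter how many times it mapped within the taxon.  A pair
#' hitting two or more distinct taxa at the rank is discarded.  Assignment
#' at each rank is independent.
#'
#' @param pa A `pair_alignments` object (already selected pairs).
#' @param taxonomy data.frame: strain, species, family, phylum (hit targets
#'   are strain names).
#' @param rank One of `"phylum"`, `"family"`, `"species"`, `"strain"`.
#' @return Named character vector (by pair_id): the assigned taxon, or
#'   `"DISCARDED"`.
#' @export
assign_rank <- function(pa, taxonomy, rank) {
  hits <- pa$hits
  taxa <- map_rank(hits$target, taxonomy, rank)
  n_taxa <- tapply(taxa, hits$pair_id, function(x) length(unique(x)))
  one_taxon <- tapply(taxa, hits$pair_id, function(x) x[1L])
  out <- ifelse(n_taxa == 1L, one_taxon, "DISCARDED")
  stats::setNames(as.character(out), names(n_taxa))[pa$pairs$pair_id]
}

#' Taxonomic abundance profile of a host-depleted pair stream
#'
#' Runs pair selection and rank-exclusive assignment, then tallies pairs
#' per taxon with the full accounting identity `assigned + discarded +
#' unselected = total`.
#'
#' @param pa A host-depleted `pair_alignments` object.
#' @param taxonomy Taxonomy data.frame.
#' @param rank Assignment rank.
#' @param insert_min,insert_max Passed to [select_pair()].
#' @return A list of class `abundance_table`: `table` (data.frame: taxon,
#'   pairs, percent of assigned, cpm per million depleted pairs),
#'   `assigned`, `discarded`, `unselected`, `total`.
#' @export
profile_taxa <- function(pa, taxonomy, rank = "phylum",
                         insert_min = 50, insert_max = 1000) {
  total <- nrow(pa$pairs)
  if (total == 0L) {
    return(structure(list(
      table = data.frame(taxon = character(), pairs = integer(),
                         percent = numeric(), cpm = numeric()),
      assigned = 0L, discarded = 0L, unselected = 0L, total = 0L,
      rank = rank), class = "abundance_table"))
  }
  sel <- select_pair(pa, insert_min, insert_max)
  selected <- subset_pairs(pa, names(sel)[sel])
  asg <- assign_rank(selected, taxonomy, rank)
  assigned <- asg[asg != "DISCARDED"]
  counts <- sort(table(assigned), decreasing = TRUE)
  tab <- data.frame(taxon = names(counts),
                    pairs = as.integer(counts),
                    percent = 100 * as.integer(counts) / max(1L, length(assigned)),
                    cpm = 1e6 * as.integer(counts) / total,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 assigned = length(assigned),
                 discarded = sum(asg == "DISCARDED"),
                 unselected = total - length(sel[sel]),
                 total = total,
                 rank = rank),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance at %s rank: %d assigned, %d discarded, %d unselected (of %d)\n",
              x$rank, x$assigned, x$discarded, x$unselected, x$total))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Cross-sample enrichment ratio
#'
#' Compares a taxon's abundance between two samples on the
#' counts-per-million-host-depleted-pairs scale.
#'
#' @param count1,total1 Assigned pair count and host-depleted pair total in
#'   sample 1.
#' @param count2,total2 Same for sample 2.
#' @return `cpm1 / cpm2`.
#' @export
enrichment_ratio <- function(count1, total1, count2, total2) {
  (1e6 * count1 / total1) / (1e6 * count2 / total2)
}

#' Per-gene counts of uniquely placed read pairs
#'
#' Counts a pair for a gene iff all aligned bases of both reads fall within
#' the gene's interval; a pair overlapping two or more genes is ambiguous
#' and left uncounted.  Genes are ranked by descending count, ties broken
#' by gene id.
#'
#' @param pa A `pair_alignments` object of selected, uniquely placed pairs
#'   (one hit per read).
#' @param gene_intervals data.frame: gene, target, start, end (0-based
#'   half-open on the target sequence).
#' @param read_length Aligned length (bp) of each read.
#' @return A list: `counts` (data.frame: gene, pairs, rank), `ambiguous`,
#'   `uncounted`.
#' @export
bacterial_gene_counts <- function(pa, gene_intervals, read_length = 100) {
  if (any(gene_intervals$end <= gene_intervals$start))
    stop_input("annotation error: interval with end <= start")
  hits <- pa$hits
  per_read <- table(paste(hits$pair_id, hits$read))
  if (any(per_read > 1L))
    stop_input("input error: expected uniquely placed pairs (one hit per read)")

  lo <- tapply(hits$pos, hits$pair_id, min)
  hi <- tapply(hits$pos + read_length, hits$pair_id, max)
  tgt <- tapply(hits$target, hits$pair_id, function(x) {
    if (length(unique(x)) == 1L) x[1L] else NA_character_
  })
  ids <- names(lo)

  n_ambiguous <- 0L; n_uncounted <- 0L
  gene_hits <- character()
  for (i in seq_along(ids)) {
    if (is.na(tgt[[i]])) { n_uncounted <- n_uncounted + 1L; next }
    g <- gene_intervals[gene_intervals$target == tgt[[i]], , drop = FALSE]
    # overlap in 0-based half-open coordinates; pair occupies [lo, hi)
    ov <- g$start < hi[[i]] & g$end > lo[[i]]
    if (sum(ov) >= 2L) { n_ambiguous <- n_ambiguous + 1L; next }
    contained <- ov & g$start <= lo[[i]] & g$end >= hi[[i]]
    if (sum(contained) == 1L) {
      gene_hits <- c(gene_hits, g$gene[contained])
    } else {
      n_uncounted <- n_uncounted + 1L
    }
  }
  counts <- table(factor(gene_hits, levels = sort(unique(gene_intervals$gene))))
  out <- data.frame(gene = names(counts), pairs = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pairs, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  list(counts = out, ambiguous = n_ambiguous, uncounted = n_uncounted)
}
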