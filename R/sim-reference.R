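#' Generate a synthetic host reference genome and gene models
#'
#' Chromosome sequences are i.i.d. uniform over A/C/G/T.  Gene models are
#' regularly spaced two-exon transcripts (total CDS length divisible by 3,
#' alternating strand) so consequence classification has coding context to
#' work against.  Exons never overlap within a transcript.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector of chromosome
#'   sequences) and `genes` (data.frame: transcript, gene, chrom, strand,
#'   exon, start, end; 1-based inclusive CDS exon coordinates).
#' @export
gen_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- config$chrom_lengths
  if (length(lens) < 1L || any(lens <= 0))
    stop_input("configuration error: need >= 1 chromosome of positive length")

  with_gen_seed(config$seed, 101L, {
    genome <- vapply(lens, function(n) random_dna(n), character(1))
    names(genome) <- names(lens)

    models <- list()
    for (chrom in names(lens)) {
      n_tx <- max(1L, min(20L, floor(lens[[chrom]] / 5000)))
      for (i in seq_len(n_tx)) {
        anchor <- (i - 1L) * 5000L + 101L
        if (anchor + 800L > lens[[chrom]]) next
        tx <- sprintf("%s_tx%02d", chrom, i)
        strand <- if (i %% 2L == 1L) "+" else "-"
        models[[tx]] <- data.frame(
          transcript = tx,
          gene = sprintf("%s_g%02d", chrom, i),
          chrom = chrom,
          strand = strand,
          exon = 1:2,
          start = c(anchor, anchor + 500L),
          end = c(anchor + 299L, anchor + 799L),
          stringsAsFactors = FALSE
        )
      }
    }
    list(genome = genome, genes = do.call(rbind, c(models, list(make.row.names = FALSE))))
  })
}

#' Default strain-level taxonomy for the microbial database
#'
#' A small forest spanning three gut phyla, with two multi-strain species so
#' that within-species multi-mapping (assignable at species rank, discarded
#' at strain rank) can be simulated.
#'
#' @return data.frame with columns strain, species, family, phylum.
#' @export
default_taxonomy <- function() {
  data.frame(
    strain  = c("BU_A", "BU_B", "BF_A", "EC_A", "CP_A", "CP_B"),
    species = c("Bacteroides uniformis", "Bacteroides uniformis",
                "Bacteroides fragilis", "Escherichia coli",
                "Clostridium perfringens", "Clostridium perfringens"),
    family  = c("Bacteroidaceae", "Bacteroidaceae", "Bacteroidaceae",
                "Enterobacteriaceae", "Clostridiaceae", "Clostridiaceae"),
    phylum  = c("Bacteroidetes", "Bacteroidetes", "Bacteroidetes",
                "Proteobacteria", "Firmicutes", "Firmicutes"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic microbial genome database
#'
#' Each strain receives a random sequence.  A "conserved cassette" — one
#' fixed subsequence copied verbatim into designated strains — forces
#' multi-phylum ambiguity downstream when those strains span more than one
#' phylum, emulating conserved loci shared across distant bacteria.
#'
#' @param config A [sim_config()].
#' @param taxonomy data.frame with columns strain, species, family, phylum
#'   (default [default_taxonomy()]).
#' @param strain_length Length (bp) of each strain sequence.
#' @param cassette_strains Strains receiving the cassette; `NULL` disables
#'   it.  Default: the first strain of the first and last phylum, so the
#'   cassette spans two phyla.
#' @param cassette_length Cassette length (bp).
#' @return A `microbial_db` list: `sequences` (named character vector, one
#'   per strain), `taxonomy`, and `cassette` (strains, start, length).
#' @export
gen_microbial_db <- function(config, taxonomy = default_taxonomy(),
                             strain_length = 10000L,
                             cassette_strains = NULL,
                             cassette_length = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  required <- c("strain", "species", "family", "phylum")
  if (!all(required %in% names(taxonomy)))
    stop_input("taxonomy error: need columns %s", paste(required, collapse = ", "))
  bad <- is.na(taxonomy$phylum) | !nzchar(taxonomy$phylum)
  if (any(bad))
    stop_input("taxonomy error: strain(s) without a phylum: %s",
               paste(taxonomy$strain[bad], collapse = ", "))
  if (anyDuplicated(taxonomy$strain))
    stop_input("taxonomy error: duplicated strain names")

  if (is.null(cassette_strains) && length(unique(taxonomy$phylum)) >= 2L) {
    phyla <- unique(taxonomy$phylum)
    cassette_strains <- c(taxonomy$strain[taxonomy$phylum == phyla[1L]][1L],
                          taxonomy$strain[taxonomy$phylum == phyla[length(phyla)]][1L])
  }
  if (!is.null(cassette_strains) && !all(cassette_strains %in% taxonomy$strain))
    stop_input("taxonomy error: cassette strain(s) absent from taxonomy")

  with_gen_seed(config$seed, 102L, {
    seqs <- vapply(taxonomy$strain, function(s) random_dna(strain_length),
                   character(1))
    cassette <- NULL
    if (!is.null(cassette_strains)) {
      cas_start <- 1001L
      cas <- random_dna(cassette_length)
      for (s in cassette_strains) {
        substr(seqs[[s]], cas_start, cas_start + cassette_length - 1L) <- cas
      }
      cassette <- list(strains = cassette_strains, start = cas_start,
                       length = cassette_length)
    }
    structure(list(sequences = seqs, taxonomy = taxonomy, cassette = cassette),
              class = "microbial_db")
  })
}
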