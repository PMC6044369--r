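#' Simulate paired-end hit records against a microbial database
#'
#' Emits the alignment-record stream a short-read mapper would produce for a
#' shotgun library of known taxonomic composition, without running an
#' aligner: each pair's source strain is drawn multinomially from
#' `config$mixture`, and its two reads receive hits with positions, strands
#' and mapping qualities.  Planted structure:
#'
#' * a `cassette_fraction` of pairs originates from the conserved cassette
#'   and hits *every* cassette-bearing strain (multi-phylum, MAPQ 0);
#' * a `multimap_fraction` multi-maps within one species (two strains where
#'   available), exercising the rank-dependent discard rule;
#' * a `noise_fraction` is emitted with MAPQ 0 (half) or discordant
#'   same-strand hits (half) so the pair-selection rules reject them;
#' * a `host_fraction` carries a host-mapped flag on one or both reads and
#'   is removed by host depletion.
#'
#' Remaining pairs are uniquely mapped, convergent (forward/reverse), with
#' MAPQ 60 and a fragment span of `insert_size`.
#'
#' @param config A [sim_config()]; mixture names may be strains, species,
#'   families or phyla present in `db$taxonomy`.
#' @param db A [gen_microbial_db()] result.
#' @param n_pairs Number of read pairs to simulate.
#' @return A list of class `pair_alignments` with elements `pairs`
#'   (data.frame: pair_id, host_r1, host_r2), `hits` (data.frame: pair_id,
#'   read, target, pos, strand, mapq) and `truth` (mixture fractions,
#'   per-pair source, cassette/multimap/noise pair ids).
#' @export
sim_metagenome_pairs <- function(config, db, n_pairs) {
  stopifnot(inherits(config, "sim_config"), inherits(db, "microbial_db"))
  if (n_pairs <= 0) stop_input("configuration error: n_pairs must be > 0")

  tax <- db$taxonomy
  strains_of <- function(taxon) {
    hit <- tax$strain == taxon | tax$species == taxon |
      tax$family == taxon | tax$phylum == taxon
    tax$strain[hit]
  }
  pool <- lapply(names(config$mixture), strains_of)
  names(pool) <- names(config$mixture)
  empty <- lengths(pool) == 0L
  if (any(empty))
    stop_input("configuration error: mixture taxa absent from database: %s",
               paste(names(pool)[empty], collapse = ", "))

  slen <- nchar(db$sequences)
  ins <- config$insert_size
  has_cassette <- !is.null(db$cassette)

  with_gen_seed(config$seed, 103L, {
    id <- sprintf("p%06d", seq_len(n_pairs))

    is_cassette <- has_cassette &
      stats::runif(n_pairs) < config$cassette_fraction
    taxon <- sample(names(config$mixture), n_pairs, replace = TRUE,
                    prob = config$mixture)
    strain <- vapply(taxon, function(tx) {
      s <- pool[[tx]]
      if (length(s) == 1L) s else sample(s, 1L)
    }, character(1), USE.NAMES = FALSE)

    u <- stats::runif(n_pairs)
    kind <- rep("unique", n_pairs)
    kind[u < config$multimap_fraction] <- "multimap"
    kind[u >= config$multimap_fraction &
           u < config$multimap_fraction + config$noise_fraction / 2] <- "mapq0"
    kind[u >= config$multimap_fraction + config$noise_fraction / 2 &
           u < config$multimap_fraction + config$noise_fraction] <- "discordant"
    kind[is_cassette] <- "cassette"

    hv <- stats::runif(n_pairs)
    host_r1 <- hv < config$host_fraction * 0.6
    host_r2 <- (hv >= config$host_fraction * 0.6 & hv < config$host_fraction) |
      (hv < config$host_fraction * 0.2)   # some pairs host-mapped on both reads

    # vectorized hit construction per pair kind (a per-pair loop does not
    # scale to the 50k-pair simulations used downstream)
    rand_pos <- function(strains) {
      lim <- slen[strains] - ins - config$read_length
      1L + as.integer(floor(stats::runif(length(strains)) * lim))
    }
    sib1 <- vapply(tax$strain, function(s) {
      sibs <- tax$strain[tax$species == tax$species[tax$strain == s]]
      if (length(sibs) >= 2L) sibs[1L] else s
    }, character(1))
    sib2 <- vapply(tax$strain, function(s) {
      sibs <- tax$strain[tax$species == tax$species[tax$strain == s]]
      if (length(sibs) >= 2L) sibs[2L] else s
    }, character(1))

    hits <- list()
    simple <- kind %in% c("unique", "mapq0")
    if (any(simple)) {
      n <- sum(simple)
      p <- rand_pos(strain[simple])
      hits$simple <- data.frame(
        pair_id = rep(id[simple], 2L),
        read = rep(c(1L, 2L), each = n),
        target = rep(strain[simple], 2L),
        pos = c(p, p + ins),
        strand = rep(c("+", "-"), each = n),
        mapq = rep(ifelse(kind[simple] == "mapq0", 0L, 60L), 2L),
        stringsAsFactors = FALSE)
    }
    disc <- kind == "discordant"
    if (any(disc)) {
      n <- sum(disc)
      p <- rand_pos(strain[disc])
      hits$disc <- data.frame(
        pair_id = rep(id[disc], 4L),
        read = rep(c(1L, 1L, 2L, 2L), each = n),
        target = rep(strain[disc], 4L),
        pos = c(p, p + 50L, p + ins, p + ins + 50L),
        strand = "+",                      # no convergent combination exists
        mapq = 0L, stringsAsFactors = FALSE)
    }
    mm <- kind == "multimap"
    if (any(mm)) {
      n <- sum(mm)
      lim <- pmin(slen[sib1[strain[mm]]], slen[sib2[strain[mm]]]) -
        ins - config$read_length
      p <- 1L + as.integer(floor(stats::runif(n) * lim))
      hits$mm <- data.frame(
        pair_id = rep(id[mm], 4L),
        read = rep(c(1L, 1L, 2L, 2L), each = n),
        target = c(sib1[strain[mm]], sib2[strain[mm]],
                   sib1[strain[mm]], sib2[strain[mm]]),
        pos = c(p, p, p + ins, p + ins),
        strand = rep(c("+", "+", "-", "-"), each = n),
        mapq = 0L, stringsAsFactors = FALSE)
    }
    cas <- kind == "cassette"
    if (any(cas)) {
      n <- sum(cas)
      cs <- db$cassette$strains
      k <- length(cs)
      p <- db$cassette$start - 1L +
        1L + as.integer(floor(stats::runif(n) * (db$cassette$length - ins)))
      hits$cas <- data.frame(
        pair_id = rep(id[cas], 2L * k),
        read = rep(c(1L, 2L), each = n * k),
        target = rep(rep(cs, each = n), 2L),
        pos = c(rep(p, k), rep(p + ins, k)),
        strand = rep(c("+", "-"), each = n * k),
        mapq = 0L, stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, unname(hits))
    hits <- hits[order(hits$pair_id, hits$read, hits$target), , drop = FALSE]
    rownames(hits) <- NULL

    structure(list(
      pairs = data.frame(pair_id = id, host_r1 = host_r1, host_r2 = host_r2,
                         stringsAsFactors = FALSE),
      hits = hits,
      truth = list(
        fractions = config$mixture,
        source = data.frame(pair_id = id, taxon = taxon, strain = strain,
                            kind = kind, stringsAsFactors = FALSE),
        cassette_pairs = id[kind == "cassette"],
        multimap_pairs = id[kind == "multimap"],
        noise_pairs = id[kind %in% c("mapq0", "discordant")]
      )
    ), class = "pair_alignments")
  })
}
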