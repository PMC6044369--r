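#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object.  Generators are pure functions of `(seed, config)`: the same
#' configuration always yields byte-identical output.
#'
#' @param seed Integer seed driving every generator.
#' @param chrom_lengths Named numeric vector of host chromosome lengths (bp).
#' @param n_samples Number of expression samples (the study design uses 28
#'   intestinal tumor/normal samples; the first sample is the polyp case).
#' @param mixture Named numeric vector of true taxon fractions for the
#'   metagenome simulator; names may refer to any taxonomic rank present in
#'   the microbial database.  Must sum to 1.
#' @param wgs_depth,rna_depth Mean per-context read depth for the variant
#'   simulator (fragment coverage around 21X for WGS; RNA coverage of
#'   expressed exons around 100X).
#' @param outlier_effect Planted outlier shift in per-gene SD units.
#' @param trisomy_ratio Case/control depth ratio on gained chromosomes
#'   (1.5 = single-copy gain in a pure diploid sample).
#' @param cassette_fraction Fraction of simulated read pairs drawn from the
#'   conserved multi-phylum cassette (deliberately ambiguous at phylum rank).
#' @param noise_fraction Fraction of pairs emitted with MAPQ 0 or discordant
#'   orientation so the pair-selection rules have planted negatives.
#' @param multimap_fraction Fraction of pairs multi-mapped within one species
#'   (assignable at species rank, discarded at strain rank).
#' @param host_fraction Fraction of pairs flagged as host-mapped (removed by
#'   host depletion).
#' @param insert_size,read_length Fragment geometry (bp) used when emitting
#'   paired hits.
#' @param n_genes,n_high,n_low Expression matrix size and number of planted
#'   high/low outlier genes.
#' @param n_decoys_per_family Decoy variants planted per cascade step.
#' @param window_lambda Mean mapped-pair count per 1-kb window for the CNV
#'   simulator.
#' @param cnv_chroms,cnv_windows Number of chromosomes and 1-kb windows per
#'   chromosome in the CNV simulation.
#' @param gained_chroms Chromosome names planted with the `trisomy_ratio`
#'   gain.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 100000, chr2 = 80000),
                       n_samples = 28L,
                       mixture = c(Bacteroidetes = 0.7,
                                   Proteobacteria = 0.2,
                                   Firmicutes = 0.1),
                       wgs_depth = 21,
                       rna_depth = 100,
                       outlier_effect = 5,
                       trisomy_ratio = 1.5,
                       cassette_fraction = 0.05,
                       noise_fraction = 0.02,
                       multimap_fraction = 0.05,
                       host_fraction = 0.1,
                       insert_size = 300,
                       read_length = 100,
                       n_genes = 2000L,
                       n_high = 50L,
                       n_low = 50L,
                       n_decoys_per_family = 55L,
                       window_lambda = 100,
                       cnv_chroms = 10L,
                       cnv_windows = 1000L,
                       gained_chroms = c("chr3", "chr6", "chr9")) {
  if (length(chrom_lengths) < 1L)
    stop_input("configuration error: at least one chromosome is required")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop_input("configuration error: chrom_lengths must be named")
  if (any(chrom_lengths <= 0))
    stop_input("configuration error: all chromosome lengths must be > 0")
  if (abs(sum(mixture) - 1) > 1e-9)
    stop_input("configuration error: mixture fractions must sum to 1 (got %g)",
               sum(mixture))
  if (any(mixture < 0))
    stop_input("configuration error: mixture fractions must be non-negative")
  if (n_samples < 3)
    stop_input("configuration error: n_samples must be >= 3")
  if (window_lambda <= 0)
    stop_input("configuration error: window_lambda must be > 0")
  if (trisomy_ratio <= 0)
    stop_input("configuration error: trisomy_ratio must be > 0")
  if (!all(gained_chroms %in% paste0("chr", seq_len(cnv_chroms))))
    stop_input("configuration error: gained_chroms outside chr1..chr%d",
               cnv_chroms)
  if (outlier_effect <= 1)
    warning("outlier effect size <= 1 SD: planted truth is not guaranteed ",
            "to be recoverable", call. = FALSE)

  structure(list(
    seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    n_samples = as.integer(n_samples),
    mixture = mixture,
    wgs_depth = wgs_depth,
    rna_depth = rna_depth,
    outlier_effect = outlier_effect,
    trisomy_ratio = trisomy_ratio,
    cassette_fraction = cassette_fraction,
    noise_fraction = noise_fraction,
    multimap_fraction = multimap_fraction,
    host_fraction = host_fraction,
    insert_size = insert_size,
    read_length = read_length,
    n_genes = as.integer(n_genes),
    n_high = as.integer(n_high),
    n_low = as.integer(n_low),
    n_decoys_per_family = as.integer(n_decoys_per_family),
    window_lambda = window_lambda,
    cnv_chroms = as.integer(cnv_chroms),
    cnv_windows = as.integer(cnv_windows),
    gained_chroms = gained_chroms
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed ", x$seed, ")\n", sep = "")
  cat("  chromosomes:", paste0(names(x$chrom_lengths), "=",
                               x$chrom_lengths, collapse = ", "), "\n")
  cat("  samples:", x$n_samples,
      " genes:", x$n_genes,
      " outlier effect:", x$outlier_effect, "SD\n")
  cat("  mixture:", paste0(names(x$mixture), "=", x$mixture,
                           collapse = ", "), "\n")
  cat("  CNV:", x$cnv_chroms, "chromosomes x", x$cnv_windows,
      "windows, gain ratio", x$trisomy_ratio, "on",
      paste(x$gained_chroms, collapse = ","), "\n")
  invisible(x)
}
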