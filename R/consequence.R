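# Coding-consequence classification.
#
# A transcript model is a data.frame of CDS exons (columns: chrom, strand,
# start, end; 1-based inclusive, given in genomic order).  The CDS sequence
# is the concatenation of exon sequences, reverse-complemented on the minus
# strand; its length must be a multiple of 3.  Variant coordinates follow
# VCF convention (1-based; indels carry a shared anchor base).

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop_input("model error: untranslatable codon %s", codon)
  aa
}

# genomic position -> 1-based CDS offset, or NA when not in a CDS exon
cds_offset <- function(transcript, pos) {
  ex <- transcript[order(transcript$start), , drop = FALSE]
  cum <- cumsum(c(0L, ex$end - ex$start + 1L))
  for (i in seq_len(nrow(ex))) {
    if (pos >= ex$start[i] && pos <= ex$end[i]) {
      off_plus <- cum[i] + (pos - ex$start[i] + 1L)
      total <- cum[length(cum)]
      return(if (all(transcript$strand == "+")) off_plus
             else total - off_plus + 1L)
    }
  }
  NA_integer_
}

cds_sequence <- function(transcript, genome) {
  chrom <- transcript$chrom[1L]
  if (!chrom %in% names(genome))
    stop_input("model error: chromosome %s absent from genome", chrom)
  ex <- transcript[order(transcript$start), , drop = FALSE]
  pieces <- substring(genome[[chrom]], ex$start, ex$end)
  s <- paste(pieces, collapse = "")
  if (all(transcript$strand == "-")) s <- revcomp(s)
  s
}

#' Classify the coding consequence of a variant
#'
#' SNVs inside the CDS are translated by codon substitution; coding indels
#' are frameshift when the length change is not a multiple of 3, in-frame
#' otherwise.  Variants outside the CDS exons are noncoding.  Protein
#' notation follows the `<refAA><codon><altAA>` convention with `X` for a
#' stop gain and `fs` for a frameshift (e.g. `W411X`, `D404fs`).
#'
#' @param variant A list/row with `chrom`, `pos`, `ref`, `alt`.
#' @param transcript CDS exon data.frame (chrom, strand, start, end).
#' @param genome Named character vector of chromosome sequences.
#' @return A list with `consequence` (one of synonymous, missense, nonsense,
#'   frameshift, inframe_indel, noncoding) and `notation` (protein-level
#'   string, `NA` for noncoding).
#' @export
classify_consequence <- function(variant, transcript, genome) {
  stopifnot(all(c("chrom", "strand", "start", "end") %in% names(transcript)))
  if (length(unique(transcript$strand)) != 1L)
    stop_input("model error: mixed exon strands in one transcript")
  cds <- cds_sequence(transcript, genome)
  if (nchar(cds) %% 3L != 0L)
    stop_input("model error: CDS length %d is not a multiple of 3", nchar(cds))
  if (variant$chrom != transcript$chrom[1L])
    return(list(consequence = "noncoding", notation = NA_character_))

  minus <- all(transcript$strand == "-")
  off <- cds_offset(transcript, variant$pos)
  ref_len <- nchar(variant$ref)
  alt_len <- nchar(variant$alt)

  if (ref_len == 1L && alt_len == 1L) {
    if (is.na(off))
      return(list(consequence = "noncoding", notation = NA_character_))
    codon_idx <- (off - 1L) %/% 3L + 1L
    within <- (off - 1L) %% 3L + 1L
    codon <- substring(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    ref_cds <- if (minus) revcomp_base(variant$ref) else variant$ref
    alt_cds <- if (minus) revcomp_base(variant$alt) else variant$alt
    if (substring(codon, within, within) != ref_cds)
      stop_input("model error: reference allele %s does not match CDS (%s)",
                 variant$ref, substring(codon, within, within))
    alt_codon <- codon
    substring(alt_codon, within, within) <- alt_cds
    ref_aa <- translate_codon(codon)
    alt_aa <- translate_codon(alt_codon)
    cons <- if (ref_aa == alt_aa) "synonymous"
            else if (alt_aa == "*") "nonsense"
            else "missense"
    show_alt <- if (alt_aa == "*") "X" else alt_aa
    return(list(consequence = cons,
                notation = paste0(ref_aa, codon_idx, show_alt)))
  }

  # indel: changed bases start after the shared anchor base
  first_changed <- variant$pos + 1L
  off_ch <- cds_offset(transcript, first_changed)
  if (is.na(off_ch)) off_ch <- cds_offset(transcript, variant$pos)
  if (is.na(off_ch))
    return(list(consequence = "noncoding", notation = NA_character_))
  codon_idx <- (off_ch - 1L) %/% 3L + 1L
  codon <- substring(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  ref_aa <- translate_codon(codon)
  if (abs(ref_len - alt_len) %% 3L != 0L) {
    list(consequence = "frameshift",
         notation = paste0(ref_aa, codon_idx, "fs"))
  } else {
    list(consequence = "inframe_indel",
         notation = paste0(ref_aa, codon_idx, "delins"))
  }
}

#' Flag indels in or adjoining a homopolymer run
#'
#' Single-base runs are error-prone for indel calling; an indel is flagged
#' when a run of length `>= min_run` overlaps or is immediately adjacent to
#' the affected reference interval.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,pos,ref Variant location and reference allele (VCF
#'   convention; for a deletion the affected bases are `pos+1 ..
#'   pos+nchar(ref)-1`).
#' @param min_run Minimum run length (default 6, e.g. GGGGGG).
#' @return Logical.
#' @export
homopolymer_flag <- function(genome, chrom, pos, ref, min_run = 6L) {
  if (!chrom %in% names(genome))
    stop_input("coordinate error: unknown chromosome %s", chrom)
  len <- nchar(genome[[chrom]])
  var_end <- pos + nchar(ref) - 1L
  if (pos < 1L || var_end > len)
    stop_input("coordinate error: position %d outside %s (1..%d)", pos, chrom, len)
  win_start <- max(1L, pos - min_run - 1L)
  win_end <- min(len, var_end + min_run + 1L)
  win <- strsplit(substring(genome[[chrom]], win_start, win_end), "",
                  fixed = TRUE)[[1]]
  runs <- rle(win)
  run_end <- cumsum(runs$lengths) + win_start - 1L
  run_start <- run_end - runs$lengths + 1L
  # overlap or adjacency with the variant interval, expanded by one base
  any(runs$lengths >= min_run &
        run_start <= var_end + 1L & run_end >= pos - 1L)
}
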