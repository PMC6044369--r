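# Collapsed base-substitution spectrum.
#
# A substitution and its reverse complement describe the same double-strand
# event, so the 12 ordered single-base changes collapse onto 6 classes,
# labelled by the pyrimidine-containing base pair first (e.g. a G>A call is
# the C:G>T:A class).

SPECTRUM_CLASSES <- c("C:G>T:A", "C:G>A:T", "C:G>G:C",
                      "T:A>A:T", "T:A>C:G", "T:A>G:C")

#' Collapse a single-base substitution onto one of six classes
#'
#' @param ref_base,alt_base Single bases in A/C/G/T; `ref_base != alt_base`.
#'   Vectorized.
#' @return Class label(s) among `C:G>T:A`, `C:G>A:T`, `C:G>G:C`, `T:A>A:T`,
#'   `T:A>C:G`, `T:A>G:C`.
#' @export
collapse_substitution <- function(ref_base, alt_base) {
  if (length(ref_base) != length(alt_base))
    stop_input("classification error: ref and alt lengths differ")
  ok <- ref_base %in% DNA_BASES & alt_base %in% DNA_BASES
  if (any(!ok))
    stop_input("classification error: alleles must be single bases in ACGT")
  if (any(ref_base == alt_base))
    stop_input("classification error: ref and alt are identical")
  # orient so the reference base is a pyrimidine (C or T)
  flip <- ref_base %in% c("A", "G")
  r <- ifelse(flip, revcomp_base(ref_base), ref_base)
  a <- ifelse(flip, revcomp_base(alt_base), alt_base)
  paste0(r, ":", revcomp_base(r), ">", a, ":", revcomp_base(a))
}

#' Substitution spectrum of a variant table
#'
#' Classifies every single-nucleotide substitution into the six collapsed
#' classes; indels (multi-base ref or alt) are skipped and tallied.
#'
#' @param variants Data.frame with `ref` and `alt` columns.
#' @return A list of class `spectrum`: `counts` (named integer vector over
#'   the six classes), `skipped` (indel count) and `dominant` (argmax class,
#'   or `NA` on a tie or empty input).
#' @export
spectrum <- function(variants) {
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% DNA_BASES & variants$alt %in% DNA_BASES
  counts <- stats::setNames(integer(length(SPECTRUM_CLASSES)), SPECTRUM_CLASSES)
  if (any(is_snv)) {
    cl <- collapse_substitution(variants$ref[is_snv], variants$alt[is_snv])
    tab <- table(factor(cl, levels = SPECTRUM_CLASSES))
    counts[] <- as.integer(tab)
  }
  dominant <- NA_character_
  if (sum(counts) > 0) {
    top <- which(counts == max(counts))
    if (length(top) == 1L) dominant <- names(counts)[top]
  }
  structure(list(counts = counts, skipped = sum(!is_snv), dominant = dominant),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("Substitution spectrum (", sum(x$counts), " substitutions, ",
      x$skipped, " indels skipped)\n", sep = "")
  print(x$counts)
  cat("dominant class:", ifelse(is.na(x$dominant), "none", x$dominant), "\n")
  invisible(x)
}
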