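#' polypomics: multi-omic analysis of a canine extreme-polyposis case
#'
#' Variant prioritization, consequence and spectrum classification,
#' outlier-expression and ssGSEA analysis, host-depleted metagenomic
#' profiling and tiling-window copy-number calling, with synthetic-data
#' generators carrying planted ground truth for every stage.
#'
#' @importFrom jsonlite write_json
#' @keywords internal
"_PACKAGE"

# Variant identity used throughout: exact (chrom, pos, ref, alt).
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)

# All randomness in the generators flows through this: each generator uses the
# config seed plus a fixed per-generator offset, so generators are pure
# functions of (seed, config) and independent of call order.
with_gen_seed <- function(seed, offset, code) {
  withr::with_seed(as.integer(seed) + as.integer(offset), code)
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
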