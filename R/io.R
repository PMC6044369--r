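# Readers and writers for the pipeline's on-disk formats, plus the
# end-to-end orchestrator.  Variant tables travel as VCF 4.2 (four samples
# WGS_N, WGS_P, RNA_N, RNA_P with DP and AD FORMAT fields) or as a flat TSV
# with explicit dp_*/ad_* columns; alignment records as a TSV dialect of
# SAM hit lines; matrices, taxonomies and intervals as TSV; gene sets as
# GMT; reports as JSON.

VARIANT_TSV_COLS <- c("chrom", "pos", "ref", "alt", "gene", "flags",
                      "structure_destabilizing", OBS_COLS)

#' Write a candidate-variant table as TSV
#' @param variants Candidate-variant data.frame.
#' @param path Output path.
#' @export
write_variants_tsv <- function(variants, path) {
  cols <- intersect(VARIANT_TSV_COLS, names(variants))
  utils::write.table(variants[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate-variant table
#'
#' @param path Input path.
#' @param dialect `"tsv"` (flat table, see [write_variants_tsv()]) or
#'   `"vcf"` (VCF 4.2 with samples WGS_N, WGS_P, RNA_N, RNA_P carrying
#'   DP and AD).
#' @return Candidate-variant data.frame.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    v <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          flags = "character"),
                           na.strings = "NA")
    v$flags[is.na(v$flags)] <- ""
    missing <- setdiff(c("chrom", "pos", "ref", "alt", OBS_COLS), names(v))
    if (length(missing))
      stop_input("format error: TSV lacks column(s): %s",
                 paste(missing, collapse = ", "))
    return(v)
  }
  read_variants_vcf(path)
}

VCF_SAMPLES <- c("WGS_N", "WGS_P", "RNA_N", "RNA_P")
VCF_CONTEXTS <- c("wgs_n", "wgs_p", "rna_n", "rna_p")

#' Write a candidate-variant table as VCF 4.2
#'
#' Four genotype columns (WGS_N, WGS_P, RNA_N, RNA_P) carry per-context
#' depth (DP) and ref,alt allele depths (AD); gene, flags and the structure
#' annotation travel in INFO.
#'
#' @param variants Candidate-variant data.frame.
#' @param path Output path.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=FLAGS,Number=.,Type=String,Description=\"Annotation flags\">",
    "##INFO=<ID=DESTAB,Number=1,Type=String,Description=\"Structure destabilizing prediction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", VCF_SAMPLES), collapse = "\t"))
  fmt_ctx <- function(dp, ad) {
    ifelse(is.na(dp), ".:.",
           paste0(dp, ":", ifelse(is.na(ad), ".", paste0(dp - ad, ",", ad))))
  }
  info <- paste0("GENE=", variants$gene %||% rep(".", nrow(variants)),
                 ";FLAGS=", ifelse(nzchar(variants$flags %||% ""),
                                   variants$flags, "."),
                 ";DESTAB=", ifelse(is.na(variants$structure_destabilizing %||%
                                            rep(NA, nrow(variants))),
                                    ".", variants$structure_destabilizing))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, "DP:AD",
                fmt_ctx(variants$dp_wgs_n, variants$ad_wgs_n),
                fmt_ctx(variants$dp_wgs_p, variants$ad_wgs_p),
                fmt_ctx(variants$dp_rna_n, variants$ad_rna_n),
                fmt_ctx(variants$dp_rna_p, variants$ad_rna_p),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a candidate-variant table from VCF 4.2
#'
#' @param path Input path.
#' @return Candidate-variant data.frame.
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcf@gt
  if (!all(VCF_SAMPLES %in% colnames(gt)))
    stop_input("format error: VCF lacks sample column(s): %s",
               paste(setdiff(VCF_SAMPLES, colnames(gt)), collapse = ", "))
  fmt <- unique(gt[, "FORMAT"])
  if (!all(grepl("AD", fmt)))
    stop_input("format error: VCF FORMAT lacks the AD field")
  if (!all(grepl("DP", fmt)))
    stop_input("format error: VCF FORMAT lacks the DP field")
  fx <- vcf@fix
  info <- fx[, "INFO"]
  grab <- function(k) {
    m <- regmatches(info, regexpr(paste0(k, "=[^;]*"), info))
    val <- sub(paste0(k, "="), "", m)
    out <- rep(NA_character_, length(info))
    out[grepl(paste0(k, "="), info)] <- val
    out
  }
  v <- data.frame(chrom = fx[, "CHROM"],
                  pos = as.integer(fx[, "POS"]),
                  ref = fx[, "REF"], alt = fx[, "ALT"],
                  gene = grab("GENE"),
                  flags = grab("FLAGS"),
                  stringsAsFactors = FALSE)
  v$flags[is.na(v$flags) | v$flags == "."] <- ""
  destab <- grab("DESTAB")
  v$structure_destabilizing <- ifelse(is.na(destab) | destab == ".",
                                      NA, destab == "TRUE")
  dp <- vcfR::extract.gt(vcf, element = "DP")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  for (i in seq_along(VCF_SAMPLES)) {
    s <- VCF_SAMPLES[i]; ctx <- VCF_CONTEXTS[i]
    v[[paste0("dp_", ctx)]] <- suppressWarnings(as.integer(dp[, s]))
    alt_reads <- suppressWarnings(
      as.integer(sub("^[0-9.]+,", "", ad[, s])))
    v[[paste0("ad_", ctx)]] <- alt_reads
  }
  rownames(v) <- NULL
  v
}

#' Write / read pair-alignment records (TSV dialect)
#'
#' Two files: `<path>` holds one row per hit (pair_id, read, target, pos,
#' strand, mapq) and `<path>.pairs` one row per pair (pair_id, host_r1,
#' host_r2).
#'
#' @param pa A `pair_alignments` object.
#' @param path Output path for the hits table.
#' @export
write_alignments_tsv <- function(pa, path) {
  utils::write.table(pa$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pa$pairs, paste0(path, ".pairs"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @return For the reader: a `pair_alignments` object; orphan hits (rows
#'   whose pair_id lacks a pair record) are skipped with a warning and
#'   counted in attribute `skipped`.
#' @export
read_alignments_tsv <- function(path) {
  hits <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(pair_id = "character",
                                           target = "character",
                                           strand = "character"))
  pairs <- utils::read.table(paste0(path, ".pairs"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(pair_id = "character"))
  orphan <- !(hits$pair_id %in% pairs$pair_id)
  if (any(orphan)) {
    warning(sum(orphan), " orphan hit record(s) skipped", call. = FALSE)
    hits <- hits[!orphan, , drop = FALSE]
  }
  pa <- as_pair_alignments(pairs, hits)
  attr(pa, "skipped") <- sum(orphan)
  pa
}

#' Read gene sets from a GMT file
#' @param path GMT path (set name, description, member genes per line).
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE),
                 function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a genes-x-samples matrix as TSV
#' @param mat Numeric matrix with dimnames.
#' @param path Path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> cascade -> spectrum -> expression -> microbiome ->
#' cnv on a [sim_config()], writing one JSON report per stage (plus TSV
#' side tables) into `out_dir`.  Reports are a pure function of the
#' configuration: rerunning with the same seed reproduces them
#' byte-identically.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_pairs Simulated metagenome size (read pairs).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of the six stage reports.
#' @export
run_pipeline <- function(config, out_dir, n_pairs = 20000L, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  wj <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  say("stage simulate: seed %d", config$seed)
  sim <- sim_variant_table(config)
  expr <- sim_expression(config)
  db <- gen_microbial_db(config)
  pairs <- sim_metagenome_pairs(config, db, n_pairs = n_pairs)
  cnv <- sim_cnv(config)
  wj(list(seed = config$seed,
          n_variants = nrow(sim$variants),
          n_genes = nrow(expr$log2_fpkm),
          n_pairs = nrow(pairs$pairs),
          cnv_windows = nrow(cnv$case)), "simulate")

  say("stage cascade: %d candidates", nrow(sim$variants))
  report <- run_cascade(sim$variants, sim$panel_keys, sim$snp_keys,
                        sim$profiles, cascade_config())
  rec <- cascade_recovery(report, sim$truth)
  wj(list(steps = report$steps, top_keys = report$top_keys,
          precision = rec$precision, recall = rec$recall), "cascade")
  utils::write.table(report$steps, file.path(out_dir, "cascade_steps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage spectrum")
  sp <- spectrum(sim$variants)
  wj(list(counts = as.list(sp$counts), skipped = sp$skipped,
          dominant = sp$dominant), "spectrum")

  say("stage expression: %d genes x %d samples",
      nrow(expr$log2_fpkm), ncol(expr$log2_fpkm))
  calls <- detect_sample_outliers(expr$log2_fpkm, expr$case_sample)
  wj(list(n_high = sum(calls$direction == "high"),
          n_low = sum(calls$direction == "low"),
          n_planted = nrow(expr$truth)), "expression")
  utils::write.table(calls, file.path(out_dir, "outlier_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage microbiome: %d pairs", nrow(pairs$pairs))
  depleted <- host_deplete(pairs)
  prof <- profile_taxa(depleted, db$taxonomy, rank = "phylum")
  wj(list(rank = prof$rank, table = prof$table, assigned = prof$assigned,
          discarded = prof$discarded, unselected = prof$unselected,
          total = prof$total), "microbiome")

  say("stage cnv: %d chromosomes", config$cnv_chroms)
  norm <- normalize_to_control(cnv$case, cnv$control)
  cnv_calls <- call_whole_chromosome(norm)
  wj(cnv_calls, "cnv")
  utils::write.table(cnv_calls, file.path(out_dir, "cnv_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(simulate = sim, cascade = report, spectrum = sp,
                 expression = calls, microbiome = prof, cnv = cnv_calls))
}
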