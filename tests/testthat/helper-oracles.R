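# Independent brute-force oracles used to cross-check the implementation.
# Each oracle applies the analysis rules literally, one record at a time,
# sharing no code with the package internals it checks.

# -- cascade: single-pass predicate conjunction over one variant row -------

oracle_present <- function(row, ctx, min_alt = 2, min_vaf = 0.05) {
  dp <- row[[paste0("dp_", ctx)]]
  ad <- row[[paste0("ad_", ctx)]]
  !is.na(dp) && !is.na(ad) && dp > 0 && ad >= min_alt && ad / dp >= min_vaf
}

oracle_key <- function(row) paste(row$chrom, row$pos, row$ref, row$alt, sep = ":")

# returns the name of the first step that removes the variant, or "pass"
oracle_fate <- function(row, panel, snps, profiles,
                        wgs_min = 10, rna_min = 30, polyp_vaf = 0.5) {
  for (ctx in c("wgs_n", "wgs_p", "rna_n", "rna_p")) {
    if (!oracle_present(row, ctx)) return("concordance")
  }
  if (oracle_key(row) %in% c(panel, snps)) return("uniqueness")
  fl <- strsplit(row$flags, ",")[[1]]
  if (any(fl %in% c("retrogene", "pseudogene"))) return("annotation")
  if (is.na(row$dp_wgs_n) || row$dp_wgs_n < wgs_min) return("support")
  if (is.na(row$dp_wgs_p) || row$dp_wgs_p < wgs_min) return("support")
  rna_ok <- (!is.na(row$dp_rna_n) && row$dp_rna_n >= rna_min) ||
    (!is.na(row$dp_rna_p) && row$dp_rna_p >= rna_min)
  if (!rna_ok) return("support")
  vw <- if (!is.na(row$dp_wgs_p) && row$dp_wgs_p > 0)
    row$ad_wgs_p / row$dp_wgs_p else -1
  vr <- if (!is.na(row$dp_rna_p) && row$dp_rna_p > 0)
    row$ad_rna_p / row$dp_rna_p else -1
  if (vw < polyp_vaf && vr < polyp_vaf) return("support")
  prof <- profiles[[oracle_key(row)]]
  if (!is.null(prof) && length(prof) > 0 && row$alt %in% prof)
    return("conservation")
  "pass"
}

oracle_selected <- function(row) {
  vn_wgs <- row$ad_wgs_n / row$dp_wgs_n
  if (is.na(vn_wgs) || vn_wgs < 0.2 || vn_wgs > 0.8) return(FALSE)  # not het
  up <- c()
  for (assay in c("wgs", "rna")) {
    dn <- row[[paste0("dp_", assay, "_n")]]; dp <- row[[paste0("dp_", assay, "_p")]]
    if (!is.na(dn) && !is.na(dp) && dn > 0 && dp > 0) {
      up <- c(up, row[[paste0("ad_", assay, "_p")]] / dp >
                row[[paste0("ad_", assay, "_n")]] / dn)
    }
  }
  length(up) > 0 && all(up)
}

oracle_cascade <- function(variants, panel, snps, profiles) {
  fate <- vapply(seq_len(nrow(variants)),
                 function(i) oracle_fate(variants[i, ], panel, snps, profiles),
                 character(1))
  survivors <- variants[fate == "pass", , drop = FALSE]
  top <- vapply(seq_len(nrow(survivors)), function(i) {
    row <- survivors[i, ]
    oracle_selected(row) && isTRUE(row$structure_destabilizing)
  }, logical(1))
  list(fate = fate,
       surviving_keys = vapply(seq_len(nrow(survivors)),
                               function(i) oracle_key(survivors[i, ]),
                               character(1)),
       top_keys = vapply(which(top),
                         function(i) oracle_key(survivors[i, ]), character(1)))
}

# -- ssGSEA: direct running-sum loop --------------------------------------

oracle_ssgsea <- function(profile, gene_set, alpha) {
  ord <- order(profile, decreasing = TRUE)
  genes <- names(profile)[ord]
  n <- length(genes)
  in_set <- genes %in% gene_set
  w_total <- 0
  for (i in seq_len(n)) if (in_set[i]) w_total <- w_total + (n - i + 1)^alpha
  es <- 0; cum_in <- 0; cum_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cum_in <- cum_in + (n - i + 1)^alpha / w_total
    else cum_out <- cum_out + 1 / (n - sum(in_set))
    es <- es + (cum_in - cum_out)
  }
  es
}

# -- homopolymer: character scan of the +/- min_run neighborhood ----------

oracle_homopolymer <- function(seq_str, pos, ref, min_run = 6) {
  chars <- strsplit(seq_str, "")[[1]]
  var_lo <- pos; var_hi <- pos + nchar(ref) - 1
  for (center in max(1, var_lo - min_run - 1):min(length(chars), var_hi + min_run + 1)) {
    b <- chars[center]
    lo <- center; hi <- center
    while (lo > 1 && chars[lo - 1] == b) lo <- lo - 1
    while (hi < length(chars) && chars[hi + 1] == b) hi <- hi + 1
    if (hi - lo + 1 >= min_run && lo <= var_hi + 1 && hi >= var_lo - 1)
      return(TRUE)
  }
  FALSE
}

# -- hypergeometric enrichment: full enumeration with choose() ------------

oracle_hypergeom_two_sided <- function(a, b, c_, d) {
  m <- a + b; n_tot <- a + b + c_ + d; k <- a + c_
  prob <- function(x) {
    choose(m, x) * choose(n_tot - m, k - x) / choose(n_tot, k)
  }
  support <- max(0, k - (n_tot - m)):min(m, k)
  p_obs <- prob(a)
  sum(vapply(support, prob, numeric(1))[vapply(support, prob, numeric(1)) <=
                                          p_obs * (1 + 1e-7)])
}

# -- microbiome profile: literal per-pair rule application ----------------

oracle_profile <- function(pa, taxonomy, rank, insert_min = 50,
                           insert_max = 1000) {
  counts <- list(); discarded <- 0; unselected <- 0
  for (pid in pa$pairs$pair_id) {
    h <- pa$hits[pa$hits$pair_id == pid, , drop = FALSE]
    h1 <- h[h$read == 1, , drop = FALSE]
    h2 <- h[h$read == 2, , drop = FALSE]
    uniq1 <- nrow(h1) == 1; uniq2 <- nrow(h2) == 1
    sel <- FALSE
    if ((nrow(h1) > 0 && uniq1) || (nrow(h2) > 0 && uniq2)) {
      if (uniq1 && nrow(h1) == 1 && h1$mapq > 0) sel <- TRUE
      if (uniq2 && nrow(h2) == 1 && h2$mapq > 0) sel <- TRUE
    } else if (nrow(h1) >= 2 && nrow(h2) >= 2) {
      for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2))) {
        if (h1$target[i] != h2$target[j]) next
        span <- abs(h2$pos[j] - h1$pos[i])
        conv <- (h1$strand[i] == "+" && h2$strand[j] == "-" &&
                   h2$pos[j] >= h1$pos[i]) ||
          (h2$strand[j] == "+" && h1$strand[i] == "-" &&
             h1$pos[i] >= h2$pos[j])
        if (conv && span >= insert_min && span <= insert_max) sel <- TRUE
      }
    }
    if (!sel) { unselected <- unselected + 1; next }
    taxa <- unique(taxonomy[[rank]][match(h$target, taxonomy$strain)])
    if (length(taxa) == 1) {
      counts[[taxa]] <- (counts[[taxa]] %||% 0) + 1
    } else {
      discarded <- discarded + 1
    }
  }
  list(counts = unlist(counts) %||% stats::setNames(numeric(0), character(0)),
       discarded = discarded, unselected = unselected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
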