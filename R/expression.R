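# Expression analysis: FPKM, the per-sample outlier statistic, single-sample
# gene set enrichment (ssGSEA) and score-based sample clustering.

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `FPKM(g, s) = count(g, s) / (length_kb(g) * total_millions(s))`.
#'
#' @param counts Genes x samples matrix of fragment counts.
#' @param lengths Per-gene exonic lengths in bp (recycled by gene).
#' @param totals Per-sample library-wide mapped-fragment totals (may exceed
#'   the column sums).
#' @return Matrix of FPKM values with the same dimnames.
#' @export
compute_fpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop_input("input error: need one exonic length per gene")
  if (length(totals) != ncol(counts))
    stop_input("input error: need one fragment total per sample")
  if (any(lengths <= 0)) stop_input("input error: gene lengths must be > 0")
  if (any(totals <= 0)) stop_input("input error: library totals must be > 0")
  if (any(counts < 0)) stop_input("input error: negative counts")
  sweep(sweep(counts, 1, lengths / 1000, "/"), 2, totals / 1e6, "/")
}

#' Log-transform an FPKM matrix
#'
#' `log2(FPKM + pseudocount)`; the default pseudocount 1 maps zero FPKM to 0.
#'
#' @param fpkm FPKM matrix.
#' @param pseudocount Added before the log.
#' @return Matrix of log2 values.
#' @export
log_fpkm <- function(fpkm, pseudocount = 1) log2(fpkm + pseudocount)

#' Outlier-expression calls for one sample
#'
#' A gene is called *high* in the target sample when its value there lies
#' above the across-sample mean + 1 SD **and** is the strict maximum over
#' all samples; *low* symmetrically.  Mean and SD include the target sample.
#' Constant rows (SD 0) yield no call.
#'
#' @param mat Genes x samples matrix, normally in log2(FPKM + 1) space.
#' @param target Target sample (column name or index).
#' @param n_sd Width of the exclusion band in SD units (default 1).
#' @return data.frame: gene, sample, direction (high/low), z (distance from
#'   the mean in SD units).
#' @export
detect_sample_outliers <- function(mat, target, n_sd = 1) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L) stop_input("input error: need >= 3 samples")
  if (is.character(target)) {
    target <- match(target, colnames(mat))
    if (is.na(target)) stop_input("input error: unknown target sample")
  }
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  x <- mat[, target]
  other_max <- apply(mat[, -target, drop = FALSE], 1, max)
  other_min <- apply(mat[, -target, drop = FALSE], 1, min)
  ok <- s > 0
  hi <- ok & x > m + n_sd * s & x > other_max
  lo <- ok & x < m - n_sd * s & x < other_min
  out <- data.frame(
    gene = c(rownames(mat)[hi], rownames(mat)[lo]),
    sample = rep(colnames(mat)[target], sum(hi) + sum(lo)),
    direction = rep(c("high", "low"), c(sum(hi), sum(lo))),
    z = c((x[hi] - m[hi]) / s[hi], (x[lo] - m[lo]) / s[lo]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Single-sample gene set enrichment score
#'
#' Rank-weighted running-sum statistic: genes are ordered by decreasing
#' expression; the in-set cumulative distribution is weighted by
#' `rank^alpha` (rank N for the top gene) and compared against the uniform
#' out-of-set cumulative; the score is the sum of the per-position
#' differences (the running-sum integral).  Positive scores mean the set
#' concentrates at the top of the profile.  Being rank-based, the score is
#' invariant under strictly monotone transforms of the expression values.
#'
#' @param profile Named numeric vector of expression values (one sample).
#' @param gene_set Character vector of member gene ids.
#' @param alpha Rank-weighting exponent (0 = unweighted).
#' @return Numeric enrichment score.
#' @export
ssgsea_score <- function(profile, gene_set, alpha = 0.75) {
  if (is.null(names(profile)))
    stop_input("scoring error: profile must be a named vector")
  gene_set <- unique(gene_set)
  if (!any(gene_set %in% names(profile)))
    stop_input("scoring error: gene set has no overlap with the profile")
  n <- length(profile)
  ord <- order(profile, decreasing = TRUE)
  in_set <- names(profile)[ord] %in% gene_set
  rank_stat <- as.numeric(n - seq_len(n) + 1L)  # N at the top, 1 at the bottom
  w <- rank_stat^alpha * in_set
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / sum(!in_set)
  sum(p_in - p_out)
}

#' ssGSEA scores for every sample and gene set
#'
#' @param mat Genes x samples expression matrix.
#' @param gene_sets Named list of gene-id vectors.
#' @param alpha Rank-weighting exponent.
#' @return Samples x sets numeric matrix of enrichment scores.
#' @export
ssgsea_matrix <- function(mat, gene_sets, alpha = 0.75) {
  mat <- as.matrix(mat)
  scores <- vapply(gene_sets, function(gs) {
    vapply(seq_len(ncol(mat)), function(j) {
      ssgsea_score(stats::setNames(mat[, j], rownames(mat)), gs, alpha)
    }, numeric(1))
  }, numeric(ncol(mat)))
  scores <- matrix(scores, nrow = ncol(mat),
                   dimnames = list(colnames(mat), names(gene_sets)))
  scores
}

#' Category fraction and enrichment of an annotated subset
#'
#' Reports how many member genes carry an annotation, the percentage
#' (rounded to the nearest integer, as printed in category summaries such
#' as "474 (90%)") and a two-sided exact hypergeometric (Fisher) p-value
#' against the background universe.
#'
#' @param member_genes Gene ids in the category of interest.
#' @param annotated_genes Gene ids carrying the annotation (anywhere in the
#'   background).
#' @param background Background gene universe; must contain `member_genes`.
#' @return List: `count`, `percent`, `p_value`, `table` (the 2x2 matrix).
#' @export
category_fraction <- function(member_genes, annotated_genes, background) {
  member_genes <- unique(member_genes)
  annotated_genes <- unique(annotated_genes)
  background <- unique(background)
  if (length(member_genes) == 0L)
    stop_input("input error: empty member set")
  if (!all(member_genes %in% background))
    stop_input("input error: member genes outside the background")
  if (!all(annotated_genes %in% background))
    stop_input("input error: annotated genes outside the background")
  a <- sum(member_genes %in% annotated_genes)
  b <- length(member_genes) - a
  out_bg <- setdiff(background, member_genes)
  c_ <- sum(out_bg %in% annotated_genes)
  d <- length(out_bg) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2,
                dimnames = list(c("annotated", "not"),
                                c("members", "background")))
  list(count = a,
       percent = round(100 * a / length(member_genes)),
       p_value = stats::fisher.test(tab)$p.value,
       table = tab)
}

#' Category enrichment across several annotation categories
#'
#' Runs [category_fraction()] per category and adjusts p-values with
#' Benjamini-Hochberg.
#'
#' @param member_genes Gene ids in the category of interest (e.g. the
#'   highly expressed genes).
#' @param annotation_sets Named list of annotated gene-id vectors.
#' @param background Background gene universe.
#' @return data.frame: category, count, percent, p_value, p_adjusted.
#' @export
category_enrichment <- function(member_genes, annotation_sets, background) {
  rows <- lapply(names(annotation_sets), function(nm) {
    cf <- category_fraction(member_genes, annotation_sets[[nm]], background)
    data.frame(category = nm, count = cf$count, percent = cf$percent,
               p_value = cf$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Cluster samples by their enrichment-score profiles
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' samples x sets score matrix, with a flat grouping cut at `k` and a
#' Newick rendering of the dendrogram.
#'
#' @param scores Samples x sets numeric matrix.
#' @param k Number of flat groups to cut (default 2); ignored with a single
#'   sample.
#' @return List: `hclust` (or `NULL` for a single sample), `groups` (named
#'   integer vector), `newick` (character).
#' @export
cluster_by_scores <- function(scores, k = 2) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores)))
    stop_input("input error: non-finite enrichment score")
  if (nrow(scores) == 1L) {
    return(list(hclust = NULL,
                groups = stats::setNames(1L, rownames(scores)),
                newick = paste0("(", rownames(scores), ");")))
  }
  hc <- stats::hclust(stats::dist(scores, method = "euclidean"),
                      method = "average")
  groups <- stats::cutree(hc, k = min(k, nrow(scores)))
  phy <- ape::as.phylo(hc)
  list(hclust = hc, groups = groups,
       newick = ape::write.tree(phy))
}
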