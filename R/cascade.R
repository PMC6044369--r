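# Germline missense prioritization cascade.
#
# Candidate variants carry read support in up to four contexts — WGS/RNA x
# normal/polyp — as depth (dp_*) and alt-read (ad_*) columns.  The cascade
# applies, in order: cross-context concordance, uniqueness against a
# comparison panel and known SNPs, gene-annotation blacklist, read-support
# thresholds, polyp-selection ranking, evolutionary conservation (missense
# mode only) and structure-destabilization annotation (never a filter).

BLACKLIST_FLAGS <- c("retrogene", "pseudogene")

#' Cascade configuration
#'
#' @param wgs_min_depth Minimum WGS depth required in both tissues.
#' @param rna_min_depth Minimum RNA depth required in at least one tissue.
#' @param min_polyp_vaf Minimum polyp VAF required in at least one assay.
#' @param presence_min_alt,presence_min_vaf A variant counts as "found" in a
#'   context when its alt reads and VAF both reach these values (stands in
#'   for the per-caller call sets the original analysis intersected).
#' @param mode `"missense"` runs all steps; `"truncation"` skips the
#'   conservation and structure steps.
#' @param selection_as_filter If `TRUE` the polyp-selection step removes
#'   non-selected heterozygous variants instead of ranking them down.
#' @param selection_scope `"every_assay"` requires a strict polyp VAF
#'   increase in every assay observed in both tissues; `"any_assay"` in at
#'   least one.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(wgs_min_depth = 10, rna_min_depth = 30,
                           min_polyp_vaf = 0.5,
                           presence_min_alt = 2, presence_min_vaf = 0.05,
                           mode = c("missense", "truncation"),
                           selection_as_filter = FALSE,
                           selection_scope = c("every_assay", "any_assay")) {
  mode <- match.arg(mode)
  selection_scope <- match.arg(selection_scope)
  thr <- c(wgs_min_depth, rna_min_depth, min_polyp_vaf,
           presence_min_alt, presence_min_vaf)
  if (any(thr < 0)) stop_input("config error: thresholds must be >= 0")
  structure(list(wgs_min_depth = wgs_min_depth, rna_min_depth = rna_min_depth,
                 min_polyp_vaf = min_polyp_vaf,
                 presence_min_alt = presence_min_alt,
                 presence_min_vaf = presence_min_vaf,
                 mode = mode, selection_as_filter = selection_as_filter,
                 selection_scope = selection_scope),
            class = "cascade_config")
}

#' Variant allele frequency
#'
#' @param alt_count Alt-supporting read count(s).
#' @param depth Total read depth(s); must be positive where non-missing.
#' @return `alt_count / depth`; `NA` propagates.
#' @export
vaf <- function(alt_count, depth) {
  if (any(!is.na(depth) & depth == 0))
    stop_input("undefined VAF: depth is 0")
  if (any(!is.na(depth) & !is.na(alt_count) &
          (alt_count < 0 | alt_count > depth)))
    stop_input("invalid observation: alt_count outside [0, depth]")
  alt_count / depth
}

keys_of <- function(variants) {
  variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
}

# "found" in a context: enough alt reads and a non-trivial VAF; a missing
# context record (NA depth) counts as absent
present_in <- function(variants, ctx, config) {
  dp <- variants[[paste0("dp_", ctx)]]
  ad <- variants[[paste0("ad_", ctx)]]
  !is.na(dp) & !is.na(ad) & dp > 0 &
    ad >= config$presence_min_alt &
    ad / dp >= config$presence_min_vaf
}

#' Cross-assay / cross-tissue concordance step
#'
#' Keeps variants found in all four contexts (WGS and RNA, normal and
#' polyp), i.e. germline, expressed variants.
#'
#' @param variants Candidate-variant data.frame.
#' @param config A [cascade_config()].
#' @return The surviving subset.
#' @export
step_concordance <- function(variants, config = cascade_config()) {
  keep <- present_in(variants, "wgs_n", config) &
    present_in(variants, "wgs_p", config) &
    present_in(variants, "rna_n", config) &
    present_in(variants, "rna_p", config)
  variants[keep, , drop = FALSE]
}

#' Uniqueness step: exclude panel and known-SNP variants
#'
#' Removes variants whose (chrom, pos, ref, alt) key occurs in the
#' comparison panel (other cases' calls) or in the known-SNP sets.
#'
#' @param variants Candidate-variant data.frame.
#' @param panel_keys,snp_keys Character vectors of variant keys.
#' @return The surviving subset.
#' @export
step_uniqueness <- function(variants, panel_keys = character(),
                            snp_keys = character()) {
  keep <- !(keys_of(variants) %in% c(panel_keys, snp_keys))
  variants[keep, , drop = FALSE]
}

#' Annotation step: exclude blacklisted gene annotations
#'
#' Removes variants in genes flagged as retrogenes or pseudogenes.  Flags
#' are comma-separated values from the closed vocabulary
#' `{retrogene, pseudogene}` (empty string = no flag).
#'
#' @param variants Candidate-variant data.frame with a `flags` column.
#' @return The surviving subset.
#' @export
step_annotation <- function(variants) {
  fl <- strsplit(variants$flags %||% rep("", nrow(variants)), ",", fixed = TRUE)
  fl <- lapply(fl, function(x) x[nzchar(x)])
  unknown <- setdiff(unique(unlist(fl)), BLACKLIST_FLAGS)
  if (length(unknown))
    stop_input("validation error: unknown annotation flag(s): %s",
               paste(unknown, collapse = ", "))
  keep <- !vapply(fl, function(x) any(x %in% BLACKLIST_FLAGS), logical(1))
  variants[keep, , drop = FALSE]
}

#' Read-support step
#'
#' Keeps variants with (1) WGS depth at/above `wgs_min_depth` in both
#' tissues, (2) RNA depth at/above `rna_min_depth` in at least one tissue,
#' and (3) polyp VAF at/above `min_polyp_vaf` in at least one assay.  All
#' boundaries are inclusive.
#'
#' @param variants Candidate-variant data.frame.
#' @param config A [cascade_config()].
#' @return The surviving subset.
#' @export
step_support <- function(variants, config = cascade_config()) {
  num <- function(x) ifelse(is.na(x), -Inf, x)
  vaf_or_na <- function(ad, dp) ifelse(is.na(dp) | dp == 0, -Inf, ad / dp)
  keep <- num(variants$dp_wgs_n) >= config$wgs_min_depth &
    num(variants$dp_wgs_p) >= config$wgs_min_depth &
    (num(variants$dp_rna_n) >= config$rna_min_depth |
       num(variants$dp_rna_p) >= config$rna_min_depth) &
    (vaf_or_na(variants$ad_wgs_p, variants$dp_wgs_p) >= config$min_polyp_vaf |
       vaf_or_na(variants$ad_rna_p, variants$dp_rna_p) >= config$min_polyp_vaf)
  variants[keep, , drop = FALSE]
}

#' Assign zygosity from the WGS normal-tissue VAF
#'
#' Heterozygous when the germline VAF falls in [0.2, 0.8], homozygous above
#' 0.8, otherwise unknown (including a missing WGS normal context).
#'
#' @param variants Candidate-variant data.frame.
#' @return `variants` with a `zygosity` column.
#' @export
assign_zygosity <- function(variants) {
  v <- ifelse(is.na(variants$dp_wgs_n) | variants$dp_wgs_n == 0,
              NA_real_, variants$ad_wgs_n / variants$dp_wgs_n)
  variants$zygosity <- ifelse(is.na(v), "unknown",
                              ifelse(v > 0.8, "hom",
                                     ifelse(v >= 0.2, "het", "unknown")))
  variants
}

#' Polyp-selection step: rank variants under positive selection in polyps
#'
#' A heterozygous variant is "selected" when its polyp VAF strictly exceeds
#' its normal VAF in every assay observed in both tissues (configurable to
#' any assay).  By default this step only ranks — selected variants first,
#' stable order otherwise; with `selection_as_filter` it drops non-selected
#' heterozygous variants (homozygous/unknown variants always pass through).
#'
#' @param variants Candidate-variant data.frame (zygosity assigned if
#'   available; otherwise assigned here).
#' @param config A [cascade_config()].
#' @return `variants` with a logical `selected` column, reordered
#'   selected-first (or filtered).
#' @export
rank_polyp_selection <- function(variants, config = cascade_config()) {
  if (is.null(variants$zygosity)) variants <- assign_zygosity(variants)
  inc <- function(assay) {
    dn <- variants[[paste0("dp_", assay, "_n")]]
    an <- variants[[paste0("ad_", assay, "_n")]]
    dp <- variants[[paste0("dp_", assay, "_p")]]
    ap <- variants[[paste0("ad_", assay, "_p")]]
    obs <- !is.na(dn) & !is.na(dp) & dn > 0 & dp > 0
    list(obs = obs, up = obs & (ap / dp > an / dn))
  }
  w <- inc("wgs"); r <- inc("rna")
  n_obs <- w$obs + r$obs
  n_up <- w$up + r$up
  sel_vaf <- if (config$selection_scope == "every_assay") {
    n_obs > 0 & n_up == n_obs
  } else {
    n_up > 0
  }
  variants$selected <- variants$zygosity == "het" & sel_vaf
  if (config$selection_as_filter) {
    variants <- variants[variants$selected | variants$zygosity != "het", ,
                         drop = FALSE]
  }
  variants[order(!variants$selected), , drop = FALSE]
}

#' Evolutionary-conservation step
#'
#' Removes a variant when its alternate allele is observed at the homologous
#' position in any ortholog — a change that already occurred during
#' evolution is most likely a natural variant, not pathogenic.  Variants
#' without a profile are retained with a warning.
#'
#' @param variants Candidate-variant data.frame.
#' @param profiles Named list (by variant key) of character vectors of
#'   ortholog states.
#' @return The surviving subset.
#' @export
step_conservation <- function(variants, profiles = list()) {
  key <- keys_of(variants)
  has <- key %in% names(profiles) &
    vapply(profiles[match(key, names(profiles))],
           function(p) length(p) > 0, logical(1))
  if (any(!has))
    warning(sum(!has), " variant(s) without a conservation profile were ",
            "retained", call. = FALSE)
  seen <- rep(FALSE, nrow(variants))
  if (any(has)) {
    seen[has] <- mapply(function(k, a) a %in% profiles[[k]],
                        key[has], variants$alt[has], USE.NAMES = FALSE)
  }
  variants[!seen, , drop = FALSE]
}

#' Structure-annotation step
#'
#' Copies the externally supplied destabilization prediction into a
#' `priority` flag.  Annotation only: never removes a variant.
#'
#' @param variants Candidate-variant data.frame with an optional
#'   `structure_destabilizing` column.
#' @return `variants` with a logical `priority` column.
#' @export
annotate_structure <- function(variants) {
  sd_flag <- variants$structure_destabilizing %||% rep(NA, nrow(variants))
  variants$priority <- !is.na(sd_flag) & sd_flag
  variants
}

#' Run the full prioritization cascade
#'
#' Applies, in order: concordance, uniqueness, annotation, support,
#' polyp-selection ranking, conservation (missense mode only) and structure
#' annotation (missense mode only).  The report records per-step input and
#' surviving counts, the surviving keys, the final ranked table and the
#' top-priority tier.
#'
#' @param variants Candidate-variant data.frame.
#' @param panel_keys,snp_keys Exclusion key sets for the uniqueness step.
#' @param profiles Conservation profiles (named list by key).
#' @param config A [cascade_config()].
#' @return A list of class `cascade_report`: `steps` (data.frame: step,
#'   n_in, n_out), `surviving_keys` (list by step), `final` (ranked
#'   data.frame), `top_keys` (selected and, in missense mode,
#'   structure-prioritized survivors) and `mode`.
#' @export
run_cascade <- function(variants, panel_keys = character(),
                        snp_keys = character(), profiles = list(),
                        config = cascade_config()) {
  steps <- character(); n_in <- integer(); n_out <- integer()
  surviving <- list()
  cur <- variants
  apply_step <- function(name, f) {
    steps <<- c(steps, name); n_in <<- c(n_in, nrow(cur))
    cur <<- f(cur)
    n_out <<- c(n_out, nrow(cur))
    surviving[[name]] <<- keys_of(cur)
  }
  apply_step("concordance", function(v) step_concordance(v, config))
  apply_step("uniqueness", function(v) step_uniqueness(v, panel_keys, snp_keys))
  apply_step("annotation", step_annotation)
  apply_step("support", function(v) step_support(v, config))
  cur <- assign_zygosity(cur)
  apply_step("selection", function(v) rank_polyp_selection(v, config))
  if (config$mode == "missense") {
    apply_step("conservation", function(v) step_conservation(v, profiles))
    apply_step("structure", annotate_structure)
  }
  if (is.null(cur$selected)) cur$selected <- FALSE
  if (is.null(cur$priority)) cur$priority <- FALSE
  cur <- cur[order(!cur$selected, !cur$priority), , drop = FALSE]
  top <- if (config$mode == "missense") {
    cur$selected & cur$priority
  } else {
    cur$selected
  }
  structure(list(
    steps = data.frame(step = steps, n_in = n_in, n_out = n_out,
                       stringsAsFactors = FALSE),
    surviving_keys = surviving,
    final = cur,
    top_keys = keys_of(cur)[top],
    mode = config$mode
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Prioritization cascade (", x$mode, " mode)\n", sep = "")
  print(x$steps, row.names = FALSE)
  cat("top-priority survivors:",
      if (length(x$top_keys)) paste(x$top_keys, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Precision and recall of a cascade run against planted truth
#'
#' Compares the report's top-priority tier with the planted survivor keys.
#'
#' @param report A [run_cascade()] result.
#' @param truth A planted-truth list with `survivor_keys`.
#' @return A list with `precision`, `recall`, `called`, `expected`.
#' @export
cascade_recovery <- function(report, truth) {
  called <- report$top_keys
  expected <- truth$survivor_keys
  tp <- length(intersect(called, expected))
  list(
    precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(expected)) tp / length(expected) else NA_real_,
    called = called, expected = expected
  )
}
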