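# Candidate-variant table simulator.
#
# Plants exactly one germline missense survivor shaped like the case study's
# exemplar (VAF rising 0.67 -> 0.82 in WGS and 0.50 -> 0.70 in RNA) plus one
# decoy family per cascade step.  Each decoy is constructed to pass every
# step upstream of its own and to violate its own step deterministically:
# alt counts are binomial draws around the family's target VAF, clamped into
# the VAF interval the family requires so sampling noise cannot move a decoy
# across a threshold it is meant to sit on.

# binomial alt count clamped so that alt/depth stays inside [lo, hi]
clamped_alt <- function(depth, p, lo, hi) {
  alt <- stats::rbinom(length(depth), depth, p)
  pmin(pmax(alt, ceiling(lo * depth)), floor(hi * depth))
}

# depths around the configured means, floored at the cascade thresholds so a
# "passing" pattern cannot fail the support step by sampling noise
passing_depths <- function(n, config) {
  list(
    dp_wgs_n = pmax(stats::rpois(n, config$wgs_depth), 10L),
    dp_wgs_p = pmax(stats::rpois(n, config$wgs_depth), 10L),
    dp_rna_n = pmax(stats::rpois(n, config$rna_depth), 30L),
    dp_rna_p = pmax(stats::rpois(n, config$rna_depth), 30L)
  )
}

# alt counts for a fully passing heterozygous pattern: normal VAF in
# [0.55, 0.70], polyp VAF in [0.74, 0.90] -> concordant, het, supported,
# polyp-selected
passing_alts <- function(dp) {
  list(
    ad_wgs_n = clamped_alt(dp$dp_wgs_n, 0.62, 0.55, 0.70),
    ad_wgs_p = clamped_alt(dp$dp_wgs_p, 0.80, 0.74, 0.90),
    ad_rna_n = clamped_alt(dp$dp_rna_n, 0.62, 0.55, 0.70),
    ad_rna_p = clamped_alt(dp$dp_rna_p, 0.80, 0.74, 0.90)
  )
}

#' Simulate a candidate-variant table with planted cascade ground truth
#'
#' Generates `1 + 10 * n_decoys_per_family` candidate variants: one survivor
#' that passes the whole prioritization cascade by construction, and ten
#' decoy families each violating exactly one cascade step (concordance;
#' uniqueness against the SNP set and against the comparison panel;
#' annotation blacklist; the three read-support clauses; polyp selection;
#' evolutionary conservation; structure annotation).
#'
#' @param config A [sim_config()].
#' @return A list with `variants` (data.frame, one row per candidate with
#'   per-context depth/alt columns), `panel_keys`, `snp_keys`, `profiles`
#'   (named list of ortholog allele vectors keyed by variant key) and
#'   `truth` (`survivor_keys`; `decoys` data.frame mapping each decoy key to
#'   the step meant to remove or demote it).
#' @export
sim_variant_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_decoys_per_family
  families <- c("concordance", "uniqueness_snp", "uniqueness_panel",
                "annotation", "support_wgs_depth", "support_rna_depth",
                "support_vaf", "selection", "conservation", "structure")
  n <- 1L + length(families) * m

  with_gen_seed(config$seed, 104L, {
    chrom <- sample(names(config$chrom_lengths), n, replace = TRUE)
    pos <- integer(n)
    for (cn in unique(chrom)) {
      idx <- which(chrom == cn)
      pos[idx] <- sample.int(config$chrom_lengths[[cn]], length(idx))
    }
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    gene <- sprintf("gene%04d", seq_len(n))
    key <- variant_key(chrom, pos, ref, alt)

    role <- c("survivor", rep(families, each = m))
    dp <- passing_depths(n, config)
    ad <- passing_alts(dp)
    v <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene = gene, flags = "",
                    structure_destabilizing = NA,
                    stringsAsFactors = FALSE)
    for (cl in names(dp)) v[[cl]] <- dp[[cl]]
    for (cl in names(ad)) v[[cl]] <- ad[[cl]]
    v <- v[, c("chrom", "pos", "ref", "alt", "gene", "flags",
               "structure_destabilizing", OBS_COLS)]

    # survivor: the exemplar support pattern, deterministic so it passes
    # every step by construction
    i <- which(role == "survivor")
    v$dp_wgs_n[i] <- 21L; v$ad_wgs_n[i] <- round(0.67 * 21)   # VAF 0.67
    v$dp_wgs_p[i] <- 22L; v$ad_wgs_p[i] <- round(0.82 * 22)   # VAF 0.82
    v$dp_rna_n[i] <- 100L; v$ad_rna_n[i] <- 50L               # VAF 0.50
    v$dp_rna_p[i] <- 110L; v$ad_rna_p[i] <- round(0.70 * 110) # VAF 0.70
    v$structure_destabilizing[i] <- TRUE

    fi <- function(f) which(role == f)

    # absent from one RNA context -> fails cross-assay/tissue concordance
    i <- fi("concordance"); v$ad_rna_n[i] <- 0L
    # blacklisted gene annotation
    i <- fi("annotation")
    v$flags[i] <- sample(c("retrogene", "pseudogene"), m, replace = TRUE)
    # WGS coverage 9 in the normal sample (one read below the >=10 rule)
    i <- fi("support_wgs_depth")
    v$dp_wgs_n[i] <- 9L
    v$ad_wgs_n[i] <- clamped_alt(v$dp_wgs_n[i], 0.62, 0.55, 0.70)
    # RNA coverage below 30 in both tissues
    i <- fi("support_rna_depth")
    v$dp_rna_n[i] <- 29L; v$dp_rna_p[i] <- 25L
    v$ad_rna_n[i] <- clamped_alt(v$dp_rna_n[i], 0.62, 0.55, 0.70)
    v$ad_rna_p[i] <- clamped_alt(v$dp_rna_p[i], 0.80, 0.74, 0.90)
    # polyp VAF below 0.5 in both assays (normal lower still, to stay het
    # and concordant)
    i <- fi("support_vaf")
    v$ad_wgs_n[i] <- clamped_alt(v$dp_wgs_n[i], 0.25, 0.20, 0.28)
    v$ad_rna_n[i] <- clamped_alt(v$dp_rna_n[i], 0.25, 0.20, 0.28)
    v$ad_wgs_p[i] <- clamped_alt(v$dp_wgs_p[i], 0.40, 0.30, 0.49)
    v$ad_rna_p[i] <- clamped_alt(v$dp_rna_p[i], 0.40, 0.30, 0.49)
    # heterozygous but not polyp-selected: polyp VAF at or below normal
    i <- fi("selection")
    v$ad_wgs_n[i] <- clamped_alt(v$dp_wgs_n[i], 0.65, 0.60, 0.70)
    v$ad_rna_n[i] <- clamped_alt(v$dp_rna_n[i], 0.65, 0.60, 0.70)
    v$ad_wgs_p[i] <- clamped_alt(v$dp_wgs_p[i], 0.55, 0.50, 0.58)
    v$ad_rna_p[i] <- clamped_alt(v$dp_rna_p[i], 0.55, 0.50, 0.58)
    v$structure_destabilizing[i] <- FALSE
    # passes every filter and is selected, but not structure-destabilizing
    i <- fi("structure"); v$structure_destabilizing[i] <- FALSE

    # uniqueness decoys share their keys with the exclusion sets
    snp_keys <- key[fi("uniqueness_snp")]
    panel_keys <- key[fi("uniqueness_panel")]

    # ortholog profiles: 20 species carrying the reference allele, except the
    # conservation family whose alternate allele recurs in >=1 species
    profiles <- lapply(seq_len(n), function(j) rep(ref[j], 20L))
    names(profiles) <- key
    for (j in fi("conservation")) {
      prof <- profiles[[j]]
      prof[sample.int(20L, sample(1:3, 1L))] <- alt[j]
      profiles[[j]] <- prof
    }

    list(
      variants = v,
      panel_keys = panel_keys,
      snp_keys = snp_keys,
      profiles = profiles,
      truth = list(
        survivor_keys = key[role == "survivor"],
        decoys = data.frame(
          key = key[role != "survivor"],
          step = sub("_(snp|panel|wgs_depth|rna_depth|vaf)$", "",
                     role[role != "survivor"]),
          stringsAsFactors = FALSE)
      )
    )
  })
}
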