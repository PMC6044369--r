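#' Simulate a log2-FPKM expression matrix with planted outlier genes
#'
#' Baseline values are drawn per gene from a normal distribution with a
#' gene-specific mean and SD.  `n_high` genes are shifted up and `n_low`
#' genes shifted down by `outlier_effect` SD units in the case sample only
#' (the first column).  Two guard rails make the planted truth exactly
#' recoverable by the outlier statistic: non-case draws are truncated to
#' |z| <= 3 (so no background draw can out-rank a 5-SD plant), and the case
#' sample's baseline draw for unplanted genes is truncated to |z| <= 0.5 (so
#' an unplanted gene can never place the case sample outside mean +/- 1 SD
#' as the strict extremum).  Real data carry no such guarantee; see the
#' methods vignette.
#'
#' @param config A [sim_config()].
#' @return A list with `log2_fpkm` (genes x samples matrix, case sample
#'   first), `case_sample` (its column name) and `truth` (data.frame: gene,
#'   direction in {high, low}).
#' @export
sim_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  ns <- config$n_samples
  if (ns < 3L) stop_input("configuration error: need >= 3 samples")
  if (config$n_high + config$n_low > ng)
    stop_input("configuration error: more planted outliers than genes")

  rtrunc_norm <- function(n, bound) {
    z <- stats::rnorm(n)
    pmin(pmax(z, -bound), bound)
  }

  with_gen_seed(config$seed, 105L, {
    genes <- sprintf("g%04d", seq_len(ng))
    samples <- c("case_polyp", sprintf("S%02d", seq_len(ns - 1L)))
    mu <- stats::runif(ng, 2, 12)
    sigma <- stats::runif(ng, 0.3, 0.8)

    z <- matrix(rtrunc_norm(ng * ns, 3), nrow = ng)
    z[, 1L] <- rtrunc_norm(ng, 0.5)

    planted <- sample.int(ng, config$n_high + config$n_low)
    hi <- planted[seq_len(config$n_high)]
    lo <- setdiff(planted, hi)
    z[hi, 1L] <- z[hi, 1L] + config$outlier_effect
    z[lo, 1L] <- z[lo, 1L] - config$outlier_effect

    x <- mu + z * sigma
    dimnames(x) <- list(genes, samples)

    list(
      log2_fpkm = x,
      case_sample = samples[1L],
      truth = data.frame(
        gene = genes[c(hi, lo)],
        direction = rep(c("high", "low"), c(length(hi), length(lo))),
        stringsAsFactors = FALSE)
    )
  })
}

#' Simulate per-window read-pair densities with planted chromosome gains
#'
#' Control window counts are Poisson with mean `window_lambda`; case counts
#' are Poisson with mean `trisomy_ratio * window_lambda` on the gained
#' chromosomes and `window_lambda` elsewhere, emulating whole-chromosome
#' aneuploidy at desk scale.
#'
#' @param config A [sim_config()]; uses `cnv_chroms`, `cnv_windows`,
#'   `window_lambda`, `trisomy_ratio`, `gained_chroms`.
#' @return A list with `case` and `control` data.frames (chrom, window,
#'   count; window 0-based) and `truth` (gained chromosome names).
#' @export
sim_cnv <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cnv_chroms < 2L)
    stop_input("configuration error: need >= 2 chromosomes")
  if (config$window_lambda <= 0)
    stop_input("configuration error: window_lambda must be > 0")

  with_gen_seed(config$seed, 106L, {
    chroms <- paste0("chr", seq_len(config$cnv_chroms))
    nw <- config$cnv_windows
    grid <- data.frame(
      chrom = rep(chroms, each = nw),
      window = rep(seq_len(nw) - 1L, times = length(chroms)),
      stringsAsFactors = FALSE)
    lam <- config$window_lambda
    gained <- grid$chrom %in% config$gained_chroms

    control <- grid
    control$count <- stats::rpois(nrow(grid), lam)
    case <- grid
    case$count <- stats::rpois(nrow(grid),
                               ifelse(gained, config$trisomy_ratio * lam, lam))
    list(case = case, control = control, truth = config$gained_chroms)
  })
}
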