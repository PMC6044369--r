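# Read-depth copy-number analysis on 1-kb tiling windows.

#' Per-window mapped-pair density for one chromosome
#'
#' Assigns each fragment midpoint to `floor(midpoint / window)`; the final
#' partial window is included.
#'
#' @param midpoints Fragment midpoints, 0-based, in `[0, chrom_length)`.
#' @param chrom_length Chromosome length (bp).
#' @param window Window size (bp), default 1000.
#' @return data.frame: window (0-based index), count; one row per window
#'   tiling the chromosome.
#' @export
window_density <- function(midpoints, chrom_length, window = 1000) {
  if (chrom_length <= 0) stop_input("input error: chrom_length must be > 0")
  if (length(midpoints) && (min(midpoints) < 0 || max(midpoints) >= chrom_length))
    stop_input("coordinate error: midpoint outside [0, %d)", chrom_length)
  n_win <- ceiling(chrom_length / window)
  idx <- floor(midpoints / window) + 1L
  data.frame(window = seq_len(n_win) - 1L,
             count = tabulate(idx, nbins = n_win))
}

#' Normalize case window densities against a control genome
#'
#' Both profiles are scaled to pairs per million (library-size correction),
#' then each window gets `log2(case_scaled / control_scaled)`.  Windows
#' whose raw control count falls below `min_control` are masked (their
#' ratio is unstable).  By default the library size is estimated robustly
#' as `median(count) * n_windows`, so that chromosomes with a genuine
#' copy-number change do not inflate the baseline and deflate their own
#' ratio; pass explicit totals to scale by true library sizes instead.
#' The estimate is the median over chromosomes of the per-chromosome median
#' window count, times the window count — insensitive to whole-chromosome
#' gains as long as they affect a minority of chromosomes.
#'
#' @param case,control data.frames with columns chrom, window, count on the
#'   identical window grid.
#' @param min_control Minimum raw control count for an unmasked window.
#' @param case_total,control_total Library-wide pair totals; `NULL` (the
#'   default) uses the robust median-based estimate.
#' @return data.frame: chrom, window, log2_ratio, masked.
#' @export
normalize_to_control <- function(case, control, min_control = 10,
                                 case_total = NULL, control_total = NULL) {
  if (nrow(case) != nrow(control) ||
      !all(case$chrom == control$chrom) ||
      !all(case$window == control$window))
    stop_input("input error: case and control window grids differ")
  robust_total <- function(d) {
    per_chrom <- tapply(d$count, d$chrom, stats::median)
    stats::median(per_chrom) * nrow(d)
  }
  case_total <- case_total %||% robust_total(case)
  control_total <- control_total %||% robust_total(control)
  if (case_total <= 0 || control_total <= 0)
    stop_input("input error: library totals must be > 0")
  case_rate <- 1e6 * case$count / case_total
  ctrl_rate <- 1e6 * control$count / control_total
  masked <- control$count < min_control
  ratio <- ifelse(masked, NA_real_, log2(case_rate / ctrl_rate))
  data.frame(chrom = case$chrom, window = case$window,
             log2_ratio = ratio, masked = masked,
             stringsAsFactors = FALSE)
}

#' Whole-chromosome gain/loss calls
#'
#' Calls each chromosome from the median of its unmasked per-window log2
#' ratios: gain at/above `gain_thresh`, loss at/below `loss_thresh`,
#' otherwise neutral; `NA` when every window is masked.  The default
#' thresholds sit below the pure-diploid single-copy values (+0.585 /
#' -1) to tolerate subclonality and impure tissue.
#'
#' @param profile A [normalize_to_control()] result.
#' @param gain_thresh,loss_thresh Median log2-ratio thresholds.
#' @return data.frame: chrom, state (gain/neutral/loss/NA), median_log2,
#'   n_windows (unmasked).
#' @export
call_whole_chromosome <- function(profile, gain_thresh = 0.32,
                                  loss_thresh = -0.42) {
  chroms <- unique(profile$chrom)
  rows <- lapply(chroms, function(cn) {
    r <- profile$log2_ratio[profile$chrom == cn & !profile$masked]
    if (length(r) == 0L) {
      return(data.frame(chrom = cn, state = NA_character_,
                        median_log2 = NA_real_, n_windows = 0L,
                        stringsAsFactors = FALSE))
    }
    med <- stats::median(r)
    state <- if (med >= gain_thresh) "gain"
             else if (med <= loss_thresh) "loss"
             else "neutral"
    data.frame(chrom = cn, state = state, median_log2 = med,
               n_windows = length(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
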