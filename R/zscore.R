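#' Chromosome-wise z-score standardization
#'
#' Transforms each chromosome's log2 ratios to z-scores using that
#' chromosome's own mean and sample standard deviation (n - 1 denominator),
#' so that each chromosome is centered at 0 with unit spread. This is the
#' scale on which the HMM emissions are defined; downstream calls are
#' therefore invariant to chromosome-wide shifts of the raw ratios.
#'
#' @param track A [probe_track()]; every chromosome needs at least two
#'   probes and non-zero variance.
#' @return An object of class `zscore_track`: list with `sample_id`,
#'   `probes` (columns `chrom`, `pos`, `z`) and `stats` (per-chromosome
#'   `mean_log2`, `sd_log2`).
#' @examples
#' tr <- probe_track(data.frame(chrom = "1", pos = c(1, 2, 3) * 25000,
#'                              log2_ratio = c(1, 2, 3)), "s1")
#' zscore_normalize(tr)$probes$z  # -1 0 1
#' @export
zscore_normalize <- function(track) {
  stopifnot(inherits(track, "probe_track"))
  p <- track$probes
  chroms <- chrom_order(p$chrom)
  z <- numeric(nrow(p))
  stats <- data.frame(chrom = chroms, mean_log2 = NA_real_,
                      sd_log2 = NA_real_)
  for (i in seq_along(chroms)) {
    idx <- which(p$chrom == chroms[i])
    if (length(idx) < 2L)
      stop_cnv("cnv_insufficient_data_error",
               "%s has %d probe(s); need >= 2 for standardization",
               chroms[i], length(idx))
    m <- mean(p$log2_ratio[idx])
    s <- stats::sd(p$log2_ratio[idx])
    if (!is.finite(s) || s <= 0)
      stop_cnv("cnv_degenerate_variance_error",
               "%s has zero variance; z-scores undefined", chroms[i])
    z[idx] <- (p$log2_ratio[idx] - m) / s
    stats$mean_log2[i] <- m
    stats$sd_log2[i] <- s
  }
  structure(list(sample_id = track$sample_id,
                 probes = data.frame(chrom = p$chrom, pos = p$pos, z = z),
                 stats = stats),
            class = "zscore_track")
}
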