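#' Two-sided Fisher's exact test for a 2x2 burden table
#'
#' Exact two-sided p-value by the probability-mass method: with all margins
#' fixed, the hypergeometric probabilities of every table whose probability
#' does not exceed that of the observed table (within relative tolerance
#' 1e-7) are summed. This is the convention of standard statistical
#' software. When any margin is zero the test is uninformative and 1 is
#' returned with a warning.
#'
#' @param a Cases with the event, or a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))` in which case `b`, `c`, `d` are ignored.
#' @param b Cases without the event.
#' @param c Controls with the event.
#' @param d Controls without the event.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(3, 183, 8, 2485)  # 0.036
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop_cnv("cnv_value_error", "table entries must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    warning("a margin of the 2x2 table is zero; Fisher's exact test is ",
            "uninformative (p = 1)")
    return(1)
  }
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(support, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Count samples carrying at least one large rare event
#'
#' @param cohort_calls Named list mapping sample id to its `cnv_segments`.
#' @param threshold_mb Size threshold in Mb; an event counts when its
#'   `size_mb` is strictly greater than the threshold (the comparison uses
#'   the unrounded size).
#' @return Number of samples with at least one rare call above the
#'   threshold.
#' @export
count_large_event_carriers <- function(cohort_calls, threshold_mb) {
  sum(vapply(cohort_calls, function(seg) {
    if (is.null(seg) || nrow(seg) == 0L) return(FALSE)
    rare <- !is.na(seg$rare) & seg$rare
    any(rare & segment_size_mb(seg) > threshold_mb)
  }, logical(1)))
}

#' Cohort-level rare-CNV summary and burden tests
#'
#' Counts the samples carrying at least one rare, gene-containing call
#' (gene annotation must already have been applied, e.g. via
#' [annotate_calls()]) and reports the carrier percentage to one decimal.
#' For each size threshold in `config$large_event_thresholds_mb` the number
#' of case samples with a rare event strictly above the threshold is
#' compared against the supplied control carrier count by
#' [fisher_exact_two_sided()].
#'
#' @param cohort_calls Named list mapping sample id to its annotated
#'   `cnv_segments`.
#' @param control_n Number of control individuals.
#' @param control_large_event_carriers Control samples carrying an event
#'   above each threshold: a single number (used for every threshold), a
#'   vector matching `large_event_thresholds_mb` in length, or a named
#'   vector keyed by threshold (e.g. `c("2" = 8)`); thresholds without a
#'   supplied count get `NA` burden results.
#' @param config A [run_config()].
#' @return Object of class `cohort_summary`: `n_samples`,
#'   `n_rare_gene_cnv_carriers`, `carrier_percent`, and a `burden` data
#'   frame with one row per threshold (`threshold_mb`, the 2x2 counts, and
#'   `p_value`).
#' @export
summarize_cohort <- function(cohort_calls, control_n = NA,
                             control_large_event_carriers = NA,
                             config = run_config()) {
  n <- length(cohort_calls)
  if (n == 0L)
    stop_cnv("cnv_value_error", "empty cohort")
  if (!is.na(control_n) && control_n <= 0)
    stop_cnv("cnv_config_error", "control_n must be > 0")
  carriers <- sum(vapply(cohort_calls, function(seg) {
    if (is.null(seg) || nrow(seg) == 0L) return(FALSE)
    any(!is.na(seg$rare) & seg$rare &
          !is.na(seg$gene_containing) & seg$gene_containing)
  }, logical(1)))
  thr <- config$large_event_thresholds_mb
  ctl <- control_large_event_carriers
  if (length(ctl) == 1L && is.null(names(ctl))) ctl <- rep(ctl, length(thr))
  ctl_for <- function(t) {
    if (!is.null(names(ctl))) {
      m <- match(as.character(t), names(ctl))
      if (is.na(m)) NA_real_ else ctl[[m]]
    } else ctl[[match(t, thr)]]
  }
  burden <- do.call(rbind, lapply(thr, function(t) {
    a <- count_large_event_carriers(cohort_calls, t)
    cc <- ctl_for(t)
    p <- if (is.na(control_n) || is.na(cc)) NA_real_ else
      fisher_exact_two_sided(a, n - a, cc, control_n - cc)
    data.frame(threshold_mb = t, cases_with_event = a,
               cases_without = n - a, controls_with_event = cc,
               controls_without = if (is.na(cc)) NA_real_ else control_n - cc,
               p_value = p)
  }))
  structure(list(n_samples = n,
                 n_rare_gene_cnv_carriers = carriers,
                 carrier_percent = round(100 * carriers / n, 1),
                 burden = burden),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "cohort of %d samples: %d (%.1f%%) carry >=1 rare gene-containing CNV\n",
    x$n_samples, x$n_rare_gene_cnv_carriers, x$carrier_percent))
  for (i in seq_len(nrow(x$burden))) {
    b <- x$burden[i, ]
    cat(sprintf("  events > %g Mb: %d/%d cases vs %s/%s controls%s\n",
                b$threshold_mb, b$cases_with_event, x$n_samples,
                ifelse(is.na(b$controls_with_event), "?",
                       format(b$controls_with_event)),
                ifelse(is.na(b$controls_without), "?",
                       format(b$controls_with_event + b$controls_without)),
                ifelse(is.na(b$p_value), "",
                       sprintf(" (Fisher's exact P = %.3f)", b$p_value))))
  }
  invisible(x)
}

#' Write a cohort summary as TSV
#'
#' @param summary A [summarize_cohort()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_summary <- function(summary, path) {
  df <- summary$burden
  df$n_samples <- summary$n_samples
  df$n_rare_gene_cnv_carriers <- summary$n_rare_gene_cnv_carriers
  df$carrier_percent <- summary$carrier_percent
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
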