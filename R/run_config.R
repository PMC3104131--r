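#' Pipeline configuration
#'
#' Bundles every tunable threshold of the calling pipeline. Defaults encode
#' the published segmentation rules: probe runs of one state are split at
#' inter-probe gaps of 50 kb or more; same-state segments separated by at
#' most 5 intervening probes spanning at most 10 kb are bridged into one
#' variant; events with fewer than 5 probes are discarded; events matching a
#' control-catalog interval of the same type at >= 50% reciprocal overlap
#' are discarded as common.
#'
#' @param min_probes Minimum probes per surviving event (default 5).
#' @param merge_gap_bp Same-state probes at least this far apart are split
#'   into separate segments (default 50000; the merge rule is strict
#'   "< 50 kb").
#' @param bridge_max_probes Maximum intervening probe count for bridging two
#'   same-state segments (default 5).
#' @param bridge_max_bp Maximum intervening span in bp for bridging
#'   (default 10000).
#' @param emission_mean_shift Emission means of the altered copy-number
#'   states, in z-score units above/below the normal mean (default 2).
#' @param state_self_transition Self-transition probability of each HMM
#'   state, strictly inside (0, 1). The default 0.9999 corresponds to an
#'   expected one copy-number state change per ~10,000 probes (roughly the
#'   per-genome CNV rate at 25-kb probe spacing) and keeps the expected
#'   number of false segments per genome well below one; see the package
#'   vignette.
#' @param common_overlap_fraction Reciprocal-overlap fraction in (0, 1] at or
#'   above which a call matches a control-catalog interval (default 0.5).
#'   The same threshold is used for inheritance matching.
#' @param large_event_thresholds_mb Size thresholds (Mb) for the cohort
#'   large-event counts and burden tests (default c(1, 2)).
#' @param random_seed Integer seed recorded with the configuration.
#'
#' @return An object of class `cnv_run_config` (a validated list).
#' @examples
#' cfg <- run_config()
#' cfg$min_probes
#' @export
run_config <- function(min_probes = 5L,
                       merge_gap_bp = 50000L,
                       bridge_max_probes = 5L,
                       bridge_max_bp = 10000L,
                       emission_mean_shift = 2,
                       state_self_transition = 0.9999,
                       common_overlap_fraction = 0.5,
                       large_event_thresholds_mb = c(1, 2),
                       random_seed = 1L) {
  cfg <- list(min_probes = as.integer(min_probes),
              merge_gap_bp = as.integer(merge_gap_bp),
              bridge_max_probes = as.integer(bridge_max_probes),
              bridge_max_bp = as.integer(bridge_max_bp),
              emission_mean_shift = as.numeric(emission_mean_shift),
              state_self_transition = as.numeric(state_self_transition),
              common_overlap_fraction = as.numeric(common_overlap_fraction),
              large_event_thresholds_mb = as.numeric(large_event_thresholds_mb),
              random_seed = as.integer(random_seed))
  validate_run_config(cfg)
  structure(cfg, class = "cnv_run_config")
}

validate_run_config <- function(cfg) {
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(cfg$min_probes) || cfg$min_probes < 1L)
    stop_cnv("cnv_config_error", "min_probes must be a positive integer")
  for (f in c("merge_gap_bp", "bridge_max_probes", "bridge_max_bp",
              "emission_mean_shift"))
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0)
      stop_cnv("cnv_config_error", "%s must be positive", f)
  if (!num1(cfg$state_self_transition) ||
      cfg$state_self_transition <= 0 || cfg$state_self_transition >= 1)
    stop_cnv("cnv_config_error",
             "state_self_transition must lie strictly in (0, 1)")
  if (!num1(cfg$common_overlap_fraction) ||
      cfg$common_overlap_fraction <= 0 || cfg$common_overlap_fraction > 1)
    stop_cnv("cnv_config_error",
             "common_overlap_fraction must lie in (0, 1]")
  if (length(cfg$large_event_thresholds_mb) < 1L ||
      any(!is.finite(cfg$large_event_thresholds_mb)) ||
      any(cfg$large_event_thresholds_mb <= 0))
    stop_cnv("cnv_config_error",
             "large_event_thresholds_mb must be positive")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys take their [run_config()] defaults; unknown keys are an
#' error. Arguments in `...` override values from the file (the CLI uses
#' this for flag overrides).
#'
#' @param path Path to a YAML file whose keys match [run_config()] arguments.
#' @param ... Named overrides applied after the file is read.
#' @return A `cnv_run_config` object.
#' @export
read_run_config <- function(path, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_cnv("cnv_config_error", "unknown configuration key(s): %s",
             paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.cnv_run_config <- function(x, ...) {
  cat("CNV calling configuration\n")
  for (f in setdiff(names(x), "random_seed"))
    cat(sprintf("  %-26s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  cat(sprintf("  %-26s %d\n", "random_seed", x$random_seed))
  invisible(x)
}
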