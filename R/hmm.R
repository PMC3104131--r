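CNV_STATES <- c("decreased", "normal", "increased")

#' Build the three-state copy-number HMM
#'
#' States are `decreased`, `normal` and `increased` copy number with
#' Gaussian emissions on the z-score scale: the normal state emits N(0, 1),
#' the altered states share the normal state's standard deviation but have
#' means `d` z-score units below and above it (`d =
#' emission_mean_shift`, default 2). Transitions are symmetric with
#' self-probability `s = state_self_transition` and `(1 - s)/2` to each
#' other state; the initial distribution is uniform.
#'
#' @param config A [run_config()].
#' @return Object of class `cnv_hmm`: states, `emission_means`,
#'   `emission_sds`, row-stochastic 3x3 `transition`, `initial`.
#' @export
build_hmm <- function(config = run_config()) {
  validate_run_config(config)
  d <- config$emission_mean_shift
  s <- config$state_self_transition
  trans <- matrix((1 - s) / 2, 3, 3,
                  dimnames = list(CNV_STATES, CNV_STATES))
  diag(trans) <- s
  structure(list(states = CNV_STATES,
                 emission_means = c(-d, 0, d),
                 emission_sds = c(1, 1, 1),
                 transition = trans,
                 initial = rep(1 / 3, 3)),
            class = "cnv_hmm")
}

#' @export
print.cnv_hmm <- function(x, ...) {
  cat("3-state copy-number HMM (Gaussian emissions on z-scores)\n")
  cat("  means:", paste(format(x$emission_means), collapse = " "),
      " sds:", paste(format(x$emission_sds), collapse = " "), "\n")
  cat("  self-transition:", format(x$transition[1, 1]), "\n")
  invisible(x)
}

#' Decode per-probe copy-number states
#'
#' Computes, independently for each chromosome, the Viterbi (global maximum
#' a posteriori) state path of the three-state HMM over the chromosome's
#' z-scores. All arithmetic is in log space, so arbitrarily long
#' chromosomes decode without underflow. Exact score ties are broken in
#' favour of `normal`, then `increased`, then `decreased` (bias toward
#' no-call).
#'
#' @param model A [build_hmm()] model.
#' @param z A [zscore_normalize()] track.
#' @return Object of class `state_track`: data frame `probes` with columns
#'   `chrom`, `pos`, `state` (factor with levels decreased/normal/increased)
#'   aligned 1:1 with the z-score track, plus the `sample_id`.
#' @export
decode_states <- function(model, z) {
  stopifnot(inherits(model, "cnv_hmm"), inherits(z, "zscore_track"))
  if (nrow(z$probes) == 0L)
    stop_cnv("cnv_value_error", "empty z-score track")
  p <- z$probes
  ltrans <- log(model$transition)
  linit <- log(model$initial)
  state <- integer(nrow(p))
  for (ch in chrom_order(p$chrom)) {
    idx <- which(p$chrom == ch)
    state[idx] <- viterbi_path(p$z[idx], model$emission_means,
                               model$emission_sds, ltrans, linit)
  }
  structure(list(sample_id = z$sample_id,
                 probes = data.frame(chrom = p$chrom, pos = p$pos,
                                     state = factor(CNV_STATES[state],
                                                    levels = CNV_STATES))),
            class = "state_track")
}
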