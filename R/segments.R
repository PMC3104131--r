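SEGMENT_COLS <- c("sample_id", "chrom", "start", "end", "state", "n_probes",
                  "mean_z", "size_mb", "genes", "gene_containing", "rare")

new_segments <- function(df) {
  for (col in SEGMENT_COLS)
    if (is.null(df[[col]]))
      df[[col]] <- switch(col,
                          size_mb = (df$end - df$start) / 1e6,
                          genes = NA_character_,
                          gene_containing = NA,
                          rare = NA,
                          stop("missing column ", col))
  df <- df[SEGMENT_COLS]
  df$size_mb <- (df$end - df$start) / 1e6
  rownames(df) <- NULL
  class(df) <- c("cnv_segments", "data.frame")
  df
}

empty_segments <- function(sample_id = character(0)) {
  new_segments(data.frame(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          state = character(), n_probes = integer(),
                          mean_z = numeric(), size_mb = numeric(),
                          genes = character(), gene_containing = logical(),
                          rare = logical()))
}

#' Build CNV segments from per-probe state calls
#'
#' Maximal runs of consecutive same-state non-normal probes become candidate
#' segments; a run is split wherever two adjacent same-state probes are
#' `merge_gap_bp` or more apart (the merge rule is strict: probes less than
#' 50 kb apart are merged under the defaults). Segment coordinates are the
#' outermost probe positions of the run, half-open (`end` is the last probe
#' position + 1). Normal-state probes never form segments.
#'
#' @param states A [decode_states()] result.
#' @param track The matching [probe_track()] or [zscore_normalize()] track
#'   (probe-aligned); its value column supplies each segment's `mean_z`.
#' @param config A [run_config()].
#' @return A `cnv_segments` data frame sorted by chromosome and start.
#' @export
segments_from_states <- function(states, track, config = run_config()) {
  stopifnot(inherits(states, "state_track"))
  vals <- track_values(track)
  sp <- states$probes
  if (nrow(sp) != length(vals$value) ||
      any(sp$chrom != vals$chrom) || any(sp$pos != vals$pos))
    stop_cnv("cnv_alignment_error",
             "state track and probe track are not aligned")
  out <- list()
  for (ch in chrom_order(sp$chrom)) {
    idx <- which(sp$chrom == ch)
    st <- as.integer(sp$state[idx])      # 1 dec, 2 normal, 3 inc
    pos <- sp$pos[idx]
    runs <- rle(st)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values != 2L)) {
      ri <- idx[starts[r]:ends[r]]
      # split the run at inter-probe gaps >= merge_gap_bp
      gaps <- diff(sp$pos[ri])
      grp <- cumsum(c(0L, gaps >= config$merge_gap_bp))
      for (g in unique(grp)) {
        gi <- ri[grp == g]
        out[[length(out) + 1L]] <- data.frame(
          sample_id = states$sample_id,
          chrom = ch,
          start = sp$pos[gi[1]],
          end = sp$pos[gi[length(gi)]] + 1,
          state = if (runs$values[r] == 3L) "gain" else "loss",
          n_probes = length(gi),
          mean_z = mean(vals$value[gi]))
      }
    }
  }
  if (length(out) == 0L) return(empty_segments())
  df <- do.call(rbind, out)
  df <- df[order(match(df$chrom, chrom_order(df$chrom)), df$start), ]
  new_segments(df)
}

track_values <- function(track) {
  if (inherits(track, "zscore_track"))
    data.frame(chrom = track$probes$chrom, pos = track$probes$pos,
               value = track$probes$z)
  else if (inherits(track, "probe_track"))
    data.frame(chrom = track$probes$chrom, pos = track$probes$pos,
               value = track$probes$log2_ratio)
  else stop_cnv("cnv_value_error", "expected a probe_track or zscore_track")
}

#' Bridge nearby same-state segments into single variants
#'
#' Two same-state segments with no other segment between them are called as
#' one variant (together with the intervening probes) when the intervening
#' sequence has at most `bridge_max_probes` probes and the gap between the
#' segments' facing boundaries spans at most `bridge_max_bp`. Bridging is
#' applied iteratively until a fixed point; each individual bridge must
#' satisfy both conditions. Segments of different states are never bridged.
#'
#' @inheritParams segments_from_states
#' @param segments A `cnv_segments` data frame sorted by chromosome and
#'   start (as produced by [segments_from_states()]).
#' @return A `cnv_segments` data frame.
#' @export
bridge_segments <- function(segments, states, track, config = run_config()) {
  if (nrow(segments) < 2L) return(segments)
  ord <- order(match(segments$chrom, chrom_order(segments$chrom)),
               segments$start)
  if (!identical(ord, seq_len(nrow(segments))))
    stop_cnv("cnv_ordering_error",
             "segments must be sorted by chromosome and start")
  vals <- track_values(track)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(segments)) {
      a <- segments[i, ]
      b <- segments[i + 1L, ]
      if (a$chrom == b$chrom && a$state == b$state) {
        span <- b$start - a$end
        between <- vals$chrom == a$chrom & vals$pos >= a$end &
          vals$pos < b$start
        if (sum(between) <= config$bridge_max_probes &&
            span <= config$bridge_max_bp) {
          inside <- vals$chrom == a$chrom & vals$pos >= a$start &
            vals$pos < b$end
          segments$end[i] <- b$end
          segments$n_probes[i] <- sum(inside)
          segments$mean_z[i] <- mean(vals$value[inside])
          segments$size_mb[i] <- (b$end - a$start) / 1e6
          segments <- segments[-(i + 1L), ]
          class(segments) <- c("cnv_segments", "data.frame")
          merged <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  rownames(segments) <- NULL
  segments
}

#' Drop events with too few probes
#'
#' Retains exactly the segments supported by at least `min_probes` probes
#' (default 5, i.e. events with fewer than 5 probes are eliminated),
#' preserving order.
#'
#' @param segments A `cnv_segments` data frame.
#' @param config A [run_config()].
#' @return The filtered `cnv_segments`.
#' @export
filter_min_probes <- function(segments, config = run_config()) {
  out <- segments[segments$n_probes >= config$min_probes, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_segments", "data.frame")
  out
}

#' Remove common CNVs seen in unaffected individuals
#'
#' A call is common — and removed — when some control-catalog interval of
#' the same type (gain/loss) overlaps it reciprocally at or above
#' `common_overlap_fraction` (default 50% reciprocal overlap, the standard
#' CNV matching criterion). Surviving calls are flagged `rare = TRUE`.
#'
#' @param segments A `cnv_segments` data frame.
#' @param catalog A [control_catalog()].
#' @param config A [run_config()].
#' @return The rare `cnv_segments`.
#' @export
filter_common <- function(segments, catalog, config = run_config()) {
  stopifnot(inherits(catalog, "control_catalog"))
  if (nrow(segments) == 0L) return(segments)
  common <- rep(FALSE, nrow(segments))
  hits <- reciprocal_overlap(segments, catalog$intervals)
  if (nrow(hits) > 0) {
    same <- segments$state[hits$query] == catalog$intervals$name[hits$subject]
    ok <- same & hits$fraction >= config$common_overlap_fraction
    common[unique(hits$query[ok])] <- TRUE
  }
  out <- segments[!common, , drop = FALSE]
  out$rare <- if (nrow(out)) TRUE else logical(0)
  rownames(out) <- NULL
  class(out) <- c("cnv_segments", "data.frame")
  out
}

#' Call CNVs for one sample
#'
#' Runs the full per-sample pipeline: chromosome-wise z-scores, Viterbi
#' decoding of the three-state HMM, run-to-segment construction with the
#' 50-kb merge rule, bridging of nearby same-state segments, the minimum
#' probe-count filter and the common-CNV filter. Deterministic given the
#' inputs and configuration.
#'
#' @param track A [probe_track()].
#' @param catalog A [control_catalog()] (may be empty).
#' @param config A [run_config()].
#' @return A `cnv_segments` data frame of rare calls.
#' @export
call_sample <- function(track, catalog = NULL, config = run_config()) {
  if (is.null(catalog))
    catalog <- control_catalog(data.frame(chrom = character(),
                                          start = numeric(),
                                          end = numeric(),
                                          name = character()))
  z <- zscore_normalize(track)
  st <- decode_states(build_hmm(config), z)
  seg <- segments_from_states(st, z, config)
  seg <- bridge_segments(seg, st, z, config)
  seg <- filter_min_probes(seg, config)
  filter_common(seg, catalog, config)
}

#' @export
print.cnv_segments <- function(x, ...) {
  cat(sprintf("cnv_segments: %d call(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}
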