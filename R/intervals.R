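#' Read BED-style intervals
#'
#' Reads a tab-delimited BED-like file (no header, 0-based half-open
#' coordinates) into a data frame of genomic intervals. Input ordering is
#' preserved; chromosome names are normalized to the "chr" form.
#'
#' @param path Path to the file.
#' @param payload_column 1-based column index carrying the payload (gene
#'   name, CNV type, ...); default 4, the BED name column.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`
#'   (payload). Zero rows for an empty file.
#' @export
read_bed_intervals <- function(path, payload_column = 4L) {
  if (!file.exists(path))
    stop_cnv("cnv_io_error", "interval file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < max(3L, payload_column)))
    stop_cnv("cnv_parse_error", "%s: too few columns at line %d",
             path, which(nf < max(3L, payload_column))[1])
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                   start = suppressWarnings(
                     as.numeric(vapply(fields, `[[`, "", 2L))),
                   end = suppressWarnings(
                     as.numeric(vapply(fields, `[[`, "", 3L))),
                   name = vapply(fields, `[[`, "", payload_column))
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad))
    stop_cnv("cnv_parse_error", "%s: malformed coordinate at line %d",
             path, bad[1])
  validate_intervals(df, path)
  df$chrom <- normalize_chrom(df$chrom)
  df
}

validate_intervals <- function(df, label = "intervals") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0))
    stop_cnv("cnv_interval_error", "%s: negative coordinate", label)
  if (any(df$start >= df$end))
    stop_cnv("cnv_interval_error",
             "%s: start >= end for interval %s:%g-%g", label,
             df$chrom[df$start >= df$end][1],
             df$start[df$start >= df$end][1],
             df$end[df$start >= df$end][1])
  invisible(df)
}

#' Write BED4 intervals
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_intervals <- function(df, path) {
  out <- data.frame(df$chrom, sprintf("%d", as.integer(df$start)),
                    sprintf("%d", as.integer(df$end)), df$name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a control-CNV catalog
#'
#' Intervals of copy-number variants observed in unaffected individuals;
#' calls matching such an interval (same type, sufficient reciprocal
#' overlap) are filtered out as common.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   `name` (or `type`) whose values are `"gain"` or `"loss"`.
#' @param source_label Free-text provenance label.
#' @param n_individuals Number of control individuals the catalog reflects.
#' @return Object of class `control_catalog`.
#' @export
control_catalog <- function(intervals, source_label = "controls",
                            n_individuals = 1L) {
  if (!is.null(intervals$type) && is.null(intervals$name))
    names(intervals)[names(intervals) == "type"] <- "name"
  if (nrow(intervals) > 0) {
    validate_intervals(intervals, "control catalog")
    if (!all(intervals$name %in% c("gain", "loss")))
      stop_cnv("cnv_value_error",
               "control catalog types must be 'gain' or 'loss'")
    intervals$chrom <- normalize_chrom(intervals$chrom)
  }
  if (!is.finite(n_individuals) || n_individuals <= 0)
    stop_cnv("cnv_config_error", "n_individuals must be > 0")
  structure(list(intervals = intervals[c("chrom", "start", "end", "name")],
                 source_label = as.character(source_label),
                 n_individuals = as.integer(n_individuals)),
            class = "control_catalog")
}

#' Read a control catalog from BED4
#'
#' @param path BED4 file; name column must be `gain` or `loss`.
#' @param n_individuals Number of control individuals behind the catalog.
#' @param source_label Provenance label (default: file name).
#' @return A `control_catalog`.
#' @export
read_control_catalog <- function(path, n_individuals,
                                 source_label = basename(path)) {
  control_catalog(read_bed_intervals(path), source_label, n_individuals)
}

#' @export
print.control_catalog <- function(x, ...) {
  cat(sprintf("control_catalog '%s': %d interval(s) from %d individuals\n",
              x$source_label, nrow(x$intervals), x$n_individuals))
  invisible(x)
}

# GRanges view of a chrom/start/end data frame (0-based half-open in,
# 1-based closed inside GRanges). `levels` fixes a shared seqlevel set so
# that two views are comparable.
as_granges <- function(df, levels = chrom_order(df$chrom)) {
  GenomicRanges::GRanges(factor(df$chrom, levels = levels),
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Reciprocal overlap between two interval sets
#'
#' For every overlapping pair (one interval from `a`, one from `b`) the
#' reciprocal overlap fraction `min(w / width(a), w / width(b))` is
#' computed, where `w` is the intersection width. This is the standard CNV
#' matching criterion used by the common-CNV filter and the inheritance
#' classifier.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Data frame with columns `query` (row of `a`), `subject` (row of
#'   `b`) and `fraction`.
#' @export
reciprocal_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(query = integer(), subject = integer(),
                      fraction = numeric()))
  lev <- chrom_order(c(a$chrom, b$chrom))
  ga <- as_granges(a, lev)
  gb <- as_granges(b, lev)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(GenomicRanges::pintersect(ga[q], gb[s]))
  data.frame(query = q, subject = s,
             fraction = pmin(w / GenomicRanges::width(ga)[q],
                             w / GenomicRanges::width(gb)[s]))
}
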