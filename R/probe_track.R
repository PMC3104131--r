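#' Construct a probe track
#'
#' A probe track holds one sample's probe-level log2 ratios, grouped by
#' chromosome and sorted by position. Positions must be strictly increasing
#' within a chromosome and every ratio finite.
#'
#' @param probes A data frame with columns `chrom`, `pos` (bp) and
#'   `log2_ratio`. Chromosome names are normalized to the "chr" prefix form;
#'   rows are sorted by chromosome (natural order) and position.
#' @param sample_id Sample identifier.
#' @param genome_label Free-text label of the genome/coordinate system.
#' @return An object of class `probe_track`: a list with elements
#'   `sample_id`, `genome_label` and the validated `probes` data frame.
#' @examples
#' probe_track(data.frame(chrom = "1", pos = c(1000, 26000),
#'                        log2_ratio = c(0.1, -0.2)), "s1")
#' @export
probe_track <- function(probes, sample_id, genome_label = "synthetic") {
  need <- c("chrom", "pos", "log2_ratio")
  if (!all(need %in% names(probes)))
    stop_cnv("cnv_parse_error", "probe table must have columns %s",
             paste(need, collapse = ", "))
  probes <- data.frame(chrom = normalize_chrom(probes$chrom),
                       pos = as.numeric(probes$pos),
                       log2_ratio = as.numeric(probes$log2_ratio))
  if (nrow(probes) == 0L)
    stop_cnv("cnv_parse_error", "probe table is empty")
  if (any(!is.finite(probes$log2_ratio)))
    stop_cnv("cnv_value_error",
             "non-finite log2 ratio at probe row(s) %s",
             paste(utils::head(which(!is.finite(probes$log2_ratio)), 3),
                   collapse = ", "))
  if (any(!is.finite(probes$pos)) || any(probes$pos < 0))
    stop_cnv("cnv_value_error", "probe positions must be finite and >= 0")
  lev <- chrom_order(probes$chrom)
  probes <- probes[order(match(probes$chrom, lev), probes$pos), , drop = FALSE]
  rownames(probes) <- NULL
  dup <- duplicated(probes[c("chrom", "pos")])
  if (any(dup))
    stop_cnv("cnv_duplicate_probe_error",
             "duplicate probe position(s), e.g. %s:%d",
             probes$chrom[dup][1], probes$pos[dup][1])
  structure(list(sample_id = as.character(sample_id),
                 genome_label = as.character(genome_label),
                 probes = probes),
            class = "probe_track")
}

#' Read a probe-level log2-ratio table
#'
#' Reads a tab-delimited file with header columns `chromosome`, `position`
#' and `log2_ratio` into a [probe_track()]. Rows may appear in any order;
#' output is grouped by chromosome and sorted by position. Malformed rows,
#' non-finite ratios and duplicate (chromosome, position) pairs are errors.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample identifier; default is the file name without
#'   extension.
#' @return A `probe_track`.
#' @export
read_probe_table <- function(path, sample_id = NULL) {
  if (!file.exists(path))
    stop_cnv("cnv_io_error", "probe file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("chromosome", "position", "log2_ratio")
  if (!all(need %in% names(raw)))
    stop_cnv("cnv_parse_error",
             "%s: header must contain columns %s", path,
             paste(need, collapse = ", "))
  pos <- suppressWarnings(as.numeric(raw$position))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad))
    stop_cnv("cnv_parse_error", "%s: malformed position at line %d",
             path, bad[1] + 1L)  # +1 for the header line
  ratio <- suppressWarnings(as.numeric(raw$log2_ratio))
  bad <- which(is.na(ratio) & !(raw$log2_ratio %in% c("NaN", "Inf", "-Inf")))
  if (length(bad))
    stop_cnv("cnv_parse_error", "%s: malformed log2_ratio at line %d",
             path, bad[1] + 1L)
  ratio[raw$log2_ratio == "NaN"] <- NaN
  ratio[raw$log2_ratio == "Inf"] <- Inf
  ratio[raw$log2_ratio == "-Inf"] <- -Inf
  if (any(!is.finite(ratio)))
    stop_cnv("cnv_value_error", "%s: non-finite log2_ratio at line %d",
             path, which(!is.finite(ratio))[1] + 1L)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  probe_track(data.frame(chrom = raw$chromosome, pos = pos,
                         log2_ratio = ratio),
              sample_id = sample_id)
}

#' Write a probe track
#'
#' Inverse of [read_probe_table()]: writes the tab-delimited three-column
#' format at full double precision, so that write-then-read is the identity
#' on (chromosome, position, ratio) triples.
#'
#' @param track A `probe_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_probe_table <- function(track, path) {
  stopifnot(inherits(track, "probe_track"))
  df <- data.frame(chromosome = track$probes$chrom,
                   position = sprintf("%d", as.integer(track$probes$pos)),
                   log2_ratio = sprintf("%.17g", track$probes$log2_ratio))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.probe_track <- function(x, ...) {
  tab <- table(factor(x$probes$chrom, levels = chrom_order(x$probes$chrom)))
  cat(sprintf("probe_track '%s' (%s): %d probes on %d chromosome(s)\n",
              x$sample_id, x$genome_label, nrow(x$probes), length(tab)))
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.probe_track <- function(x, ...) x$probes
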