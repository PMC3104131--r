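#' Write CNV calls as a BED track and a report table
#'
#' Writes two files: `<stem>.bed`, a BED4 track (chromosome, start, end,
#' state) that round-trips bit-exactly through [read_calls_bed()]; and
#' `<stem>.tsv`, a report with one row per call in the style of published
#' rare-CNV tables: sample, locus string `"chrN: start-end"`, size in Mb to
#' two decimals, gene list, rarity flag, and — when an `inheritance`
#' column is present — the inheritance label (`Inh (M)`, `Inh (P)`, `Unk`).
#'
#' @param segments A `cnv_segments` data frame (may be empty).
#' @param path Output stem; `.bed` and `.tsv` are appended (a trailing
#'   `.bed` or `.tsv` is stripped first).
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_calls <- function(segments, path) {
  stem <- sub("\\.(bed|tsv)$", "", path)
  bed_path <- paste0(stem, ".bed")
  tsv_path <- paste0(stem, ".tsv")
  bed <- data.frame(chrom = segments$chrom,
                    start = sprintf("%d", as.integer(segments$start)),
                    end = sprintf("%d", as.integer(segments$end)),
                    name = segments$state)
  writeLines(c("#chrom\tstart\tend\tstate",
               if (nrow(bed)) do.call(paste, c(bed, sep = "\t"))),
             bed_path)
  report <- data.frame(
    sample = segments$sample_id,
    locus = sprintf("%s: %d-%d", segments$chrom,
                    as.integer(segments$start), as.integer(segments$end)),
    state = segments$state,
    size_mb = sprintf("%.2f", segment_size_mb(segments)),
    n_probes = segments$n_probes,
    genes = ifelse(is.na(segments$genes), "", segments$genes),
    rare = ifelse(is.na(segments$rare), "NA",
                  ifelse(segments$rare, "rare", "common")))
  if (!is.null(segments$inheritance))
    report$inheritance <- inheritance_label(segments$inheritance)
  utils::write.table(report, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read a BED call track written by [write_calls()]
#'
#' @param path Path to the `.bed` file.
#' @return Data frame with columns `chrom`, `start`, `end`, `state`.
#' @export
read_calls_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(fields, `[[`, "", 1L),
             start = as.numeric(vapply(fields, `[[`, "", 2L)),
             end = as.numeric(vapply(fields, `[[`, "", 3L)),
             state = vapply(fields, `[[`, "", 4L))
}
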