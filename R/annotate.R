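#' Gene overlap report for one segment
#'
#' Classifies each gene interval as fully contained in the segment
#' (interval entirely within the call) or partially overlapped
#' (intersection non-empty but not contained). A segment is
#' `gene_containing` when either list is non-empty; published call tables
#' conventionally mark partial overlap with "+" and full containment with
#' "++".
#'
#' @param segment A single-row `cnv_segments` data frame (or any list with
#'   `chrom`, `start`, `end`).
#' @param genes Data frame of gene intervals (`chrom`, `start`, `end`,
#'   `name`).
#' @return Object of class `gene_overlap_report`: list with the segment,
#'   `genes_fully_contained` and `genes_partially_overlapped` (each sorted
#'   lexicographically) and the `gene_containing` flag.
#' @export
annotate_genes <- function(segment, genes) {
  seg <- data.frame(chrom = segment$chrom[1], start = segment$start[1],
                    end = segment$end[1])
  full <- character(0)
  part <- character(0)
  if (nrow(genes)) {
    validate_intervals(genes, "gene annotation")
    hits <- reciprocal_overlap(seg, genes)
    if (nrow(hits)) {
      g <- genes[hits$subject, ]
      contained <- g$start >= seg$start & g$end <= seg$end
      full <- sort(unique(g$name[contained]))
      part <- sort(unique(g$name[!contained]))
    }
  }
  structure(list(segment = segment,
                 genes_fully_contained = full,
                 genes_partially_overlapped = part,
                 gene_containing = length(full) + length(part) > 0),
            class = "gene_overlap_report")
}

#' @export
print.gene_overlap_report <- function(x, ...) {
  cat(sprintf("segment %s:%g-%g — gene containing: %s\n",
              x$segment$chrom[1], x$segment$start[1], x$segment$end[1],
              x$gene_containing))
  if (length(x$genes_fully_contained))
    cat("  fully contained: ",
        paste(x$genes_fully_contained, collapse = ", "), "\n")
  if (length(x$genes_partially_overlapped))
    cat("  partially overlapped: ",
        paste(x$genes_partially_overlapped, collapse = ", "), "\n")
  invisible(x)
}

#' Annotate a call set with gene overlaps
#'
#' Fills the `genes` column (comma-separated gene symbols, "++" marking
#' full containment and "+" partial overlap) and the `gene_containing`
#' flag for every segment.
#'
#' @param segments A `cnv_segments` data frame.
#' @param genes Gene interval data frame (`chrom`, `start`, `end`, `name`).
#' @return The annotated `cnv_segments`.
#' @export
annotate_calls <- function(segments, genes) {
  if (nrow(segments) == 0L) return(segments)
  segments$genes <- ""
  segments$gene_containing <- FALSE
  if (nrow(genes) == 0L) return(segments)
  validate_intervals(genes, "gene annotation")
  hits <- reciprocal_overlap(segments, genes)
  for (i in unique(hits$query)) {
    g <- genes[hits$subject[hits$query == i], ]
    contained <- g$start >= segments$start[i] & g$end <= segments$end[i]
    lab <- c(paste0(sort(unique(g$name[contained])), "++"),
             paste0(sort(unique(g$name[!contained])), "+"))
    lab <- lab[!lab %in% c("++", "+")]
    segments$genes[i] <- paste(lab, collapse = ",")
    segments$gene_containing[i] <- TRUE
  }
  segments
}

#' Segment size in megabases
#'
#' Size is the coordinate difference `(end - start) / 1e6`; report tables
#' display it rounded to two decimals.
#'
#' @param segment A `cnv_segments` data frame (any number of rows).
#' @return Numeric vector of sizes in Mb.
#' @examples
#' segment_size_mb(data.frame(start = 93.59e6, end = 97.51e6))  # 3.92
#' @export
segment_size_mb <- function(segment) {
  (segment$end - segment$start) / 1e6
}

#' Label inheritance of child calls against one parent
#'
#' A child call is inherited from the tested parent when a same-type
#' parental call overlaps it reciprocally at or above
#' `common_overlap_fraction` — the same overlap engine and threshold as
#' the common-CNV filter. Calls with no such parental match are
#' `not_in_tested_parent`; when no parent call set is supplied every
#' verdict is `unknown`.
#'
#' @param child_calls A `cnv_segments` data frame.
#' @param parent_calls A `cnv_segments` data frame for the parent, or
#'   `NULL` when the parent was not tested.
#' @param parent_role `"maternal"` or `"paternal"`.
#' @param config A [run_config()].
#' @return The child calls with an added `inheritance` column taking values
#'   `inherited_maternal`, `inherited_paternal`, `not_in_tested_parent` or
#'   `unknown`.
#' @export
classify_inheritance <- function(child_calls, parent_calls = NULL,
                                 parent_role = c("maternal", "paternal"),
                                 config = run_config()) {
  parent_role <- match.arg(parent_role)
  if (nrow(child_calls) == 0L) {
    child_calls$inheritance <- character(0)
    return(child_calls)
  }
  if (is.null(parent_calls)) {
    child_calls$inheritance <- "unknown"
    return(child_calls)
  }
  verdict <- rep("not_in_tested_parent", nrow(child_calls))
  hits <- reciprocal_overlap(child_calls, parent_calls)
  if (nrow(hits)) {
    ok <- child_calls$state[hits$query] ==
      parent_calls$state[hits$subject] &
      hits$fraction >= config$common_overlap_fraction
    verdict[unique(hits$query[ok])] <- paste0("inherited_", parent_role)
  }
  child_calls$inheritance <- verdict
  child_calls
}

# Table-style vocabulary for inheritance verdicts ("Inh (M)", "Inh (P)",
# "Unk", "Not inh").
inheritance_label <- function(verdict) {
  vapply(verdict, function(v) switch(v,
    inherited_maternal = "Inh (M)",
    inherited_paternal = "Inh (P)",
    not_in_tested_parent = "Not inh",
    "Unk"), "")
}
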