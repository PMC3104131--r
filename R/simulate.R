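#' Specification of one synthetic aCGH track
#'
#' Emulates a whole-genome tiling array: probes on a jittered grid spaced
#' approximately every 25 kb, baseline log2 ratio 0 with i.i.d. Gaussian
#' noise, and implanted heterozygous CNVs whose mean log2 shift follows
#' ideal copy-number arithmetic `log2(copy_number / 2)` — +0.585 for a
#' three-copy duplication, -1 for a one-copy deletion.
#'
#' @param chromosome_lengths Named vector of chromosome lengths in bp
#'   (default: three 50-Mb chromosomes, a desk-scale genome).
#' @param probe_spacing_bp Mean inter-probe spacing (default 25000).
#' @param spacing_jitter_bp Uniform jitter applied to each grid position;
#'   must be below half the spacing so positions stay strictly increasing.
#' @param noise_sd_log2 Standard deviation of the probe noise in log2 units
#'   (default 0.15).
#' @param implants Data frame with columns `chrom`, `start`, `end`,
#'   `copy_number` (1 or 3); implants must lie within their chromosome and
#'   not overlap each other.
#' @param seed Integer seed; tracks are deterministic given the spec.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(chromosome_lengths = c(chr1 = 50e6, chr2 = 50e6,
                                            chr3 = 50e6),
                     probe_spacing_bp = 25000L,
                     spacing_jitter_bp = 2000L,
                     noise_sd_log2 = 0.15,
                     implants = NULL,
                     seed = 1L) {
  if (is.null(implants))
    implants <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), copy_number = integer())
  if (is.null(names(chromosome_lengths)))
    stop_cnv("cnv_spec_error", "chromosome_lengths must be named")
  names(chromosome_lengths) <- normalize_chrom(names(chromosome_lengths))
  if (noise_sd_log2 < 0)
    stop_cnv("cnv_spec_error", "noise_sd_log2 must be >= 0")
  if (spacing_jitter_bp >= probe_spacing_bp / 2)
    stop_cnv("cnv_spec_error",
             "spacing_jitter_bp must be below half the probe spacing")
  if (nrow(implants)) {
    implants$chrom <- normalize_chrom(implants$chrom)
    validate_intervals(implants, "implants")
    if (!all(implants$copy_number %in% c(1L, 3L)))
      stop_cnv("cnv_spec_error", "implant copy_number must be 1 or 3")
    if (!all(implants$chrom %in% names(chromosome_lengths)) ||
        any(implants$end > chromosome_lengths[implants$chrom]))
      stop_cnv("cnv_spec_error", "implant outside chromosome bounds")
    o <- order(implants$chrom, implants$start)
    s <- implants[o, ]
    same <- s$chrom[-1] == s$chrom[-nrow(s)]
    if (nrow(s) > 1 && any(same & s$start[-1] < s$end[-nrow(s)]))
      stop_cnv("cnv_spec_error", "implants overlap")
  }
  structure(list(chromosome_lengths = chromosome_lengths,
                 probe_spacing_bp = as.integer(probe_spacing_bp),
                 spacing_jitter_bp = as.integer(spacing_jitter_bp),
                 noise_sd_log2 = as.numeric(noise_sd_log2),
                 implants = implants,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate one probe track with known truth
#'
#' @param spec A [sim_spec()].
#' @param sample_id Sample identifier for the generated track.
#' @return List with elements `track` (a [probe_track()]) and `truth`
#'   (data frame of implanted intervals with `name` = gain/loss).
#' @export
simulate_track <- function(spec, sample_id = "sim") {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    probes <- lapply(names(spec$chromosome_lengths), function(ch) {
      len <- spec$chromosome_lengths[[ch]]
      k <- floor(len / spec$probe_spacing_bp)
      centers <- (seq_len(k) - 0.5) * spec$probe_spacing_bp
      pos <- round(centers + runif(k, -spec$spacing_jitter_bp,
                                   spec$spacing_jitter_bp))
      ratio <- rnorm(k, 0, spec$noise_sd_log2)
      imp <- spec$implants[spec$implants$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(imp))) {
        inside <- pos >= imp$start[i] & pos < imp$end[i]
        ratio[inside] <- ratio[inside] + log2(imp$copy_number[i] / 2)
      }
      data.frame(chrom = ch, pos = pos, log2_ratio = ratio)
    })
    truth <- spec$implants
    truth$name <- ifelse(truth$copy_number > 2, "gain", "loss")
    list(track = probe_track(do.call(rbind, probes), sample_id),
         truth = truth[c("chrom", "start", "end", "name")])
  })
}

#' Specification of a synthetic case cohort
#'
#' Describes a cohort in which a known subset of samples carries one rare,
#' gene-overlapping CNV absent from the control catalog, while common CNVs
#' drawn from a shared set of catalog loci segregate through the whole
#' cohort. Defaults mirror a 186-sample study with 14 rare-CNV carriers.
#'
#' @param n_samples Number of case samples (default 186).
#' @param n_rare_carriers Samples carrying one implanted rare
#'   gene-overlapping CNV (default 14).
#' @param rare_cnv_size_probes Two-element range of rare implant sizes in
#'   probes (default c(8, 60), i.e. roughly 0.2-1.5 Mb at 25-kb spacing).
#' @param n_common_cnv_loci Number of catalog (common) CNV loci (default 8).
#' @param common_carrier_fraction Probability that any sample carries each
#'   common locus (default 0.3).
#' @param gene_density Genes per Mb of synthetic genome (default 5; gene
#'   lengths are drawn uniformly between 20 and 100 kb).
#' @param seed Integer seed; the cohort is deterministic given the spec.
#' @param ... Further arguments passed to [sim_spec()] (chromosome lengths,
#'   probe spacing, noise sd, ...).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 186L, n_rare_carriers = 14L,
                        rare_cnv_size_probes = c(8L, 60L),
                        n_common_cnv_loci = 8L,
                        common_carrier_fraction = 0.3,
                        gene_density = 5,
                        seed = 1L, ...) {
  base <- sim_spec(seed = seed, ...)
  if (n_rare_carriers > n_samples)
    stop_cnv("cnv_spec_error", "n_rare_carriers exceeds n_samples")
  if (common_carrier_fraction < 0 || common_carrier_fraction > 1)
    stop_cnv("cnv_spec_error", "common_carrier_fraction must be in [0, 1]")
  if (length(rare_cnv_size_probes) != 2L ||
      rare_cnv_size_probes[1] > rare_cnv_size_probes[2] ||
      rare_cnv_size_probes[1] < 1)
    stop_cnv("cnv_spec_error", "rare_cnv_size_probes must be a valid range")
  max_len <- max(base$chromosome_lengths)
  if ((rare_cnv_size_probes[2] + 1) * base$probe_spacing_bp > max_len)
    stop_cnv("cnv_spec_error",
             "rare CNV size range exceeds chromosome length")
  structure(c(base[setdiff(names(base), "seed")],
              list(n_samples = as.integer(n_samples),
                   n_rare_carriers = as.integer(n_rare_carriers),
                   rare_cnv_size_probes = as.integer(rare_cnv_size_probes),
                   n_common_cnv_loci = as.integer(n_common_cnv_loci),
                   common_carrier_fraction = common_carrier_fraction,
                   gene_density = gene_density,
                   seed = as.integer(seed))),
            class = "cohort_spec")
}

# uniform integer start for an interval of length len on chromosome ch
runif_start <- function(len_chrom, len) round(runif(1, 0, len_chrom - len))

overlaps_any <- function(chrom, start, end, df, margin = 0) {
  if (nrow(df) == 0L) return(FALSE)
  any(df$chrom == chrom & df$start - margin < end & df$end + margin > start)
}

#' Simulate a whole case cohort with known ground truth
#'
#' Generates a synthetic gene annotation, a set of common CNV loci forming
#' the control catalog, and one probe track per sample. Exactly
#' `n_rare_carriers` samples carry one implanted rare CNV that overlaps at
#' least one gene, spans at least `rare_cnv_size_probes[1]` probes and does
#' not overlap any catalog locus; every sample may additionally carry
#' common CNVs copied from the catalog. Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `tracks` (named list of [probe_track()]), `catalog`
#'   (a [control_catalog()] of the common loci), `genes` (gene interval
#'   data frame) and `truth` (named list of rare implanted intervals per
#'   sample; zero-row for non-carriers).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  spacing <- spec$probe_spacing_bp
  with_seed(spec$seed, {
    chroms <- names(spec$chromosome_lengths)
    # synthetic gene annotation
    genes <- do.call(rbind, lapply(chroms, function(ch) {
      len <- spec$chromosome_lengths[[ch]]
      ng <- max(1L, round(spec$gene_density * len / 1e6))
      glen <- round(runif(ng, 2e4, 1e5))
      gstart <- vapply(glen, function(l) runif_start(len, l), 0)
      data.frame(chrom = ch, start = gstart, end = gstart + glen,
                 name = sprintf("G%s_%04d", sub("^chr", "", ch),
                                seq_len(ng)))
    }))
    genes <- genes[order(match(genes$chrom, chroms), genes$start), ]
    rownames(genes) <- NULL
    # common CNV loci (the control catalog), mutually non-overlapping
    loci <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), name = character(),
                       copy_number = integer())
    while (nrow(loci) < spec$n_common_cnv_loci) {
      ch <- sample(chroms, 1)
      n_pr <- sample(10:25, 1)
      len <- (n_pr + 1) * spacing
      st <- runif_start(spec$chromosome_lengths[[ch]], len)
      if (overlaps_any(ch, st, st + len, loci, margin = 4 * spacing)) next
      cn <- sample(c(1L, 3L), 1)
      loci <- rbind(loci, data.frame(
        chrom = ch, start = st, end = st + len,
        name = if (cn == 3L) "gain" else "loss", copy_number = cn))
    }
    # rare gene-overlapping implants for the carrier samples
    carrier_ids <- sort(sample.int(spec$n_samples, spec$n_rare_carriers))
    rare <- vector("list", spec$n_rare_carriers)
    for (i in seq_len(spec$n_rare_carriers)) {
      repeat {
        g <- genes[sample.int(nrow(genes), 1), ]
        n_pr <- sample(spec$rare_cnv_size_probes[1]:
                         spec$rare_cnv_size_probes[2], 1)
        len <- (n_pr + 1) * spacing
        mid <- (g$start + g$end) / 2
        st <- round(min(max(0, mid - len / 2),
                        spec$chromosome_lengths[[g$chrom]] - len))
        if (overlaps_any(g$chrom, st, st + len, loci,
                         margin = 4 * spacing)) next
        # the gene must sit inside the implant with margin for boundary
        # wobble of a couple of probes
        if (g$start < st + 2 * spacing ||
            g$end > st + len - 2 * spacing) next
        cn <- sample(c(1L, 3L), 1)
        rare[[i]] <- data.frame(chrom = g$chrom, start = st, end = st + len,
                                copy_number = cn,
                                name = if (cn == 3L) "gain" else "loss")
        break
      }
    }
    sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))
    sample_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_samples)
    tracks <- vector("list", spec$n_samples)
    truth <- vector("list", spec$n_samples)
    names(tracks) <- names(truth) <- sample_ids
    carry_common <- matrix(
      rbinom(spec$n_samples * nrow(loci), 1,
             spec$common_carrier_fraction) == 1,
      nrow = spec$n_samples)
    for (s in seq_len(spec$n_samples)) {
      imp <- loci[carry_common[s, ], c("chrom", "start", "end",
                                       "copy_number"), drop = FALSE]
      k <- match(s, carrier_ids)
      if (!is.na(k))
        imp <- rbind(imp, rare[[k]][c("chrom", "start", "end",
                                      "copy_number")])
      ss <- sim_spec(chromosome_lengths = spec$chromosome_lengths,
                     probe_spacing_bp = spec$probe_spacing_bp,
                     spacing_jitter_bp = spec$spacing_jitter_bp,
                     noise_sd_log2 = spec$noise_sd_log2,
                     implants = imp, seed = sample_seeds[s])
      tracks[[s]] <- simulate_track(ss, sample_ids[s])$track
      truth[[s]] <- if (!is.na(k))
        rare[[k]][c("chrom", "start", "end", "name")]
      else data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character())
    }
    list(tracks = tracks,
         catalog = control_catalog(loci[c("chrom", "start", "end", "name")],
                                   source_label = "synthetic-controls",
                                   n_individuals = 2493L),
         genes = genes,
         truth = truth)
  })
}
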