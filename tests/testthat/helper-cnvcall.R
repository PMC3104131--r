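# Shared fixtures and independent oracles for the cnvcall test suite.

# Build a probe_track from a bare z-like ratio vector on one chromosome,
# probes every `spacing` bp.
track_from_ratios <- function(ratios, spacing = 25000, chrom = "chr1",
                              sample_id = "t") {
  probe_track(data.frame(chrom = chrom,
                         pos = seq_along(ratios) * spacing,
                         log2_ratio = ratios), sample_id)
}

# Wrap a plain z vector (single chromosome) as a zscore_track without
# re-standardizing, so HMM inputs can be controlled exactly.
ztrack <- function(z, pos = seq_along(z) * 25000, chrom = "chr1",
                   sample_id = "t") {
  structure(list(sample_id = sample_id,
                 probes = data.frame(chrom = chrom, pos = pos, z = z),
                 stats = data.frame(chrom = chrom, mean_log2 = 0,
                                    sd_log2 = 1)),
            class = "zscore_track")
}

# State track builder aligned with a zscore_track; states given as
# integers 1 (decreased), 2 (normal), 3 (increased) or state names.
strack <- function(states, z) {
  lv <- c("decreased", "normal", "increased")
  if (is.numeric(states)) states <- lv[states]
  structure(list(sample_id = z$sample_id,
                 probes = data.frame(chrom = z$probes$chrom,
                                     pos = z$probes$pos,
                                     state = factor(states, levels = lv))),
            class = "state_track")
}

# --- exhaustive Viterbi oracle -------------------------------------------
# Enumerates all 3^n state paths and scores them directly from the model
# definition; independent of the package's dynamic-programming decoder.
.path_cache <- new.env(parent = emptyenv())

all_paths <- function(n) {
  key <- as.character(n)
  if (is.null(.path_cache[[key]]))
    .path_cache[[key]] <- as.matrix(expand.grid(rep(list(1:3), n)))
  .path_cache[[key]]
}

enum_best_paths <- function(z, model, tol = 1e-9) {
  n <- length(z)
  paths <- all_paths(n)
  lemis <- vapply(1:3, function(k)
    dnorm(z, model$emission_means[k], model$emission_sds[k], log = TRUE),
    numeric(n))  # n x 3
  ltrans <- log(model$transition)
  lp <- log(model$initial)[paths[, 1]] + lemis[cbind(1L, paths[, 1])]
  if (n > 1) for (t in 2:n) {
    lp <- lp + lemis[cbind(t, paths[, t])] +
      ltrans[cbind(paths[, t - 1], paths[, t])]
  }
  best <- max(lp)
  list(best = best, paths = paths[lp >= best - tol, , drop = FALSE])
}

# --- brute-force Fisher oracle -------------------------------------------
# Sums binomial-coefficient table probabilities directly; independent of
# dhyper and of stats::fisher.test.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  tab_prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(support, tab_prob, 0)
  sum(probs[probs <= tab_prob(a) * (1 + 1e-7)])
}

# --- published rare-CNV call table ---------------------------------------
# Coordinates (Mb) and printed sizes of the 14 reported rare CNVs; the two
# 6p21 rows and the SAG02 row print sizes inconsistent with their own
# coordinates and are flagged.
table1_calls <- function() {
  df <- read.table(header = TRUE, text = "
sample  chrom start_mb end_mb state printed_mb consistent
4038    chr9    93.59  97.51 loss  3.92 TRUE
1056    chr3    11.96  15.30 gain  3.34 TRUE
2082    chr5     7.59  10.06 gain  2.47 TRUE
1061    chr1   239.34 240.99 gain  1.65 TRUE
1007    chr6    44.99  46.12 gain  1.10 FALSE
1019    chr6    44.99  46.12 gain  1.10 FALSE
2076    chr2   115.97 116.70 gain  0.73 TRUE
1012    chr17   78.05  78.65 loss  0.60 TRUE
1063    chr6   162.84 163.46 loss  0.62 TRUE
2003    chr11  130.22 130.67 gain  0.45 TRUE
1020    chr2    45.75  46.15 gain  0.40 TRUE
2024    chr7   158.17 158.33 loss  0.16 TRUE
4033    chr12   18.12  18.20 loss  0.08 TRUE
SAG02   chr9    74.25  74.60 loss  0.04 FALSE
", colClasses = c(sample = "character"))
  data.frame(sample_id = df$sample, chrom = df$chrom,
             start = df$start_mb * 1e6, end = df$end_mb * 1e6,
             state = df$state, n_probes = NA_integer_, mean_z = NA_real_,
             size_mb = (df$end_mb - df$start_mb) * 1e6 / 1e6,
             genes = NA_character_, gene_containing = TRUE, rare = TRUE,
             printed_mb = df$printed_mb, consistent = df$consistent)
}

# Per-sample call list from the published table (one call per sample).
table1_cohort <- function() {
  t1 <- table1_calls()
  split(t1, t1$sample_id)
}

# Run the full pipeline + annotation on a simulated cohort.
run_cohort <- function(cohort, config = run_config()) {
  lapply(cohort$tracks, function(tr)
    annotate_calls(call_sample(tr, cohort$catalog, config), cohort$genes))
}
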