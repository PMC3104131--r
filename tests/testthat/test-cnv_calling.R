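test_that("z-scores use chromosome-specific mean and sample sd", {
  tr <- track_from_ratios(c(1, 2, 3))
  expect_equal(zscore_normalize(tr)$probes$z, c(-1, 0, 1))

  # per-chromosome centering: different chromosome means vanish
  tr2 <- probe_track(data.frame(
    chrom = rep(c("chr1", "chr2"), each = 50),
    pos = rep(seq_len(50) * 25000, 2),
    log2_ratio = c(rnorm(50, 5, 0.1), rnorm(50, -3, 0.2))), "t")
  z <- zscore_normalize(tr2)
  for (ch in c("chr1", "chr2")) {
    zi <- z$probes$z[z$probes$chrom == ch]
    expect_lt(abs(mean(zi)), 1e-9)
    expect_lt(abs(sd(zi) - 1), 1e-9)
  }
  # stored stats reproduce the transform to numerical precision
  m <- z$stats$mean_log2[z$stats$chrom == "chr1"]
  s <- z$stats$sd_log2[z$stats$chrom == "chr1"]
  expect_equal(z$probes$z[z$probes$chrom == "chr1"],
               (tr2$probes$log2_ratio[tr2$probes$chrom == "chr1"] - m) / s,
               tolerance = 1e-12)

  expect_error(zscore_normalize(track_from_ratios(rep(0.7, 5))),
               class = "cnv_degenerate_variance_error")
  expect_error(zscore_normalize(track_from_ratios(0.2)),
               class = "cnv_insufficient_data_error")
})

test_that("the HMM is built to specification", {
  m <- build_hmm(run_config())
  expect_equal(m$emission_means, c(-2, 0, 2))
  expect_equal(m$emission_sds, c(1, 1, 1))
  expect_equal(unname(diag(m$transition)),
               rep(run_config()$state_self_transition, 3))
  expect_true(all(abs(rowSums(m$transition) - 1) < 1e-12))
  expect_equal(sum(m$initial), 1, tolerance = 1e-12)
  expect_equal(build_hmm(run_config(emission_mean_shift = 3))$emission_means,
               c(-3, 0, 3))
  expect_error(build_hmm(run_config(state_self_transition = 1.0)),
               class = "cnv_config_error")
})

test_that("Viterbi decoding recovers forced paths", {
  model <- build_hmm(run_config())
  expect_equal(as.character(decode_states(model, ztrack(rep(0, 6)))
                            $probes$state), rep("normal", 6))
  st <- decode_states(model, ztrack(c(rep(3, 5), rep(0, 5))))$probes$state
  expect_equal(as.character(st), rep(c("increased", "normal"), each = 5))
  st <- decode_states(model, ztrack(rep(-3, 8)))$probes$state
  expect_equal(as.character(st), rep("decreased", 8))
})

test_that("Viterbi equals exhaustive path enumeration on short tracks", {
  model <- build_hmm(run_config())
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:9, 1)
    z <- rnorm(n, sample(c(-2, 0, 2), 1), 1.5)
    dec <- as.integer(decode_states(model, ztrack(z))$probes$state)
    oracle <- enum_best_paths(z, model)
    if (nrow(oracle$paths) == 1L) {
      expect_equal(dec, unname(oracle$paths[1, ]))
    } else {
      expect_true(any(apply(oracle$paths, 1,
                            function(p) identical(unname(p), dec))))
    }
  }
})

test_that("decoding is independent across chromosomes", {
  model <- build_hmm(run_config())
  z1 <- ztrack(c(3, 3, 3, 3, 3, 3))
  z2 <- ztrack(rep(0, 4), chrom = "chr2")
  zc <- structure(list(sample_id = "t",
                       probes = rbind(z1$probes, z2$probes),
                       stats = rbind(z1$stats, z2$stats)),
                  class = "zscore_track")
  st <- decode_states(model, zc)$probes
  expect_equal(as.character(st$state[st$chrom == "chr1"]),
               as.character(decode_states(model, z1)$probes$state))
  expect_equal(as.character(st$state[st$chrom == "chr2"]),
               as.character(decode_states(model, z2)$probes$state))
})

test_that("long tracks decode without underflow", {
  model <- build_hmm(run_config())
  set.seed(5)
  z <- ztrack(rnorm(1e5), pos = seq_len(1e5) * 25000)
  st <- decode_states(model, z)
  expect_equal(nrow(st$probes), 1e5)
  expect_true(all(!is.na(st$probes$state)))
})

test_that("runs become segments and split at the 50-kb gap rule", {
  cfg <- run_config()
  # gaps 20 kb and 80 kb: second gap splits the run
  z <- ztrack(c(5, 5, 5), pos = c(100000, 120000, 200000))
  st <- strack(c(3, 3, 3), z)
  seg <- segments_from_states(st, z, cfg)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$n_probes, c(2L, 1L))
  expect_equal(seg$start, c(100000, 200000))
  expect_equal(seg$end, c(120001, 200001))
  expect_equal(seg$state, c("gain", "gain"))

  # gap of exactly 50 kb splits (merge rule is strict "< 50 kb")
  z <- ztrack(c(5, 5), pos = c(0, 50000))
  seg <- segments_from_states(strack(c(3, 3), z), z, cfg)
  expect_equal(nrow(seg), 2L)
  z <- ztrack(c(5, 5), pos = c(0, 49999))
  expect_equal(nrow(segments_from_states(strack(c(3, 3), z), z, cfg)), 1L)

  # single decreased probe flanked by normals -> one 1-probe loss segment
  z <- ztrack(c(0, -5, 0))
  seg <- segments_from_states(strack(c(2, 1, 2), z), z, cfg)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$state, "loss")
  expect_equal(seg$n_probes, 1L)
  expect_equal(seg$end - seg$start, 1)

  # normal probes never form segments
  z <- ztrack(rep(0, 10))
  expect_equal(nrow(segments_from_states(strack(rep(2, 10), z), z, cfg)), 0L)

  # misaligned state track is rejected
  z2 <- ztrack(rep(0, 9))
  expect_error(segments_from_states(strack(rep(2, 10), z), z2, cfg),
               class = "cnv_alignment_error")
})

test_that("bridging obeys both the probe-count and span conditions", {
  cfg <- run_config()
  mkcase <- function(n_between, span_bp, state2 = 3) {
    # two 5-probe gain runs separated by n_between intervening probes
    # spread across span_bp
    pos1 <- seq_len(5) * 1000
    gap_pos <- if (n_between > 0)
      pos1[5] + round(seq_len(n_between) * span_bp / (n_between + 1))
    else numeric(0)
    pos2 <- pos1[5] + span_bp + seq_len(5) * 1000
    z <- ztrack(c(rep(5, 5), rep(0, n_between), rep(5, 5)),
                pos = c(pos1, gap_pos, pos2))
    st <- strack(c(rep(3, 5), rep(2, n_between), rep(state2, 5)), z)
    list(z = z, st = st,
         seg = segments_from_states(st, z, cfg))
  }
  # 3 intervening probes across 8 kb -> one merged segment with all probes
  cs <- mkcase(3, 8000)
  out <- bridge_segments(cs$seg, cs$st, cs$z, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_probes, 13L)
  # 6 intervening probes across 8 kb -> probe condition violated
  cs <- mkcase(6, 8000)
  expect_equal(nrow(bridge_segments(cs$seg, cs$st, cs$z, cfg)), 2L)
  # 4 intervening probes across 12 kb -> span condition violated
  cs <- mkcase(4, 12000)
  expect_equal(nrow(bridge_segments(cs$seg, cs$st, cs$z, cfg)), 2L)
  # different states never bridge
  cs <- mkcase(3, 8000, state2 = 1)
  expect_equal(nrow(bridge_segments(cs$seg, cs$st, cs$z, cfg)), 2L)
  # unsorted input is rejected
  cs <- mkcase(3, 8000)
  expect_error(bridge_segments(cs$seg[2:1, ], cs$st, cs$z, cfg),
               class = "cnv_ordering_error")
})

test_that("bridging iterates to a fixed point across chained segments", {
  cfg <- run_config()
  # three 5-probe gain runs, each pair separated by 2 normal probes
  # across 6 kb: the first bridge enables the second
  unit <- function(off) off + seq_len(5) * 1000
  pos <- c(unit(0), 5000 + c(2000, 4000), unit(11000),
           16000 + c(2000, 4000), unit(22000))
  state <- c(rep(3, 5), 2, 2, rep(3, 5), 2, 2, rep(3, 5))
  z <- ztrack(ifelse(state == 3, 5, 0), pos = pos)
  st <- strack(state, z)
  seg <- segments_from_states(st, z, cfg)
  expect_equal(nrow(seg), 3L)
  out <- bridge_segments(seg, st, z, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_probes, 19L)
  expect_equal(out$start, 1000)
  expect_equal(out$end, 27001)
})

test_that("the minimum-probe filter keeps exactly the supported events", {
  cfg <- run_config()
  seg <- cnvcall:::new_segments(data.frame(
    sample_id = "t", chrom = "chr1",
    start = c(0, 1e6, 2e6), end = c(0.5e6, 1.5e6, 2.5e6),
    state = "gain", n_probes = c(4L, 5L, 12L), mean_z = 3))
  out <- filter_min_probes(seg, cfg)
  expect_equal(out$n_probes, c(5L, 12L))
  expect_equal(nrow(filter_min_probes(seg[0, ], cfg)), 0L)
  expect_equal(filter_min_probes(seg, run_config(min_probes = 1))$n_probes,
               seg$n_probes)
})

test_that("the common filter removes same-type reciprocal-overlap matches", {
  cfg <- run_config()
  seg <- cnvcall:::new_segments(data.frame(
    sample_id = "t", chrom = "chr1",
    start = c(1e6, 5e6, 9e6), end = c(2e6, 6e6, 10e6),
    state = c("gain", "gain", "loss"), n_probes = 40L, mean_z = 3))
  catalog <- control_catalog(data.frame(
    chrom = "chr1", start = c(1e6, 9e6), end = c(2e6, 10e6),
    name = c("gain", "gain")), n_individuals = 100)
  out <- filter_common(seg, catalog, cfg)
  # identical gain interval removed; loss at gain locus kept; no-overlap kept
  expect_equal(out$start, c(5e6, 9e6))
  expect_true(all(out$rare))

  # 40% reciprocal overlap at threshold 0.5 -> retained
  seg40 <- cnvcall:::new_segments(data.frame(
    sample_id = "t", chrom = "chr1", start = 0, end = 1e6,
    state = "gain", n_probes = 40L, mean_z = 3))
  cat40 <- control_catalog(data.frame(chrom = "chr1", start = 6e5,
                                      end = 16e5, name = "gain"))
  # overlap 4e5; fractions 0.4 and 0.4 -> below threshold
  expect_equal(nrow(filter_common(seg40, cat40, cfg)), 1L)
  # raise overlap to 50% reciprocal -> removed
  cat50 <- control_catalog(data.frame(chrom = "chr1", start = 5e5,
                                      end = 15e5, name = "gain"))
  expect_equal(nrow(filter_common(seg40, cat50, cfg)), 0L)
})

test_that("call_sample composes the stages end to end", {
  # noise-free synthetic track with one 10-probe duplication
  ss <- sim_spec(chromosome_lengths = c(chr1 = 25e6), noise_sd_log2 = 0,
                 implants = data.frame(chrom = "chr1", start = 10e6,
                                       end = 10.26e6, copy_number = 3),
                 seed = 9)
  sim <- simulate_track(ss)
  inside <- sim$track$probes$pos >= 10e6 & sim$track$probes$pos < 10.26e6
  calls <- call_sample(sim$track)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$state, "gain")
  expect_equal(calls$start, min(sim$track$probes$pos[inside]))
  expect_equal(calls$end, max(sim$track$probes$pos[inside]) + 1)
  expect_equal(calls$n_probes, sum(inside))

  # catalog containing that interval as a gain -> zero calls
  catalog <- control_catalog(data.frame(chrom = "chr1", start = 10e6,
                                        end = 10.26e6, name = "gain"))
  expect_equal(nrow(call_sample(sim$track, catalog)), 0L)
  # ... but as a loss the event stays (type-matched filtering)
  cat_loss <- control_catalog(data.frame(chrom = "chr1", start = 10e6,
                                         end = 10.26e6, name = "loss"))
  expect_equal(nrow(call_sample(sim$track, cat_loss)), 1L)

  # near-flat track: all-normal path, zero calls
  tr <- track_from_ratios(rep(c(0, 1e-7), 500))
  expect_equal(nrow(call_sample(tr)), 0L)
})

test_that("calls are invariant to chromosome-wide shifts of the ratios", {
  ss <- sim_spec(chromosome_lengths = c(chr1 = 25e6),
                 implants = data.frame(chrom = "chr1", start = 12e6,
                                       end = 12.3e6, copy_number = 1),
                 seed = 13)
  tr <- simulate_track(ss)$track
  shifted <- tr
  shifted$probes$log2_ratio <- shifted$probes$log2_ratio + 0.8
  expect_equal(call_sample(shifted)[c("chrom", "start", "end", "state")],
               call_sample(tr)[c("chrom", "start", "end", "state")])
})

test_that("loosening merge thresholds never increases the call count", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 400
    pos <- cumsum(sample(c(2000, 20000, 60000), n, TRUE,
                         prob = c(0.3, 0.5, 0.2)))
    z <- rnorm(n) + sample(c(0, 3), n, TRUE, prob = c(0.9, 0.1))
    zt <- ztrack(z, pos = pos)
    st <- decode_states(build_hmm(run_config()), zt)
    count <- function(gap, bridge) {
      cfg <- run_config(merge_gap_bp = gap, bridge_max_bp = bridge)
      seg <- segments_from_states(st, zt, cfg)
      nrow(bridge_segments(seg, st, zt, cfg))
    }
    expect_gte(count(30000, 10000), count(50000, 10000))
    expect_gte(count(50000, 10000), count(50000, 30000))
    expect_gte(count(30000, 5000), count(60000, 40000))
  }
})

test_that("surviving segments satisfy both filter invariants", {
  cs <- cohort_spec(n_samples = 8, n_rare_carriers = 4, seed = 21)
  cohort <- simulate_cohort(cs)
  cfg <- run_config()
  for (tr in cohort$tracks) {
    calls <- call_sample(tr, cohort$catalog, cfg)
    if (nrow(calls) == 0L) next
    expect_true(all(calls$n_probes >= cfg$min_probes))
    hits <- reciprocal_overlap(calls, cohort$catalog$intervals)
    same <- calls$state[hits$query] ==
      cohort$catalog$intervals$name[hits$subject]
    expect_true(all(hits$fraction[same] < cfg$common_overlap_fraction))
  }
})
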