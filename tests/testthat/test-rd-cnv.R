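# Read-depth CNV discovery: binning, GC correction, neutral statistics,
# segmentation and calling.

test_that("bin_depth counts alignment starts and propagates uniqueness", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 500), collapse = "")))   # 2 kb
  ## one start per bp over bins 1..10
  reads <- lapply(1:1000, function(i) make_read(paste0("r", i), i, "10M"))
  aln <- do.call(make_aln, c(reads, list(seq_lengths = c(chr1 = 2000L))))
  sig <- bin_depth(aln, ref, 100L)
  expect_equal(nrow(sig), 20L)
  expect_equal(sig$raw_depth[1:10], rep(100, 10))
  expect_equal(sig$raw_depth[11:20], rep(0, 10))
  ## bins tile the sequence without gaps
  expect_equal(sig$first, seq(1L, 1901L, by = 100L))
  expect_equal(sig$last, seq(100L, 2000L, by = 100L))

  ## no reads -> all zeros
  sig0 <- bin_depth(aln[0], ref, 100L)
  expect_true(all(sig0$raw_depth == 0))

  ## a multiple-alignment read overlapping bin 7 marks it non-unique
  multi <- make_aln(make_read("m", 650L, "10M", mapq = 0L, nh = 2L),
                    seq_lengths = c(chr1 = 2000L))
  sigm <- bin_depth(multi, ref, 100L)
  expect_false(sigm$is_unique[7])
  expect_true(all(sigm$is_unique[-7]))

  expect_error(bin_depth(make_aln(make_read("x", 1, rname = "chrX"),
                                  seq_lengths = c(chrX = 100L)), ref),
               "missing from the reference")
})

test_that("GC correction rescales classes by m_global/m_gc", {
  ## all bins same GC -> corrected == raw
  sig <- depth_signal(rpois(500, 30), gc = 40L)
  out <- gc_correct(sig)
  expect_equal(out$corrected_depth, out$raw_depth)

  ## GC-40 class mean 20, global mean 25 -> scaled by 1.25
  depths <- c(rep(20, 200), rep(30, 200))
  sig2 <- depth_signal(depths, gc = c(rep(40L, 200), rep(50L, 200)))
  out2 <- gc_correct(sig2, min_class_bins = 100L)
  expect_equal(out2[gc_percent == 40L, corrected_depth],
               rep(20 * 25 / 20, 200))
  expect_equal(out2[gc_percent == 50L, corrected_depth],
               rep(30 * 25 / 30, 200))
  ## total depth preserved within 0.5% on balanced classes
  expect_lt(abs(sum(out2$corrected_depth) / sum(sig2$raw_depth) - 1),
            0.005)

  ## sparse classes (< min bins) left uncorrected
  sig3 <- depth_signal(c(rep(10, 10), rep(30, 300)),
                       gc = c(rep(20L, 10), rep(45L, 300)))
  out3 <- gc_correct(sig3, min_class_bins = 100L)
  expect_equal(out3[gc_percent == 20L, corrected_depth], rep(10, 10))

  ## after correction of a GC-biased fixture, depth~GC slope is ~0
  set.seed(9)
  gc <- rep(30:59, each = 100)
  bias <- 1 + 0.01 * (gc - 45)
  d <- rpois(length(gc), 30 * bias)
  sigb <- depth_signal(d, gc = as.integer(gc))
  outb <- gc_correct(sigb, min_class_bins = 50L)
  fit0 <- coef(lm(raw_depth ~ gc_percent, data = sigb))[2]
  fit1 <- coef(lm(corrected_depth ~ gc_percent, data = outb))[2]
  expect_gt(abs(fit0), 0.2)
  expect_lt(abs(fit1), 0.02)
})

test_that("neutral statistics use unique bins only", {
  sig <- depth_signal(c(rep(50, 100), rep(500, 20)),
                      unique_bins = c(rep(TRUE, 100), rep(FALSE, 20)))
  ns <- neutral_stats(sig)
  expect_equal(ns$mu, 50)
  expect_equal(ns$sigma, 0)

  sig2 <- depth_signal(rep(c(40, 60), 50))
  ns2 <- neutral_stats(sig2)
  expect_equal(ns2$mu, 50)
  expect_equal(ns2$sigma, 10)   # population sd

  expect_error(neutral_stats(depth_signal(rep(30, 10))), "30 unique bins")
})

test_that("segmentation recovers piecewise-constant structure", {
  ## constant signal -> one segment per sequence
  set.seed(4)
  sig <- depth_signal(rpois(300, 30))
  seg <- segment_depth(sig)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_bins, 300L)

  ## 50 | 150 | 50 blocks of 50 bins -> 3 segments within +-2 bins
  d <- c(rnorm(50, 50, 3), rnorm(50, 150, 3), rnorm(50, 50, 3))
  sig2 <- depth_signal(d)
  ns <- neutral_stats(sig2)
  seg2 <- segment_depth(sig2, ns$mu, ns$sigma)
  expect_equal(nrow(seg2), 3L)
  expect_lte(abs(seg2$end_bin[1] - 50L), 2L)
  expect_lte(abs(seg2$end_bin[2] - 100L), 2L)
  ## segments tile the signal
  expect_equal(sum(seg2$n_bins), 150L)
  expect_equal(seg2$start_bin[-1], seg2$end_bin[-3] + 1L)
})

test_that("segmentation equals the exhaustive minimal-variance partition", {
  set.seed(21)
  for (rep in 1:60) {
    k <- sample(1:3, 1)
    n <- sample(10:20, 1)
    ## true segments at least 3 bins long (single-bin events are below the
    ## caller's stated resolution)
    repeat {
      bounds_true <- if (k > 1) sort(sample(3:(n - 3), k - 1)) else
        integer(0)
      if (k < 3 || diff(bounds_true) >= 3) break
    }
    means <- 50 + 100 * sample(seq_len(k))
    starts <- c(1L, bounds_true + 1L); ends <- c(bounds_true, n)
    x <- unlist(lapply(seq_len(k), function(i)
      rnorm(ends[i] - starts[i] + 1L, means[i], 3)))
    ## sigma is the neutral (within-segment) noise scale, as neutral_stats
    ## would report on a genome where events are sparse
    seg <- segment_depth(sig = depth_signal(x), mu = mean(x), sigma = 3)
    got <- if (nrow(seg) > 1) seg$end_bin[-nrow(seg)] else integer(0)
    expect_equal(got, oracle_best_partition(x, k),
                 info = sprintf("rep %d k %d n %d", rep, k, n))
  }
})

test_that("call_cnvs detects implanted events and respects alpha", {
  set.seed(5)
  ## 400 neutral bins with a 40-bin duplication and a 40-bin deep deletion
  d <- rpois(400, 30)
  d[101:140] <- rpois(40, 45)   # 3 copies
  d[301:340] <- rpois(40, 1)    # ~0 copies
  sig <- depth_signal(d)
  cnv <- discover_cnvs(sig, min_class_bins = 1000L)
  expect_equal(nrow(cnv), 2L)
  dup <- cnv[type == "DUP"]
  del <- cnv[type == "DEL"]
  expect_equal(dup$copies, 3, tolerance = 0.2)
  expect_lte(del$copies, 0.5)
  expect_lte(abs(dup$first - 10001) / 100, 2)
  expect_lte(abs(del$last - 34000) / 100, 2)

  expect_error(call_cnvs(sig, segment_depth(sig), 30, 5, alpha = 2),
               "alpha")
})

test_that("single-bin segments are never called", {
  sig <- depth_signal(c(rep(30, 50), 300, rep(30, 49)))
  seg <- segment_depth(sig, 30, sqrt(30))
  calls <- call_cnvs(sig, seg, 30, sqrt(30))
  expect_equal(nrow(calls), 0L)
})

test_that("neutral-gap merging only keeps significant merged regions", {
  ## two 20-bin duplications separated by a 5-bin neutral gap merge
  d <- c(rep(30, 50), rep(60, 20), rep(30, 5), rep(60, 20), rep(30, 50))
  sig <- depth_signal(d)
  seg <- segment_depth(sig, 30, 2)
  calls <- call_cnvs(sig, seg, 30, 2)
  expect_equal(nrow(calls[type == "DUP"]), 1L)
  expect_equal(calls[type == "DUP", n_bins], 45L)

  ## a wide gap (>= half the shorter call) prevents merging
  d2 <- c(rep(30, 50), rep(60, 20), rep(30, 15), rep(60, 20), rep(30, 50))
  sig2 <- depth_signal(d2)
  calls2 <- call_cnvs(sig2, segment_depth(sig2, 30, 2), 30, 2)
  expect_equal(nrow(calls2[type == "DUP"]), 2L)
})

test_that("Gaussian second pass adds deep deletions without overriding", {
  ## a 4-bin deep deletion: too short for the standard pass after merging
  ## into the background, but caught by the mu - 3 sigma run rule
  set.seed(8)
  d <- rpois(300, 30)
  d[101:104] <- 0
  sig <- depth_signal(d)
  ns <- neutral_stats(sig)
  seg <- data.table(rname = "chr1", start_bin = 1L, end_bin = 300L,
                    first = 1L, last = 30000L, n_bins = 300L,
                    seg_mean = mean(d), frozen = FALSE)
  calls <- call_cnvs(sig, seg, ns$mu, ns$sigma)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "DEL")
  expect_equal(calls$first, 10001L)
  expect_equal(calls$last, 10400L)
})

test_that("false-call rate on null signals stays within alpha per segment", {
  alpha <- 0.05
  n_false <- 0L; n_seg <- 0L
  for (rep in 1:30) {
    sig <- null_rd_signal(1000, 30, seed = 100 + rep)
    ns <- neutral_stats(sig)
    seg <- segment_depth(sig, ns$mu, ns$sigma)
    calls <- call_cnvs(sig, seg, ns$mu, ns$sigma, alpha = alpha)
    n_false <- n_false + nrow(calls)
    n_seg <- n_seg + nrow(seg)
  }
  ## binomial bound with 3 MC standard deviations of slack
  bound <- alpha * n_seg + 3 * sqrt(alpha * n_seg)
  expect_lte(n_false, bound)
})

test_that("strategy report quantifies repeat-region calls per strategy", {
  truth <- data.table(rname = "chr1", first = 10001L, last = 14000L)
  base <- rpois(400, 30)
  dup <- base; dup[101:140] <- rpois(40, 60)
  del <- base; del[101:140] <- rpois(40, 2)
  sigs <- list(all = depth_signal(dup), best = depth_signal(del))
  rep_ <- multi_alignment_strategy_report(sigs, truth,
                                          alpha = 0.05)
  expect_equal(rep_[strategy == "all", frac_dup], 1, tolerance = 0.11)
  expect_equal(rep_[strategy == "best", frac_del], 1, tolerance = 0.11)

  ## identical signals -> identical fractions
  sigs2 <- list(a = depth_signal(dup), b = depth_signal(dup))
  r2 <- multi_alignment_strategy_report(sigs2, truth)
  expect_equal(r2[strategy == "a", .(frac_dup, frac_del, frac_neutral)],
               r2[strategy == "b", .(frac_dup, frac_del, frac_neutral)])
})
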