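# SAM input/output, read-level filters and pileup construction.

test_that("SAM round trip preserves records and validates sorting", {
  aln <- make_aln(
    make_read("a", 10L), make_read("b", 10L), make_read("c", 42L),
    seq_lengths = c(chr1 = 1000L))
  p <- tempfile(fileext = ".sam")
  write_sam(aln, p)
  back <- read_alignments(p)
  expect_equal(nrow(back), 3L)
  expect_equal(back$pos, c(10L, 10L, 42L))
  expect_equal(back$qname, c("a", "b", "c"))
  expect_equal(attr(back, "seq_lengths"), c(chr1 = 1000L))

  ## empty file -> empty table
  p2 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:1000"), p2)
  expect_equal(nrow(read_alignments(p2)), 0L)

  ## unsorted input is a hard error naming the offender
  p3 <- tempfile(fileext = ".sam")
  lines <- readLines(p)
  writeLines(c(lines[1:2], lines[5], lines[3:4]), p3)   # 42 before 10
  expect_error(read_alignments(p3), "not coordinate-sorted")
})

test_that("secondary and low-MAPQ filtering follows the stream rules", {
  aln <- make_aln(
    make_read("a", 10L), make_read("b", 20L),
    make_read("c", 30L, flag = 256L, nh = 2L),
    make_read("d", 40L, flag = 256L, nh = 2L),
    make_read("e", 50L))
  p <- tempfile(fileext = ".sam")
  write_sam(aln, p)
  expect_equal(nrow(read_alignments(p, include_secondary = TRUE)), 5L)
  expect_equal(nrow(read_alignments(p, include_secondary = FALSE)), 3L)

  ## below-MAPQ records survive only when flagged multiple
  aln2 <- make_aln(
    make_read("a", 10L, mapq = 60L),
    make_read("b", 20L, mapq = 5L),           # low MAPQ, single placement
    make_read("c", 30L, mapq = 0L, nh = 2L))  # ambiguous, NH=2
  p2 <- tempfile(fileext = ".sam")
  write_sam(aln2, p2)
  kept <- read_alignments(p2, min_mapping_quality = 10L)
  expect_equal(sort(kept$qname), c("a", "c"))
  expect_true(kept[qname == "c", multiple])
})

test_that("cap_start_duplicates keeps the first max_per_start per key", {
  stack <- make_aln(
    make_read("a", 100L), make_read("b", 100L), make_read("c", 100L),
    make_read("d", 100L), make_read("e", 100L))
  out <- cap_start_duplicates(stack, 2L)
  expect_equal(out$qname, c("a", "b"))

  ## orientation is part of the key
  mixed <- make_aln(
    make_read("a", 100L), make_read("b", 100L),
    make_read("c", 100L, flag = 16L))
  expect_equal(nrow(cap_start_duplicates(mixed, 2L)), 3L)

  ## single read and distinct starts untouched; idempotence
  one <- make_aln(make_read("a", 5L))
  expect_equal(cap_start_duplicates(one, 2L)$qname, "a")
  distinct <- make_aln(make_read("a", 1L), make_read("b", 2L),
                       make_read("c", 3L))
  expect_equal(nrow(cap_start_duplicates(distinct, 1L)), 3L)
  once <- cap_start_duplicates(stack, 2L)
  expect_equal(cap_start_duplicates(once, 2L), once)

  expect_error(cap_start_duplicates(stack, 0L), "max_per_start")
})

test_that("cap_base_quality equalises large scores to the threshold", {
  expect_equal(cap_base_quality(40, 30), 30)
  expect_equal(cap_base_quality(20, 30), 20)
  expect_equal(cap_base_quality(30, 30), 30)
  expect_equal(cap_base_quality(c(10, 35, 93), 30), c(10, 30, 30))
})

test_that("build_pileups applies 3'-end trimming per sequencing cycle", {
  one <- make_aln(make_read("a", 1L, "10M"))
  pile <- build_pileups(one, ignore_last_n = 4L)
  expect_equal(sort(pile$obs$pos), 1:6)
  pile0 <- build_pileups(one, ignore_last_n = 0L)
  expect_equal(sort(pile0$obs$pos), 1:10)

  ## reverse-strand read: machine cycles run right-to-left on the genome
  rev <- make_aln(make_read("a", 1L, "10M", flag = 16L))
  piler <- build_pileups(rev, ignore_last_n = 4L)
  expect_equal(sort(piler$obs$pos), 5:10)
})

test_that("build_pileups extracts indel events at their start column", {
  del <- make_aln(make_read("a", 11L, "5M2D5M"))
  pile <- build_pileups(del)
  expect_equal(pile$indels$pos, 16L)     # column after the 5th M
  expect_equal(pile$indels$type, "DEL")
  expect_equal(pile$indels$len, 2L)
  expect_equal(sort(pile$obs$pos), c(11:15, 18:22))

  ins <- make_aln(make_read("a", 11L, "5M3I4M",
                            seq = "AAAAATTTCCCC"))
  pi <- build_pileups(ins)
  expect_equal(pi$indels$pos, 16L)
  expect_equal(pi$indels$type, "INS")
  expect_equal(pi$indels$allele, "TTT")

  ## CIGAR inconsistent with read length -> record skipped with warning
  bad <- make_aln(make_read("a", 1L, "20M", seq = "AAAA"))
  expect_warning(pb <- build_pileups(bad), "mismatch")
  expect_equal(nrow(pb$obs), 0L)
})

test_that("pileups agree with a brute-force per-site recount", {
  fx <- small_fixture()
  sub <- fx$aln[pos >= 5000 & end_pos <= 7000]
  sub <- sub[seq_len(min(.N, 50L))]
  pile <- build_pileups(sub, ignore_last_n = 3L, q_max = 25L)
  ## brute force: walk every read base by base
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(sub))) {
    parsed <- vardiscover:::parse_cigar(sub$cigar[i])[[1]]
    b <- vardiscover:::cigar_blocks(parsed, sub$pos[i])
    L <- nchar(sub$seq[i])
    for (j in which(b$op %in% c("M", "=", "X"))) {
      for (off in seq_len(b$len[j]) - 1L) {
        qoff <- b$qstart[j] + off
        cycle <- if (sub$reverse[i]) L - 1L - qoff else qoff
        if (cycle >= L - 3L) next
        key <- as.character(b$rstart[j] + off)
        counts[[key]] <- c(counts[[key]],
                           substr(sub$seq[i], qoff + 1L, qoff + 1L))
      }
    }
  }
  expected <- sort(as.integer(ls(counts)))
  got <- pile$obs[, .N, by = pos][order(pos)]
  expect_equal(got$pos, expected)
  for (p in expected)
    expect_equal(sort(pile$obs[pos == p, base]),
                 sort(counts[[as.character(p)]]),
                 info = paste("site", p))
})

test_that("total observations match the per-read aligned-length sum", {
  fx <- small_fixture()
  sub <- fx$aln[1:200]
  n <- 5L
  pile <- build_pileups(sub, ignore_last_n = n)
  expected <- 0L
  for (i in seq_len(nrow(sub))) {
    parsed <- vardiscover:::parse_cigar(sub$cigar[i])[[1]]
    b <- vardiscover:::cigar_blocks(parsed, sub$pos[i])
    L <- nchar(sub$seq[i])
    for (j in which(b$op %in% c("M", "=", "X"))) {
      qoffs <- b$qstart[j] + seq_len(b$len[j]) - 1L
      cycles <- if (sub$reverse[i]) L - 1L - qoffs else qoffs
      expected <- expected + sum(cycles < L - n)
    }
  }
  expect_equal(nrow(pile$obs), expected)
})

test_that("quality statistics localise errors to their cycle", {
  ## error-free synthetic reads -> all rates zero
  fx <- small_fixture()
  ref <- fx$genome$reference
  cfg0 <- simulation_config(seq_lengths = c(chr1 = 20000L), n_snvs = 0L,
                            n_indels = 0L, cnvs = NULL,
                            large_deletions = NULL, repeats = NULL,
                            quality_profile = 93L, seed = 3L)
  g0 <- simulate_genome(cfg0)
  a0 <- simulate_alignments(g0)
  qs0 <- quality_statistics(a0, g0$reference)
  expect_true(all(qs0$rate == 0))

  ## reads with errors only at the final cycle
  refseq <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 25), collapse = "")))
  good <- substr(as.character(refseq[[1]]), 1, 10)
  badlast <- paste0(substr(good, 1, 9), chartr("ACGT", "TGCA",
                                               substr(good, 10, 10)))
  aln <- make_aln(make_read("a", 1L, "10M", seq = good),
                  make_read("b", 1L, "10M", seq = badlast))
  qs <- quality_statistics(aln, refseq)
  expect_equal(qs[read_pos == 9L, mismatches], 1L)
  expect_true(all(qs[read_pos < 9L, mismatches] == 0L))

  ## empty input -> empty table
  empty <- make_aln(make_read("x", 1L))[0]
  expect_equal(nrow(quality_statistics(empty, refseq)), 0L)
})
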