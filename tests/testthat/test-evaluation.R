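# Gold-standard construction, error taxonomy, S/FDR/FPR and the
# pooled-segregant drift simulation.

## genome-wide haploid call set over `n` sites
hap_calls <- function(n, alt_sites = integer(0), gq = 95L,
                      alt_allele = "T") {
  dt <- data.table(rname = "chr1", pos = seq_len(n), ref = "A",
                   alt = "", gt = "0/0", gq = as.integer(gq), dp = 40L)
  if (length(alt_sites) > 0L) {
    dt[pos %in% alt_sites, `:=`(gt = "1/1", alt = alt_allele)]
  }
  dt[]
}

test_that("gold standard requires agreement above the quality floor", {
  ## both parents reference everywhere -> all homozygous_ref
  g <- build_gold_standard(list(hap_calls(10)), list(hap_calls(10)))
  expect_equal(nrow(g), 10L)
  expect_true(all(g$expected_class == "homozygous_ref"))

  ## parent2 carries the alternative at site 4 -> heterozygous pool site
  g2 <- build_gold_standard(list(hap_calls(10)),
                            list(hap_calls(10, alt_sites = 4L)))
  expect_equal(g2[pos == 4L, expected_class], "heterozygous")
  expect_equal(g2[pos == 4L, allele2], "T")

  ## both parents alternative -> homozygous_alt
  g3 <- build_gold_standard(list(hap_calls(10, 4L)),
                            list(hap_calls(10, 4L)))
  expect_equal(g3[pos == 4L, expected_class], "homozygous_alt")

  ## quality 85 at a site excludes it (threshold is > 90)
  low <- hap_calls(10)
  low[pos == 7L, gq := 85L]
  g4 <- build_gold_standard(list(low), list(hap_calls(10)))
  expect_false(7L %in% g4$pos)
  g4b <- build_gold_standard(list(hap_calls(10, gq = 90L)),
                             list(hap_calls(10)))
  expect_equal(nrow(g4b), 0L)

  ## disagreement between two callers of one parent excludes the site
  g5 <- build_gold_standard(list(hap_calls(10, 4L), hap_calls(10)),
                            list(hap_calls(10)))
  expect_false(4L %in% g5$pos)
  expect_equal(nrow(g5), 9L)
})

test_that("evaluation counts match the worked hand count", {
  ## gold: 4 hom + 4 het; test calls one hom site het, rest correct
  gold <- data.table(rname = "chr1", pos = 1:8, ref = "A",
                     allele1 = c(rep("A", 4), rep("A", 4)),
                     allele2 = c(rep("A", 4), rep("T", 4)))
  gold[, expected_class := fifelse(allele1 != allele2, "heterozygous",
                                   "homozygous_ref")]
  test <- data.table(rname = "chr1", pos = 1:8, ref = "A",
                     alt = c("", "", "", "T", rep("T", 4)),
                     gt = c("0/0", "0/0", "0/0", "0/1",
                            rep("0/1", 4)),
                     gq = 99L)
  ev <- evaluate_genotypes(gold, test, 0)
  het <- ev[class == "heterozygous"]
  expect_equal(het$type1, 1L)
  expect_equal(het$S, 1)
  expect_equal(het$FDR, 1 / 5)
  expect_equal(het$FPR, 1 / 4)
  hom <- ev[class == "homozygous"]
  expect_equal(hom$S, 3 / 4)
  expect_equal(hom$FDR, 0)

  ## all correct -> S = 1, FDR = 0 for both classes
  test2 <- copy(test)[pos == 4L, `:=`(gt = "0/0", alt = "")]
  ev2 <- evaluate_genotypes(gold, test2, 0)
  expect_true(all(ev2$S == 1))
  expect_true(all(ev2$FDR == 0))

  ## raising the threshold above every GQ: S = 0, FDR reported 0 + flag
  ev3 <- evaluate_genotypes(gold, test, 120)
  expect_true(all(ev3$S == 0))
  expect_true(all(ev3$FDR == 0))
  expect_true(all(ev3$zero_denominator))

  ## sites not in the gold standard are ignored entirely
  test4 <- rbind(test2, data.table(rname = "chr1", pos = 99L, ref = "A",
                                   alt = "T", gt = "0/1", gq = 99L))
  ev4 <- evaluate_genotypes(gold, test4, 0)
  expect_equal(ev4[class == "heterozygous", C_e], 4L)

  expect_error(evaluate_genotypes(gold[0], test, 0), "empty gold")
})

test_that("type 3/4 errors separate reference and variant homozygotes", {
  gold <- data.table(rname = "chr1", pos = 1:4, ref = "A",
                     allele1 = c("A", "A", "T", "T"),
                     allele2 = c("A", "A", "T", "T"))
  gold[, expected_class := fifelse(allele1 == "A", "homozygous_ref",
                                   "homozygous_alt")]
  test <- data.table(rname = "chr1", pos = 1:4, ref = "A",
                     alt = c("T", "", "", "T"),
                     gt = c("1/1", "0/0", "0/0", "1/1"), gq = 99L)
  ev <- evaluate_genotypes(gold, test, 0)[1]
  expect_equal(ev$type3, 1L)   # site 1: hom ref called hom alt
  expect_equal(ev$type4, 1L)   # site 3: hom alt called hom ref
})

test_that("evaluation equals a brute-force site recount on random toys", {
  set.seed(12)
  for (rep in 1:20) {
    n <- 100L
    cls <- sample(c("homozygous_ref", "homozygous_alt", "heterozygous"),
                  n, replace = TRUE)
    gold <- data.table(rname = "chr1", pos = seq_len(n), ref = "A",
                       allele1 = fifelse(cls == "homozygous_alt", "T", "A"),
                       allele2 = fifelse(cls == "homozygous_ref", "A", "T"),
                       expected_class = cls)
    gts <- sample(c("0/0", "0/1", "1/1", NA), n, replace = TRUE)
    test <- data.table(rname = "chr1", pos = seq_len(n), ref = "A",
                       alt = fifelse(is.na(gts) | gts == "0/0", "", "T"),
                       gt = gts, gq = sample(0:99, n, replace = TRUE))
    test <- test[!is.na(gt)]
    thr <- sample(0:80, 1)
    ev <- evaluate_genotypes(gold, test, thr)
    ## brute force
    j <- merge(gold, test, by = c("rname", "pos"), all.x = TRUE)
    called <- !is.na(j$gt) & j$gq >= thr
    ishet <- called & j$gt == "0/1"
    ishom <- called & j$gt %in% c("0/0", "1/1")
    ghet <- j$expected_class == "heterozygous"
    expect_equal(ev[class == "heterozygous", type1],
                 sum(!ghet & ishet))
    expect_equal(ev[class == "homozygous", type2], sum(ghet & ishom))
    expect_equal(ev[class == "heterozygous", S],
                 sum(ghet & ishet) / sum(ghet))
    den <- sum(ishet)
    expect_equal(ev[class == "heterozygous", FDR],
                 if (den > 0) sum(!ghet & ishet) / den else 0)
    expect_equal(ev[class == "homozygous", S],
                 sum(!ghet & ishom) / sum(!ghet))
  }
})

test_that("S falls and FDR falls as the threshold rises on a graded toy", {
  ## errors concentrated at low GQ
  set.seed(3)
  n <- 400L
  gold <- data.table(rname = "chr1", pos = seq_len(n), ref = "A",
                     allele1 = "A",
                     allele2 = rep(c("A", "T"), each = n / 2))
  gold[, expected_class := fifelse(allele2 == "T", "heterozygous",
                                   "homozygous_ref")]
  gt <- fifelse(gold$expected_class == "heterozygous", "0/1", "0/0")
  gq <- sample(1:99, n, replace = TRUE)
  flip <- gq < 30 & runif(n) < 0.5
  gt[flip] <- fifelse(gt[flip] == "0/1", "0/0", "0/1")
  test <- data.table(rname = "chr1", pos = seq_len(n), ref = "A",
                     alt = fifelse(gt == "0/0", "", "T"), gt = gt, gq = gq)
  ev <- evaluate_genotypes(gold, test, c(0, 40))
  het <- ev[class == "heterozygous"]
  expect_lt(het[threshold == 40, FDR], het[threshold == 0, FDR])
  expect_lte(het[threshold == 40, S], het[threshold == 0, S])
})

test_that("pool-site simulation follows its three-stage model", {
  ## p = 1 -> all segregants reference, all reads reference
  ps <- simulate_pool_sites(500, 20, 1, 30, seed = 2)
  expect_true(all(ps$n_i == 20L))
  expect_true(all(ps$ref_count == ps$d_i))

  ## deterministic for a fixed seed
  expect_identical(simulate_pool_sites(100, seed = 9),
                   simulate_pool_sites(100, seed = 9))

  ## mean reference frequency 0.5 within 3 SE at n = 20, p = 0.5
  ps2 <- simulate_pool_sites(20000, 20, 0.5, 34, seed = 4)
  f <- ps2[d_i > 0, ref_count / d_i]
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.5), 3 * se)

  ## drift widens the allele-frequency distribution: n = 200 and fixed-p
  ## variants both reduce the variance relative to n = 20
  v20 <- var(f)
  ps200 <- simulate_pool_sites(20000, 200, 0.5, 34, seed = 4)
  v200 <- var(ps200[d_i > 0, ref_count / d_i])
  psfix <- simulate_pool_sites(20000, 20, 0.5, 34, seed = 4, fixed_p = 0.5)
  vfix <- var(psfix[d_i > 0, ref_count / d_i])
  expect_lt(v200, v20)
  expect_lt(vfix, v20)
})
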