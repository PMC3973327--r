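# Functional annotation, filtering, merging and summaries.

## a 240 bp toy genome with one plus-strand and one minus-strand gene
annot_fixture <- function() {
  cached("annot", {
    set.seed(33)
    refseq <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
                    collapse = "")
    ## plus-strand CDS 31..90 gets a fixed codon layout we control
    substr(refseq, 31, 39) <- "ATGGGAGCA"      # M G A ...
    ref <- Biostrings::DNAStringSet(c(chr1 = refseq))
    gff <- tempfile(fileext = ".gff3")
    writeLines(c(
      "##gff-version 3",
      "chr1\ttoy\tgene\t21\t100\t.\t+\t.\tID=gplus",
      "chr1\ttoy\tmRNA\t21\t100\t.\t+\t.\tID=tplus;Parent=gplus",
      "chr1\ttoy\tCDS\t31\t90\t.\t+\t0\tID=cp1;Parent=tplus",
      "chr1\ttoy\tgene\t121\t200\t.\t-\t.\tID=gminus",
      "chr1\ttoy\tmRNA\t121\t200\t.\t-\t.\tID=tminus;Parent=gminus",
      "chr1\ttoy\tCDS\t131\t190\t.\t-\t0\tID=cm1;Parent=tminus"), gff)
    list(ref = ref, models = read_gene_models(gff), seq = refseq)
  })
}

mk_call <- function(pos, ref, alt, type = "SNV", gt = "0/1", gq = 60L) {
  data.table(rname = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
             gt = gt, gq = as.integer(gq), dp = 20L, posterior = 1,
             type = type)
}

test_that("SNV effects follow codon translation on both strands", {
  fx <- annot_fixture()
  ## GGA -> GGG at codon 2 of the plus gene: synonymous (both Gly)
  ann <- annotate_variants(mk_call(36L, "A", "G"), fx$models, fx$ref)
  expect_equal(ann$effect, "synonymous")
  expect_equal(ann$gene_id, "gplus")

  ## GGA -> GAA: nonsynonymous (Gly -> Glu)
  ann2 <- annotate_variants(mk_call(35L, "G", "A"), fx$models, fx$ref)
  expect_equal(ann2$effect, "nonsynonymous")

  ## introduce a stop: GGA -> TGA would need codon pos 1: G->T at 34
  ann3 <- annotate_variants(mk_call(34L, "G", "T"), fx$models, fx$ref)
  expect_equal(ann3$effect, "nonsense")

  ## inside the gene but outside CDS -> intron
  ann4 <- annotate_variants(mk_call(25L, substr(fx$seq, 25, 25), "A"),
                            fx$models, fx$ref)
  expect_equal(ann4$effect, "intron")

  ## far from any gene -> intergenic
  ann5 <- annotate_variants(mk_call(230L, substr(fx$seq, 230, 230), "A"),
                            fx$models, fx$ref)
  expect_equal(ann5$effect, "intergenic")
})

test_that("minus-strand annotation equals the mirrored plus-strand case", {
  fx <- annot_fixture()
  ## build a plus-strand mirror of the minus gene and compare effects
  minus_cds <- fx$models$cds[gene_id == "gminus"]
  spliced <- vardiscover:::.spliced_cds(minus_cds, fx$ref)
  mirror_ref <- Biostrings::DNAStringSet(c(chr1 = spliced))
  gffm <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("chr1\ttoy\tgene\t1\t%d\t.\t+\t.\tID=g", nchar(spliced)),
               sprintf("chr1\ttoy\tmRNA\t1\t%d\t.\t+\t.\tID=t;Parent=g",
                       nchar(spliced)),
               sprintf("chr1\ttoy\tCDS\t1\t%d\t.\t+\t0\tID=c;Parent=t",
                       nchar(spliced))), gffm)
  mirror_models <- read_gene_models(gffm)
  for (off in c(3L, 10L, 25L)) {
    gpos <- 190L - off + 1L                 # genomic position on minus gene
    refbase <- substr(fx$seq, gpos, gpos)
    altbase <- setdiff(c("A", "C", "G", "T"), refbase)[1]
    a_minus <- annotate_variants(mk_call(gpos, refbase, altbase),
                                 fx$models, fx$ref)
    comp <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(altbase)))
    a_plus <- annotate_variants(
      mk_call(off, substr(spliced, off, off), comp),
      mirror_models, mirror_ref)
    expect_equal(a_minus$effect, a_plus$effect, info = paste("offset", off))
  }
})

test_that("indel effects depend on length modulo 3", {
  fx <- annot_fixture()
  r2 <- substr(fx$seq, 40, 42)
  ann <- annotate_variants(mk_call(40L, r2, substr(r2, 1, 1), type = "DEL"),
                           fx$models, fx$ref)
  expect_equal(ann$effect, "frameshift")     # 2 bp deletion
  r3 <- substr(fx$seq, 40, 43)
  ann2 <- annotate_variants(mk_call(40L, r3, substr(r3, 1, 1),
                                    type = "DEL"), fx$models, fx$ref)
  expect_equal(ann2$effect, "inframe_indel") # 3 bp deletion
})

test_that("transcripts with CDS length not multiple of 3 are skipped", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t1\t100\t.\t+\t.\tID=g",
               "chr1\ttoy\tmRNA\t1\t100\t.\t+\t.\tID=t;Parent=g",
               "chr1\ttoy\tCDS\t1\t10\t.\t+\t0\tID=c;Parent=t"), gff)
  expect_warning(m <- read_gene_models(gff), "multiple of 3")
  expect_equal(nrow(m$cds), 0L)
})

test_that("filter_calls applies GQ and region criteria, idempotently", {
  calls <- rbindlist(list(
    mk_call(10L, "A", "T", gq = 35L),
    mk_call(50L, "A", "T", gq = 80L),
    mk_call(150L, "A", "T", gq = 80L)))
  ex <- data.table(rname = "chr1", first = 140L, last = 160L)
  out <- filter_calls(calls, min_gq = 40L, exclude_regions = ex)
  expect_equal(out$pos, 50L)

  ## identity with no criteria
  expect_equal(filter_calls(calls, 0L, NULL), calls)
  ## idempotence and commutation of the two criteria
  expect_equal(filter_calls(out, 40L, ex), out)
  a <- filter_calls(filter_calls(calls, 40L, NULL), 0L, ex)
  b <- filter_calls(filter_calls(calls, 0L, ex), 40L, NULL)
  expect_equal(a, b)
})

test_that("merge_vcfs takes the site union with missing genotypes", {
  s1 <- mk_call(10L, "A", "T")
  s2 <- mk_call(20L, "C", "G")
  m <- merge_vcfs(list(x = s1, y = s2))
  expect_equal(nrow(m), 2L)
  expect_equal(m[pos == 10L, gt_x], "0/1")
  expect_equal(m[pos == 10L, gt_y], "./.")
  expect_equal(m[pos == 20L, gt_x], "./.")
  expect_equal(m[pos == 20L, gt_y], "0/1")

  ## identical single-sample sets -> duplicated column
  m2 <- merge_vcfs(list(a = s1, b = copy(s1)))
  expect_equal(m2$gt_a, m2$gt_b)

  ## empty second sample -> all-missing column
  m3 <- merge_vcfs(list(a = s1, b = s1[0]))
  expect_equal(m3$gt_b, "./.")

  ## exactly one row per distinct site
  m4 <- merge_vcfs(list(a = rbind(s1, s2), b = s1))
  expect_equal(nrow(m4), 2L)
  expect_equal(anyDuplicated(m4[, .(rname, pos)]), 0L)

  ## allele unification renumbers genotype indices
  s3 <- mk_call(10L, "A", "G,T")[, gt := "1/2"]
  m5 <- merge_vcfs(list(a = s1, b = s3))
  expect_equal(m5$alt, "T,G")
  expect_equal(m5$gt_a, "0/1")
  expect_equal(m5$gt_b, "1/2")

  ## conflicting reference alleles are a hard error naming the site
  bad <- mk_call(10L, "C", "T")
  expect_error(merge_vcfs(list(a = s1, b = bad)), "chr1:10")
})

test_that("summaries report counts and percentages with denominators", {
  calls <- rbindlist(c(
    lapply(1:2, function(i) mk_call(i * 10L, "A", "T", gt = "0/1")),
    lapply(3:10, function(i) mk_call(i * 10L, "A", "T", gt = "1/1"))))
  s <- summarize_calls(calls)
  expect_equal(s[metric == "heterozygous", percent], 20)
  expect_equal(s[metric == "heterozygous", count], 2L)
  expect_equal(s[metric == "total", count], 10L)

  ## zero calls -> zero totals
  s0 <- summarize_calls(calls[0])
  expect_equal(s0$count, 0L)

  ## all coding SNVs synonymous -> 0% nonsense
  ann <- copy(calls)[, effect := "synonymous"]
  sa <- summarize_calls(ann)
  expect_equal(sa[metric == "nonsense", percent], 0)
  expect_equal(sa[metric == "nonsynonymous", denominator], 10L)

  ## excluded-region accounting
  ex <- data.table(rname = "chr1", first = 1L, last = 25L)
  se <- summarize_calls(calls, exclude_regions = ex)
  expect_equal(se[metric == "in_excluded_regions", count], 2L)
})
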