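# Shared fixtures, built in code.  Expensive simulations are cached for the
# duration of the test run.

library(data.table)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## Hand-built alignment record (already in the reader's schema).
make_read <- function(qname = "r1", pos = 1L, cigar = "10M",
                      seq = NULL, qual_phred = 30L, rname = "chr1",
                      mapq = 60L, flag = 0L, tlen = 0L, nh = 1L,
                      pnext = 0L) {
  qw <- vardiscover:::cigar_query_width(cigar)
  if (is.null(seq)) seq <- paste(rep("A", qw), collapse = "")
  qual <- intToUtf8(rep_len(qual_phred, nchar(seq)) + 33L)
  dt <- data.table(
    qname = qname, flag = flag, rname = rname, pos = as.integer(pos),
    mapq = as.integer(mapq), cigar = cigar, rnext = "=",
    pnext = as.integer(pnext), tlen = as.integer(tlen), seq = seq,
    qual = qual, nh = as.integer(nh))
  dt[, `:=`(secondary = bitwAnd(flag, 256L) > 0L,
            reverse = bitwAnd(flag, 16L) > 0L,
            paired = bitwAnd(flag, 1L) > 0L,
            proper = bitwAnd(flag, 2L) > 0L,
            first_of_pair = bitwAnd(flag, 64L) > 0L)]
  dt[, unique_aln := !secondary & mapq > 0L]
  dt[, multiple := secondary | nh > 1L]
  dt[, end_pos := pos + vardiscover:::cigar_ref_width(cigar) - 1L]
  dt[]
}

make_aln <- function(..., seq_lengths = c(chr1 = 100000L)) {
  aln <- rbindlist(list(...))
  setorder(aln, rname, pos)
  setattr(aln, "seq_lengths", seq_lengths)
  aln[]
}

## Small diploid fixture shared by several module tests (60 kb, SNVs+indels
## only).
small_fixture <- function() {
  cached("small", {
    cfg <- simulation_config(seq_lengths = c(chr1 = 60000L), n_snvs = 40L,
                             n_indels = 10L, cnvs = NULL,
                             large_deletions = NULL, repeats = NULL,
                             seed = 7L)
    g <- simulate_genome(cfg)
    list(genome = g, aln = simulate_alignments(g))
  })
}

## Structural fixture: 300 kb with CNVs, repeat, large deletion.
structural_fixture <- function(strategy = "all") {
  cached(paste0("struct_", strategy), {
    cfg <- simulation_config(seq_lengths = c(chr1 = 300000L), n_snvs = 50L,
                             n_indels = 10L, strategy = strategy,
                             seed = 11L)
    g <- simulate_genome(cfg)
    list(genome = g, aln = simulate_alignments(g))
  })
}

## The 1 Mb acceptance fixture (defaults of simulation_config).
acceptance_fixture <- function() {
  cached("acceptance", {
    cfg <- simulation_config(seed = 42L, strategy = "all")
    g <- simulate_genome(cfg)
    list(genome = g, aln = simulate_alignments(g))
  })
}

## Independent brute-force posterior oracle: enumerate all diploid
## genotypes over `alleles`, computing likelihoods in probability space by
## direct per-observation products (no shared code with call_genotype
## beyond the model definition).
oracle_posterior <- function(obs_allele, obs_qual, alleles, ref_index = 1L,
                             h = 0.001) {
  k <- length(alleles)
  gts <- list()
  for (i in seq_len(k)) for (j in i:k) gts[[length(gts) + 1L]] <- c(i, j)
  lik <- vapply(gts, function(g) {
    pr <- 1
    for (o in seq_along(obs_allele)) {
      e <- 10^(-obs_qual[o] / 10)
      p_of <- function(a) if (obs_allele[o] == alleles[a]) 1 - e else
        e / (k - 1)
      pr <- pr * (0.5 * p_of(g[1]) + 0.5 * p_of(g[2]))
    }
    pr
  }, numeric(1))
  prior <- vapply(gts, function(g)
    if (all(g == ref_index)) 1 - h else NA_real_, numeric(1))
  prior[is.na(prior)] <- h / sum(is.na(prior))
  post <- lik * prior
  post <- post / sum(post)
  names(post) <- vapply(gts, function(g)
    paste(sort(g - 1L), collapse = "/"), character(1))
  post
}

## Brute-force minimal within-segment-SS partition into exactly k contiguous
## segments; returns boundary positions (after-bin indices).
oracle_best_partition <- function(x, k) {
  n <- length(x)
  if (k == 1L) return(integer(0))
  wss <- function(v) sum((v - mean(v))^2)
  combs <- utils::combn(n - 1L, k - 1L)
  best <- NULL; best_ss <- Inf
  for (ci in seq_len(ncol(combs))) {
    b <- combs[, ci]
    starts <- c(1L, b + 1L); ends <- c(b, n)
    ss <- sum(vapply(seq_along(starts), function(i)
      wss(x[starts[i]:ends[i]]), numeric(1)))
    if (ss < best_ss) { best_ss <- ss; best <- b }
  }
  best
}

## Poisson upper-tail by explicit summation of P(X = j), j = k, k+1, ...
## until terms vanish (oracle for p-values; no subtractive cancellation).
oracle_poisson_tail <- function(k, lambda) {
  if (k <= 0) return(1)
  j <- k:(k + 3000L)
  sum(exp(-lambda + j * log(lambda) - lgamma(j + 1)))
}

## Null RD signal: independent Poisson bin counts, all bins unique.
null_rd_signal <- function(n_bins, lambda = 30, seed = 1L,
                           gc = 40L, b = 100L) {
  set.seed(seed)
  sig <- data.table(rname = "chr1", bin_index = seq_len(n_bins),
                    first = (seq_len(n_bins) - 1L) * b + 1L,
                    last = seq_len(n_bins) * b,
                    gc_percent = gc,
                    raw_depth = as.numeric(rpois(n_bins, lambda)),
                    is_unique = TRUE)
  sig[, corrected_depth := raw_depth]
  setattr(sig, "bin_size", b)
  sig[]
}

## RD signal with specified per-bin depths.
depth_signal <- function(depths, gc = 40L, unique_bins = TRUE, b = 100L) {
  n <- length(depths)
  sig <- data.table(rname = "chr1", bin_index = seq_len(n),
                    first = (seq_len(n) - 1L) * b + 1L,
                    last = seq_len(n) * b,
                    gc_percent = rep_len(gc, n),
                    raw_depth = as.numeric(depths),
                    is_unique = rep_len(unique_bins, n))
  sig[, corrected_depth := raw_depth]
  setattr(sig, "bin_size", b)
  sig[]
}
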