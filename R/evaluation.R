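# Gold-standard construction from two haploid parents, genotype error
# taxonomy, sensitivity/FDR/FPR/ROC computation and the pooled-segregant
# drift simulation.

## Genotype class of a GT string: "het", "hom" (either allele) or NA.
gt_class <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(x) {
    if (length(x) == 0L || anyNA(x) || any(x == "."))
      return(NA_character_)
    if (length(base::unique(x)) > 1L) "het" else "hom"
  }, character(1))
}

## Called allele of a monoallelic genotype ("0/0" -> ref, "1/1" -> alt1...).
called_allele <- function(gt, ref, alt) {
  i <- suppressWarnings(as.integer(sub("[/|].*", "", gt)))
  out <- ref
  for (j in which(!is.na(i) & i > 0L)) {
    a <- strsplit(alt[j], ",")[[1]]
    out[j] <- if (length(a) >= i[j]) a[i[j]] else NA_character_
  }
  out[is.na(i)] <- NA_character_
  out
}

#' Build gold-standard genotypes from two haploid parents
#'
#' A site enters the gold standard when, in every provided call set for
#' both parents, exactly one allele is called with quality above
#' `min_quality` and the allele agrees across the parent's call sets.
#' Sites where the two parents carry the same allele are expected
#' homozygous in an F1 segregant pool; sites where they differ are expected
#' heterozygous.
#'
#' @param parent1,parent2 lists of genome-wide call tables (one per caller;
#'   [call_variants()] with `emit_all = TRUE`).
#' @param min_quality minimum GQ, exclusive (default 90).
#' @return data.table `rname`, `pos`, `ref`, `allele1`, `allele2`,
#'   `expected_class` in `homozygous_ref` / `homozygous_alt` /
#'   `heterozygous`.
#' @export
build_gold_standard <- function(parent1, parent2, min_quality = 90L) {
  consensus <- function(call_sets) {
    per <- lapply(call_sets, function(cs) {
      cls <- gt_class(cs$gt)
      ok <- !is.na(cls) & cls == "hom" & cs$gq > min_quality
      x <- cs[ok]
      x[, allele := called_allele(gt, ref, alt)]
      x[, .(rname, pos, ref, allele)]
    })
    m <- per[[1L]]
    if (length(per) > 1L) for (i in 2L:length(per)) {
      m <- merge(m, per[[i]], by = c("rname", "pos", "ref"),
                 suffixes = c("", paste0(".", i)))
      m <- m[allele == m[[paste0("allele.", i)]]]
      m[, (paste0("allele.", i)) := NULL]
    }
    m
  }
  p1 <- consensus(parent1)
  p2 <- consensus(parent2)
  g <- merge(p1, p2, by = c("rname", "pos", "ref"),
             suffixes = c("1", "2"))
  g[, expected_class := fifelse(
    allele1 != allele2, "heterozygous",
    fifelse(allele1 == ref, "homozygous_ref", "homozygous_alt"))]
  setorder(g, rname, pos)
  g[, .(rname, pos, ref, allele1, allele2, expected_class)]
}

#' Evaluate genotype calls against a gold standard
#'
#' Sites absent from the gold standard are ignored.  At each minimum
#' quality threshold, calls below the threshold are treated as uncalled.
#' Error taxonomy: type1 = homozygous gold sites called heterozygous,
#' type2 = heterozygous gold sites called homozygous, type3 = homozygous
#' reference sites called homozygous variant, type4 = homozygous variant
#' sites called homozygous reference.  Per class (heterozygous `e`,
#' homozygous `o`): `S = |G∩C| / |G|` within the class,
#' `FDR_e = |G_o ∩ C_e| / |C_e|`, `FPR_e = |G_o ∩ C_e| / |G_o|` and
#' symmetrically for the homozygous class.  Zero-denominator rates are
#' reported as 0 with `zero_denominator = TRUE`.
#'
#' @param gold from [build_gold_standard()].
#' @param test_calls call table (hom-ref calls included if available).
#' @param thresholds numeric vector of minimum GQ thresholds.
#' @return data.table with one row per threshold and class, carrying the
#'   set sizes, type1..type4 counts, `S`, `FDR`, `FPR` and
#'   `zero_denominator`.  ROC curves are the `(FPR, S)` pairs in threshold
#'   order.
#' @export
evaluate_genotypes <- function(gold, test_calls, thresholds = c(0)) {
  if (nrow(gold) == 0L) stop("empty gold standard")
  tc <- test_calls[, .(rname, pos, gt, gq,
                       ref_t = ref, alt_t = alt)]
  j <- merge(gold, tc, by = c("rname", "pos"), all.x = TRUE)
  j[, called_class := gt_class(gt)]
  gold_het <- j$expected_class == "heterozygous"
  out <- list()
  for (thr in thresholds) {
    called <- !is.na(j$called_class) & !is.na(j$gq) & j$gq >= thr
    c_het <- called & j$called_class == "het"
    c_hom <- called & j$called_class == "hom"
    G_e <- sum(gold_het); G_o <- sum(!gold_het)
    C_e <- sum(c_het); C_o <- sum(c_hom)
    type1 <- sum(!gold_het & c_het)
    type2 <- sum(gold_het & c_hom)
    hom_call_allele <- rep(NA_character_, nrow(j))
    hc <- which(c_hom)
    if (length(hc) > 0L)
      hom_call_allele[hc] <- called_allele(j$gt[hc], j$ref_t[hc],
                                           j$alt_t[hc])
    type3 <- sum(c_hom & j$expected_class == "homozygous_ref" &
                   !is.na(hom_call_allele) & hom_call_allele != j$ref,
                 na.rm = TRUE)
    type4 <- sum(c_hom & j$expected_class == "homozygous_alt" &
                   !is.na(hom_call_allele) & hom_call_allele == j$ref,
                 na.rm = TRUE)
    mk <- function(cls, S_num, S_den, err, C_den, FPR_den) {
      data.table(threshold = thr, class = cls,
                 G_o = G_o, G_e = G_e, C_o = C_o, C_e = C_e,
                 type1 = type1, type2 = type2, type3 = type3,
                 type4 = type4,
                 S = if (S_den > 0L) S_num / S_den else 0,
                 FDR = if (C_den > 0L) err / C_den else 0,
                 FPR = if (FPR_den > 0L) err / FPR_den else 0,
                 zero_denominator = C_den == 0L || S_den == 0L)
    }
    out[[length(out) + 1L]] <- mk("heterozygous",
                                  sum(gold_het & c_het), G_e,
                                  type1, C_e, G_o)
    out[[length(out) + 1L]] <- mk("homozygous",
                                  sum(!gold_het & c_hom), G_o,
                                  type2, C_o, G_e)
  }
  rbindlist(out)
}

#' Pooled-segregant drift simulation
#'
#' For each simulated heterozygous site: the number of segregants carrying
#' the reference allele `n_i ~ Binomial(n_segregants, p)`; the total read
#' depth `d_i ~ Poisson(median_coverage)`; the observed reference count
#' `ref_count ~ Binomial(d_i, n_i / n_segregants)`.  Setting
#' `fixed_p` replaces `n_i / n_segregants` by a constant reference allele
#' frequency (removing the drift component).
#'
#' @param n_sites number of sites to simulate.
#' @param n_segregants pool size (default 20).
#' @param p segregation probability of the reference allele (default 0.5).
#' @param median_coverage Poisson depth parameter.
#' @param seed RNG seed (deterministic output).
#' @param fixed_p optional fixed reference allele frequency.
#' @return data.table `n_i`, `d_i`, `ref_count`.
#' @export
simulate_pool_sites <- function(n_sites, n_segregants = 20L, p = 0.5,
                                median_coverage = 34, seed = 1L,
                                fixed_p = NULL) {
  stopifnot(median_coverage > 0)
  with_seed(seed, {
    n_i <- stats::rbinom(n_sites, n_segregants, p)
    d_i <- stats::rpois(n_sites, median_coverage)
    freq <- if (is.null(fixed_p)) n_i / n_segregants else
      rep(fixed_p, n_sites)
    ref_count <- stats::rbinom(n_sites, d_i, freq)
    data.table(n_i = n_i, d_i = d_i, ref_count = ref_count)
  })
}
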