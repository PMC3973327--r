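# Bayesian diploid genotyping of SNVs and small indels from pileups,
# with local realignment of indels to a consensus start site.

#' Genotype log-likelihoods for one pileup column
#'
#' For a diploid genotype \{X,Y\} the likelihood of the observations is
#' `L = sum(log(0.5*P(obs|X) + 0.5*P(obs|Y)))` with
#' `P(obs|A) = 1 - e` when the observed allele equals `A` and `e/(k-1)`
#' otherwise, where `e = 10^(-q/10)` and `k` is the number of alleles under
#' consideration.
#'
#' @param obs_allele character vector of observed alleles (bases or indel
#'   allele strings), qualities already capped.
#' @param obs_qual phred qualities of the observations.
#' @param alleles character vector (>= 2) of candidate alleles.
#' @return data.table with `a1`, `a2` (allele indices, `a1 <= a2`) and
#'   `loglik`; empty when there are no observations.
#' @export
genotype_likelihoods <- function(obs_allele, obs_qual, alleles) {
  stopifnot(length(alleles) >= 2L)
  n <- length(obs_allele)
  if (n == 0L)
    return(data.table(a1 = integer(), a2 = integer(), loglik = numeric()))
  k <- length(alleles)
  e <- phred_to_prob(obs_qual)
  ## P[i, a] = P(obs i | true allele a)
  P <- matrix(rep(e / (k - 1), k), nrow = n)
  ai <- match(obs_allele, alleles)
  hit <- !is.na(ai)
  P[cbind(which(hit), ai[hit])] <- 1 - e[hit]
  gt <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  ll <- vapply(seq_len(nrow(gt)), function(g) {
    sum(log(0.5 * P[, gt[g, 1L]] + 0.5 * P[, gt[g, 2L]]))
  }, numeric(1))
  data.table(a1 = unname(gt[, 1L]), a2 = unname(gt[, 2L]), loglik = ll)
}

#' Posterior genotype call for one pileup column
#'
#' The prior places mass `1 - h` on the homozygous-reference genotype and
#' splits `h` uniformly over every genotype containing at least one
#' non-reference allele; the call is the maximum-a-posteriori genotype.
#'
#' @param obs_allele,obs_qual observations as in [genotype_likelihoods()].
#' @param alleles candidate alleles; `alleles[ref_index]` is the reference.
#' @param ref_index index of the reference allele (default 1).
#' @param h prior heterozygosity rate (0 < h < 1), default 0.001.
#' @return `NULL` when there are no observations, else a list with
#'   `gt` (sorted pair of 0-based allele indices), `gq`, `posterior`
#'   (of the called genotype), `dp`, and the full `posteriors` table.
#' @export
call_genotype <- function(obs_allele, obs_qual, alleles, ref_index = 1L,
                          h = 0.001) {
  stopifnot(h > 0, h < 1)
  lk <- genotype_likelihoods(obs_allele, obs_qual, alleles)
  if (nrow(lk) == 0L) return(NULL)
  homref <- lk$a1 == ref_index & lk$a2 == ref_index
  logprior <- ifelse(homref, log1p(-h), log(h / sum(!homref)))
  lp <- lk$loglik + logprior
  post <- exp(lp - logsumexp(lp))
  i <- which.max(post)
  list(gt = sort(c(lk$a1[i], lk$a2[i])) - 1L,
       gq = genotype_quality(post[i]),
       posterior = post[i],
       dp = length(obs_allele),
       posteriors = data.table(a1 = lk$a1, a2 = lk$a2, posterior = post))
}

#' Realign indels to a consensus start site
#'
#' Each indel start site is screened a few base pairs ahead (5 for
#' insertions, deletion length + 2 for deletions) for the same event
#' (same type and length) at other start sites.  All matching events are
#' relocated to the start with the highest read support (ties broken by the
#' leftmost start) by rewriting the CIGAR of the affected records.  Records
#' that cannot be rewritten consistently are left unchanged.
#'
#' @param aln alignment table (coordinate-sorted).
#' @return alignment table with updated `cigar` columns.
#' @export
realign_indels <- function(aln) {
  sl <- attr(aln, "seq_lengths")
  complex <- which(grepl("[ID]", aln$cigar))
  if (length(complex) == 0L) return(aln)
  a <- copy(aln)
  parsed <- parse_cigar(a$cigar[complex])
  ev <- rbindlist(lapply(seq_along(complex), function(i) {
    b <- cigar_blocks(parsed[[i]], a$pos[complex[i]])
    ii <- which(b$op %in% c("I", "D"))
    data.table(row = complex[i], op_idx = ii,
               type = fifelse(b$op[ii] == "I", "INS", "DEL"),
               len = b$len[ii], start = b$rstart[ii],
               rname = a$rname[complex[i]])
  }))
  setorder(ev, rname, type, len, start)
  ## group events reachable within the scan window of the first (leftmost)
  ## start of their cluster: 5 bp for insertions, len + 2 for deletions
  win <- fifelse(ev$type == "INS", 5L, ev$len + 2L)
  cluster <- integer(nrow(ev))
  cid <- 0L; anchor <- -1L
  for (i in seq_len(nrow(ev))) {
    newgrp <- i == 1L || ev$rname[i] != ev$rname[i - 1L] ||
      ev$type[i] != ev$type[i - 1L] || ev$len[i] != ev$len[i - 1L] ||
      ev$start[i] - anchor > win[i]
    if (newgrp) { cid <- cid + 1L; anchor <- ev$start[i] }
    cluster[i] <- cid
  }
  ev[, cluster_id := cluster]
  for (cl in ev[, unique(cluster_id[duplicated(cluster_id)])]) {
    sub <- ev[cluster_id == cl]
    support <- sub[, .N, by = start][order(-N, start)]
    target <- support$start[1L]
    for (j in which(sub$start != target)) {
      row <- sub$row[j]
      p <- parse_cigar(a$cigar[row])[[1]]
      b <- cigar_blocks(p, a$pos[row])
      oi <- which(b$rstart == sub$start[j] &
                    b$op == substr(sub$type[j], 1L, 1L) &
                    b$len == sub$len[j])[1]
      if (is.na(oi) || oi <= 1L || oi >= length(p$op)) next
      delta <- target - sub$start[j]
      if (p$op[oi - 1L] != "M" || p$op[oi + 1L] != "M") next
      newL <- p$len[oi - 1L] + delta
      newR <- p$len[oi + 1L] - delta
      if (newL < 1L || newR < 1L) next
      len2 <- p$len; len2[oi - 1L] <- newL; len2[oi + 1L] <- newR
      a$cigar[row] <- build_cigar(len2, p$op)
    }
  }
  setattr(a, "seq_lengths", sl)
  a[]
}

## Internal: MAP genotype at one site as a compact row.
.site_call <- function(obs_allele, obs_qual, alleles, h) {
  cg <- call_genotype(obs_allele, obs_qual, alleles, ref_index = 1L, h = h)
  if (is.null(cg)) return(NULL)
  list(gt = paste(cg$gt, collapse = "/"), gq = cg$gq,
       posterior = cg$posterior, dp = cg$dp)
}

#' Genotype an indel column
#'
#' Applies the same likelihood/prior machinery as [call_genotype()] to an
#' indel site: the allele universe is the reference span plus the distinct
#' indel alleles observed at the (realigned) consensus start; reads spanning
#' the site without the indel count as reference observations with their
#' local base quality.  When more than two distinct indel alleles occur, the
#' two best-supported are kept.
#'
#' @param indel_alleles character vector of indel allele strings (one per
#'   supporting read; inserted bases for insertions, `D<len>` for
#'   deletions).
#' @param indel_quals phred qualities of the indel observations.
#' @param ref_quals phred qualities of spanning reference observations.
#' @param h prior heterozygosity rate.
#' @return as [call_genotype()], with an extra `alleles` element
#'   (`"REF"` first); `NULL` with zero observations.
#' @export
genotype_indel <- function(indel_alleles, indel_quals, ref_quals,
                           h = 0.001) {
  sup <- sort(table(indel_alleles), decreasing = TRUE)
  keep <- names(sup)[seq_len(min(2L, length(sup)))]
  drop <- !(indel_alleles %in% keep)
  if (any(drop)) {
    indel_alleles <- indel_alleles[!drop]
    indel_quals <- indel_quals[!drop]
  }
  alleles <- c("REF", keep)
  cg <- call_genotype(
    c(rep("REF", length(ref_quals)), indel_alleles),
    c(ref_quals, indel_quals), alleles, ref_index = 1L, h = h)
  if (is.null(cg)) return(NULL)
  c(cg, list(alleles = alleles))
}

#' Call SNVs and small indels from alignments
#'
#' End-to-end genotyping driver: filters the alignment stream (mapping
#' quality, secondary records, duplicate start capping), realigns indels to
#' consensus start sites, builds pileups, and genotypes candidate sites.
#'
#' @param aln alignment table.
#' @param reference named `DNAStringSet`.
#' @param h prior heterozygosity rate (default 0.001).
#' @param q_max base-quality cap (default 30).
#' @param max_per_start duplicate start cap (default 2).
#' @param ignore_last_n 3'-end bases ignored per read (default 0).
#' @param min_gq minimum genotype quality for emission (default 40).
#' @param min_mapping_quality minimum mapping quality for the genotyping
#'   stream (default 1; ambiguous MAPQ-0 placements never genotype).
#' @param emit_all also emit homozygous-reference genotypes for every
#'   covered site (default FALSE).
#' @param include_secondary use secondary alignment records (default FALSE).
#' @param realign run [realign_indels()] first (default TRUE).
#' @param max_alleles maximum alleles considered per site (default 4).
#' @return calls data.table: `rname`, `pos` (VCF position), `ref`, `alt`
#'   (comma-separated, "" for pure reference calls), `gt`, `gq`, `dp`,
#'   `posterior`, `type` ("SNV", "INS", "DEL", or "REF").
#' @export
call_variants <- function(aln, reference, h = 0.001, q_max = 30L,
                          max_per_start = 2L, ignore_last_n = 0L,
                          min_gq = 40L, min_mapping_quality = 1L,
                          emit_all = FALSE, include_secondary = FALSE,
                          realign = TRUE, max_alleles = 4L) {
  stream <- aln[mapq >= min_mapping_quality]
  if (!include_secondary) stream <- stream[secondary == FALSE]
  setattr(stream, "seq_lengths", attr(aln, "seq_lengths"))
  stream <- cap_start_duplicates(stream, max_per_start)
  if (realign) stream <- realign_indels(stream)

  out <- list()
  for (sq in unique(stream$rname)) {
    sub <- stream[rname == sq]
    refchars <- strsplit(as.character(reference[[sq]]), "", fixed = TRUE)[[1]]
    ## window the sequence so pileup expansion stays bounded in memory
    wsize <- 250000L
    starts <- seq(1L, max(sub$pos), by = wsize)
    for (ws in starts) {
      we <- ws + wsize - 1L
      rows <- sub[pos <= we & end_pos >= ws]
      if (nrow(rows) == 0L) next
      pile <- build_pileups(rows, ignore_last_n, q_max)
      pile$obs <- pile$obs[pos >= ws & pos <= we]
      pile$indels <- pile$indels[pos >= ws & pos <= we]
      out[[length(out) + 1L]] <-
        .genotype_window(pile, sq, refchars, h, min_gq, emit_all, max_alleles)
    }
  }
  calls <- rbindlist(out)
  if (nrow(calls) > 0L) calls[, pos := as.integer(pos)]
  if (nrow(calls) == 0L)
    return(data.table(rname = character(), pos = integer(), ref = character(),
                      alt = character(), gt = character(), gq = integer(),
                      dp = integer(), posterior = numeric(),
                      type = character()))
  setorder(calls, rname, pos)
  calls[]
}

## Genotype one pileup window on one sequence.
.genotype_window <- function(pile, sq, refchars, h, min_gq, emit_all,
                             max_alleles) {
  obs <- pile$obs[base %in% c("A", "C", "G", "T")]
  if (nrow(obs) > 0L) obs[, ref := refchars[pos]]
  rows <- list()
  if (nrow(obs) > 0L) {
    cand_pos <- if (emit_all) unique(obs$pos) else
      unique(obs[base != ref, pos])
    cand <- obs[pos %in% cand_pos]
    if (nrow(cand) > 0L) {
      snv <- cand[, {
        refb <- ref[1L]
        tab <- sort(table(base[base != refb]), decreasing = TRUE)
        alleles <- c(refb, names(tab))
        alleles <- alleles[seq_len(min(length(alleles), max_alleles))]
        if (length(alleles) == 1L)
          alleles <- c(alleles, setdiff(c("A", "C", "G", "T"), alleles)[1L])
        sc <- .site_call(base, qual, alleles, h)
        if (is.null(sc)) NULL else {
          idx <- as.integer(strsplit(sc$gt, "/")[[1]])
          emitted <- sort(base::unique(idx[idx > 0L]))
          newidx <- ifelse(idx == 0L, 0L, match(idx, emitted))
          list(gt = paste(sort(newidx), collapse = "/"), gq = sc$gq,
               posterior = sc$posterior, dp = sc$dp, ref = refb,
               alt = paste(alleles[emitted + 1L], collapse = ","))
        }
      }, by = pos]
      if (nrow(snv) > 0L) {
        snv[, rname := sq]
        snv[, type := fifelse(gt == "0/0", "REF", "SNV")]
        rows[[length(rows) + 1L]] <- snv
      }
    }
  }
  ind <- pile$indels
  if (nrow(ind) > 0L) {
    for (p in unique(ind$pos)) {
      ev <- ind[pos == p]
      ## keep the two best-supported indel alleles at this start
      sup <- ev[, .N, by = .(allele, type, len)][order(-N, allele)]
      if (nrow(sup) > 2L) sup <- sup[1:2]
      ev <- ev[allele %in% sup$allele]
      ## reference support must SPAN the junction: a read aligned at both
      ## p-1 and p crossed the event site without the indel; reads merely
      ## starting at p carry no information about an insertion before p
      ref_obs <- if (nrow(obs) > 0L) {
        anchored <- obs[pos == p - 1L, read_id]
        obs[pos == p & read_id %in% anchored &
              !(read_id %in% ev$read_id)]
      } else obs
      alleles <- c("REF", sup$allele)
      oa <- c(rep("REF", nrow(ref_obs)), ev$allele)
      oq <- c(ref_obs$qual, ev$qual)
      sc <- .site_call(oa, oq, alleles, h)
      if (is.null(sc) || sc$gt == "0/0") next
      ## VCF-style left-anchored representation
      anchor <- p - 1L
      if (anchor < 1L) next
      idx <- as.integer(strsplit(sc$gt, "/")[[1]])
      emitted <- sort(base::unique(idx[idx > 0L]))  # rows of `sup`
      reflen <- 1L
      for (ai in emitted)
        if (sup$type[ai] == "DEL") reflen <- max(reflen, sup$len[ai] + 1L)
      if (anchor + reflen - 1L > length(refchars)) next
      refstr <- paste(refchars[anchor:(anchor + reflen - 1L)], collapse = "")
      alts <- vapply(emitted, function(ai) {
        if (sup$type[ai] == "DEL")
          paste0(substr(refstr, 1L, 1L),
                 if (reflen > sup$len[ai] + 1L)
                   substr(refstr, sup$len[ai] + 2L, reflen) else "")
        else
          paste0(substr(refstr, 1L, 1L), sup$allele[ai],
                 substr(refstr, 2L, reflen))
      }, character(1))
      newidx <- ifelse(idx == 0L, 0L, match(idx, emitted))
      rows[[length(rows) + 1L]] <- data.table(
        pos = anchor, gt = paste(sort(newidx), collapse = "/"),
        gq = sc$gq, posterior = sc$posterior, dp = sc$dp,
        ref = refstr, alt = paste(alts, collapse = ","),
        rname = sq, type = sup$type[emitted[1L]])
    }
  }
  if (length(rows) == 0L) return(NULL)
  calls <- rbindlist(rows, use.names = TRUE, fill = TRUE)
  calls[gt == "0/0", alt := ""]
  calls <- calls[gq >= min_gq]
  calls <- calls[type != "REF" | emit_all]
  calls[, .(rname, pos, ref, alt, gt, gq = as.integer(gq),
            dp = as.integer(dp), posterior, type)]
}
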