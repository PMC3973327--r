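# Read-pair discovery of large deletions and mid-size insertions from
# insert-length outliers, with Poisson significance (BreakDancerMax model).

#' Estimate the insert-length distribution
#'
#' Uses unique, properly oriented pairs only (one record per pair, positive
#' template length), discards the 1% most extreme template lengths, and
#' returns mean and standard deviation.  Deterministic for a fixed input.
#'
#' @param aln alignment table.
#' @param min_pairs minimum usable pairs (default 1000).
#' @return list with `mu`, `sigma` (floored at 1e-6), `n_pairs`,
#'   `genome_size` (from the `seq_lengths` attribute, when present).
#' @export
estimate_insert_distribution <- function(aln, min_pairs = 1000L) {
  pairs <- aln[paired == TRUE & proper == TRUE & unique_aln == TRUE &
                 tlen > 0L]
  if (nrow(pairs) < min_pairs)
    stop(sprintf("only %d unique proper pairs; need >= %d",
                 nrow(pairs), min_pairs))
  tl <- pairs$tlen
  qs <- stats::quantile(tl, c(0.005, 0.995), names = FALSE, type = 1)
  tl <- tl[tl >= qs[1] & tl <= qs[2]]
  sl <- attr(aln, "seq_lengths")
  list(mu = mean(tl), sigma = max(stats::sd(tl), 1e-6), n_pairs = length(tl),
       genome_size = if (is.null(sl)) NA_real_ else sum(as.numeric(sl)))
}

#' Cluster discordant read pairs
#'
#' Pairs whose template length deviates from the library mean by more than
#' `t` standard deviations are clustered greedily by genomic overlap of
#' their spans and by insert-length agreement (each member within
#' `2*sigma` of the cluster's running mean insert).  LONGER-than-average clusters support deletions, SHORTER
#' clusters support insertions.  Clusters with fewer than 2 pairs are
#' dropped.
#'
#' @param aln alignment table (coordinate-sorted).
#' @param dist insert distribution from [estimate_insert_distribution()].
#' @param t standard-deviation multiplier (default 3).
#' @param min_mapping_quality minimum mapping quality (default 10).
#' @return list of clusters; each is a list with `rname`, `direction`
#'   (`"LONGER"`/`"SHORTER"`), `k`, `pairs` (data.table `pos`, `end_pos`,
#'   `mate_pos`, `insert_len`), `inner_first`, `inner_last`.  The total
#'   number of discordant pairs genome-wide is attached as attribute
#'   `n_discordant`.
#' @export
cluster_discordant_pairs <- function(aln, dist, t = 3,
                                     min_mapping_quality = 10L) {
  cand <- aln[paired == TRUE & unique_aln == TRUE &
                mapq >= min_mapping_quality & tlen > 0L]
  cand <- cand[abs(tlen - dist$mu) > t * dist$sigma]
  clusters <- list()
  n_disc <- nrow(cand)
  if (n_disc > 0L) {
    cand[, insert_len := tlen]
    cand[, `:=`(span_first = pos, span_last = pos + tlen - 1L)]
    cand[, direction := fifelse(tlen > dist$mu, "LONGER", "SHORTER")]
    setorder(cand, rname, span_first)
    for (dir in base::unique(cand$direction)) {
      for (sq in base::unique(cand$rname)) {
        sub <- cand[direction == dir & rname == sq]
        if (nrow(sub) == 0L) next
        cur <- integer(0)
        lo <- -Inf; hi <- Inf; isum <- 0
        flush <- function(rows) {
          if (length(rows) >= 2L) {
            pr <- sub[rows]
            clusters[[length(clusters) + 1L]] <<- list(
              rname = sq, direction = dir, k = length(rows),
              pairs = pr[, .(pos, end_pos,
                             mate_pos = pnext, insert_len)],
              inner_first = max(pr$end_pos) + 1L,
              inner_last = min(pr$pnext) - 1L)
          }
        }
        for (i in seq_len(nrow(sub))) {
          ## insert agreement is measured against the cluster's running
          ## mean: a strict pairwise-range rule splits genuine clusters
          ## as soon as k grows (the range of k iid inserts exceeds
          ## 2 sigma with high probability)
          ok <- length(cur) > 0L &&
            sub$span_first[i] <= hi && sub$span_last[i] >= lo &&
            abs(sub$insert_len[i] - isum / length(cur)) <= 2 * dist$sigma
          if (ok) {
            cur <- c(cur, i)
            lo <- max(lo, sub$span_first[i]); hi <- min(hi, sub$span_last[i])
            isum <- isum + sub$insert_len[i]
          } else {
            flush(cur)
            cur <- i
            lo <- sub$span_first[i]; hi <- sub$span_last[i]
            isum <- sub$insert_len[i]
          }
        }
        flush(cur)
      }
    }
  }
  structure(clusters, n_discordant = n_disc)
}

#' Poisson tail probability for a cluster
#'
#' Upper-tail `P(X >= k)` for `X ~ Poisson(lambda)`.
#'
#' @param k observed supporting pair count.
#' @param lambda expected count.
#' @return tail probability.
#' @export
poisson_tail <- function(k, lambda) {
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Call large deletions and mid-size insertions from pair clusters
#'
#' The event length is the mean insert length of the supporting pairs minus
#' the library mean (absolute value); the event region is the interval
#' between the innermost read ends.  Significance follows the BreakDancerMax
#' Poisson model: `lambda = D * (span + mu) / G` where `D` is the total
#' number of discordant pairs genome-wide and `G` the genome size; the
#' p-value is the upper Poisson tail at the cluster size `k`.
#'
#' @param clusters from [cluster_discordant_pairs()].
#' @param dist insert distribution (needs `genome_size`).
#' @param alpha significance level (default 0.001).
#' @return SV call table: `rname`, `first`, `last`, `type` ("DEL"/"INS"),
#'   `length`, `k`, `p_value`, `source` ("RP").
#' @export
call_large_indels <- function(clusters, dist, alpha = 0.001) {
  empty <- data.table(rname = character(), first = integer(),
                      last = integer(), type = character(),
                      length = numeric(), k = integer(), p_value = numeric(),
                      source = character())
  if (length(clusters) == 0L) return(empty)
  D <- attr(clusters, "n_discordant")
  G <- dist$genome_size
  rows <- lapply(clusters, function(cl) {
    mean_ins <- mean(cl$pairs$insert_len)
    first <- cl$inner_first
    last <- cl$inner_last
    if (last < first) { mid <- (first + last) %/% 2L; first <- mid; last <- mid + 1L }
    span <- last - first + 1L
    lambda <- D * (span + dist$mu) / G
    data.table(rname = cl$rname, first = first, last = last,
               type = if (cl$direction == "LONGER") "DEL" else "INS",
               length = abs(mean_ins - dist$mu), k = cl$k,
               p_value = poisson_tail(cl$k, lambda), source = "RP")
  })
  out <- rbindlist(rows)
  out <- out[p_value < alpha]
  setorder(out, rname, first)
  out[]
}

#' Combine read-depth and read-pair structural-variant calls
#'
#' Union of both call sets; deletion calls with reciprocal overlap of at
#' least `min_reciprocal` are merged into one record with
#' `source = "combined"` and the tighter (intersection) breakpoints.
#'
#' @param cnv_calls RD calls ([call_cnvs()]).
#' @param sv_calls RP calls ([call_large_indels()]).
#' @param min_reciprocal reciprocal-overlap threshold (default 0.5).
#' @return unified call table with columns `rname`, `first`, `last`,
#'   `type`, `source` plus whatever metric columns each source provides.
#' @export
combine_rd_rp <- function(cnv_calls, sv_calls, min_reciprocal = 0.5) {
  rd <- if (is.null(cnv_calls)) data.table() else copy(cnv_calls)
  rp <- if (is.null(sv_calls)) data.table() else copy(sv_calls)
  if (nrow(rd) == 0L) return(rp)
  if (nrow(rp) == 0L) return(rd)
  rd_del <- which(rd$type == "DEL")
  rp_del <- which(rp$type == "DEL")
  drop_rp <- integer(0)
  for (i in rd_del) {
    for (j in setdiff(rp_del, drop_rp)) {
      if (rp$rname[j] != rd$rname[i]) next
      ov <- min(rd$last[i], rp$last[j]) - max(rd$first[i], rp$first[j]) + 1L
      if (ov <= 0L) next
      w1 <- rd$last[i] - rd$first[i] + 1L
      w2 <- rp$last[j] - rp$first[j] + 1L
      if (ov / w1 >= min_reciprocal && ov / w2 >= min_reciprocal) {
        rd$first[i] <- max(rd$first[i], rp$first[j])
        rd$last[i] <- min(rd$last[i], rp$last[j])
        rd$source[i] <- "combined"
        drop_rp <- c(drop_rp, j)
      }
    }
  }
  if (length(drop_rp) > 0L) rp <- rp[-drop_rp]
  out <- rbindlist(list(rd, rp), use.names = TRUE, fill = TRUE)
  setorder(out, rname, first)
  out[]
}
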