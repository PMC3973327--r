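# Read-depth CNV discovery: binning, GC correction over uniquely mappable
# bins, mean-shift segmentation, significance calling with neutral-gap
# merging, and a Gaussian second pass for deletions.

#' Bin read depth along the reference
#'
#' The depth of a bin is the number of alignment starts falling in it (all
#' records, including multiple/ambiguous placements).  A bin is `is_unique`
#' when no overlapping record is flagged as a multiple placement; mean and
#' variance of the neutral signal are later computed over those bins only,
#' so samples recorded with multiple alignments stay processable.
#'
#' @param aln alignment table.
#' @param reference named `DNAStringSet`; the genome size is taken from it.
#' @param b bin size in bp (default 100, must be >= 10).
#' @return `RD signal` data.table: `rname`, `bin_index`, `first`, `last`,
#'   `gc_percent`, `raw_depth`, `corrected_depth` (initialised to raw),
#'   `is_unique`.  Bin size kept as attribute `bin_size`.
#' @export
bin_depth <- function(aln, reference, b = 100L) {
  stopifnot(b >= 10L)
  if (!all(unique(aln$rname) %in% names(reference)))
    stop("alignment sequence name missing from the reference")
  out <- list()
  for (sq in names(reference)) {
    len <- length(reference[[sq]])
    nb <- as.integer(ceiling(len / b))
    firsts <- (seq_len(nb) - 1L) * b + 1L
    lasts <- pmin(firsts + b - 1L, len)
    sub <- aln[rname == sq]
    depth <- tabulate(((sub$pos - 1L) %/% b) + 1L, nbins = nb)
    uniq <- rep(TRUE, nb)
    multi <- sub[multiple == TRUE]
    if (nrow(multi) > 0L) {
      b1 <- ((multi$pos - 1L) %/% b) + 1L
      b2 <- pmin(((multi$end_pos - 1L) %/% b) + 1L, nb)
      span <- b2 - b1 + 1L
      uniq[rep(b1, span) + sequence(span) - 1L] <- FALSE
    }
    v <- Biostrings::Views(reference[[sq]], start = firsts, end = lasts)
    gc <- as.integer(round(100 *
      Biostrings::letterFrequency(v, "GC") / (lasts - firsts + 1L)))
    out[[sq]] <- data.table(rname = sq, bin_index = seq_len(nb),
                            first = firsts, last = lasts, gc_percent = gc,
                            raw_depth = as.numeric(depth),
                            corrected_depth = as.numeric(depth),
                            is_unique = uniq)
  }
  sig <- rbindlist(out)
  setattr(sig, "bin_size", as.integer(b))
  sig[]
}

#' GC-content correction of the read-depth signal
#'
#' Bins are grouped by integer GC percentage; each class with enough
#' uniquely mappable bins is rescaled by `m_global / m_gc`, where `m_global`
#' is the mean raw depth over all unique bins and `m_gc` the mean over the
#' unique bins of the class.  Classes with fewer than `min_class_bins`
#' unique bins or with `m_gc < 0.1 * m_global` are left uncorrected (the
#' scaling would be unstable).
#'
#' @param signal RD signal from [bin_depth()].
#' @param min_class_bins minimum unique bins per GC class (default 100).
#' @return signal with `corrected_depth` updated.
#' @export
gc_correct <- function(signal, min_class_bins = 100L) {
  sig <- copy(signal)
  u <- sig[is_unique == TRUE]
  if (nrow(u) == 0L) return(sig)
  m_global <- mean(u$raw_depth)
  cls <- u[, .(m_gc = mean(raw_depth), n = .N), by = gc_percent]
  cls <- cls[n >= min_class_bins & m_gc >= 0.1 * m_global]
  if (nrow(cls) > 0L) {
    cls[, factor := m_global / m_gc]
    sig[cls, corrected_depth := raw_depth * i.factor, on = "gc_percent"]
  }
  setattr(sig, "bin_size", attr(signal, "bin_size"))
  sig[]
}

#' Mean and standard deviation of the neutral read depth
#'
#' Computed over the corrected depths of uniquely mappable bins only.
#'
#' @param signal RD signal (after [gc_correct()]).
#' @return list with `mu` and `sigma` (population standard deviation).
#' @export
neutral_stats <- function(signal) {
  u <- signal[is_unique == TRUE]
  if (nrow(u) < 30L)
    stop("fewer than 30 unique bins; read-depth signal unusable")
  list(mu = mean(u$corrected_depth), sigma = pop_sd(u$corrected_depth))
}

## Mean-shift vector for one depth vector at bandwidth H.
.mean_shift_vector <- function(r, H, mu, sigma) {
  n <- length(r)
  s2 <- pmax(sigma^2 * pmax(r, 0.1 * mu) / max(mu, 1e-9), 1e-9)
  v <- numeric(n)
  maxd <- min(3L * H, n - 1L)
  for (d in seq_len(maxd)) {
    kd <- d * exp(-d^2 / (2 * H^2))
    i <- seq_len(n - d)
    w <- exp(-(r[i + d] - r[i])^2 / (2 * (s2[i + d] + s2[i])))
    v[i] <- v[i] + kd * w
    v[i + d] <- v[i + d] - kd * w
  }
  v
}

#' Mean-shift segmentation of the read-depth signal
#'
#' The signal of each sequence is smoothed with Gaussian kernels over an
#' increasing bandwidth schedule.  At each bandwidth the mean-shift vector
#' is computed per bin (positive = attracted rightwards); a boundary is put
#' between bins `i` and `i+1` where the vector changes sign from negative to
#' positive.  Segments whose mean deviates from the neutral mean by at least
#' `2*sigma/sqrt(len)` are frozen; unfrozen boundaries dissolve, so a
#' neutral background collapses into a single segment per sequence.
#'
#' @param signal RD signal (after [gc_correct()]).
#' @param mu,sigma neutral depth statistics from [neutral_stats()]; computed
#'   from `signal` when omitted.
#' @param bandwidths bandwidth schedule in bins.
#' @param merge_alpha after freezing, adjacent segments whose bin means are
#'   not significantly different at this level (Welch test) are merged, so
#'   spuriously frozen noise segments dissolve back into the background
#'   (default 0.001; real copy-number steps differ at far smaller levels).
#' @return segment table: `rname`, `start_bin`, `end_bin`, `first`, `last`,
#'   `n_bins`, `seg_mean` (mean corrected depth), `frozen`.
#' @export
segment_depth <- function(signal, mu = NULL, sigma = NULL,
                          bandwidths = c(2L, 4L, 8L, 16L, 32L, 64L, 128L),
                          merge_alpha = 0.001) {
  if (is.null(mu) || is.null(sigma)) {
    ns <- neutral_stats(signal)
    mu <- ns$mu; sigma <- ns$sigma
  }
  out <- list()
  for (sq in unique(signal$rname)) {
    sub <- signal[rname == sq]
    r <- sub$corrected_depth
    n <- length(r)
    frozen_bounds <- integer(0)  # boundary after bin i
    for (H in bandwidths[bandwidths < n]) {
      v <- .mean_shift_vector(r, H, mu, sigma)
      breaks <- which(v[-n] < 0 & v[-1] > 0)
      bounds <- sort(base::unique(c(frozen_bounds, breaks)))
      starts <- c(1L, bounds + 1L)
      ends <- c(bounds, n)
      for (si in seq_along(starts)) {
        seg <- starts[si]:ends[si]
        len <- length(seg)
        if (abs(mean(r[seg]) - mu) >= 2 * sigma / sqrt(len)) {
          fb <- c(starts[si] - 1L, ends[si])
          frozen_bounds <- base::union(frozen_bounds,
                                       fb[fb >= 1L & fb < n])
        }
      }
    }
    ## dissolve boundaries between segments that are not significantly
    ## different from each other (keeps noise out of the partition)
    bounds <- .merge_similar_segments(r, sort(frozen_bounds), sigma,
                                      merge_alpha)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    seg <- data.table(rname = sq, start_bin = starts, end_bin = ends)
    seg[, `:=`(first = sub$first[start_bin], last = sub$last[end_bin],
               n_bins = end_bin - start_bin + 1L)]
    seg[, seg_mean := vapply(seq_len(.N), function(i)
      mean(r[starts[i]:ends[i]]), numeric(1))]
    seg[, frozen := abs(seg_mean - mu) >= 2 * sigma / sqrt(n_bins)]
    out[[sq]] <- seg
  }
  rbindlist(out)
}

## p-value for "segments x and y have the same mean": Welch t-test when
## both have >= 2 bins, else a z-test using the neutral sigma.
.seg_diff_p <- function(x, y, sigma) {
  z <- (mean(x) - mean(y)) /
    max(sigma * sqrt(1 / length(x) + 1 / length(y)), 1e-12)
  pz <- 2 * stats::pnorm(-abs(z))
  pw <- if (length(x) >= 2L && length(y) >= 2L &&
            (stats::sd(x) > 0 || stats::sd(y) > 0)) {
    ## Welch loses nearly all power at tiny segment sizes (df ~ n-1), so
    ## the z-test against the neutral sigma backs it up
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  } else 1
  min(1, 2 * min(pw, pz))
}

## Iteratively remove the least significant boundary until every remaining
## boundary separates segments that differ at `merge_alpha`.
.merge_similar_segments <- function(r, bounds, sigma, merge_alpha) {
  n <- length(r)
  repeat {
    if (length(bounds) == 0L) return(bounds)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    ## each boundary was selected among all split positions of its local
    ## window, so its survival test is Bonferroni-corrected by that count
    pv <- vapply(seq_along(bounds), function(i) {
      x <- r[starts[i]:ends[i]]
      y <- r[starts[i + 1L]:ends[i + 1L]]
      min(1, .seg_diff_p(x, y, sigma) * (length(x) + length(y)))
    }, numeric(1))
    worst <- which.max(pv)
    if (pv[worst] <= merge_alpha) return(bounds)
    bounds <- bounds[-worst]
  }
}

## Refine one call's bin edges by maximising local step contrast within
## +-`win` bins (flank mean vs segment-side mean over `flank` bins).
.refine_edges <- function(r, sb, eb, win = 6L, flank = 10L) {
  n <- length(r)
  fl <- max(2L, min(flank, eb - sb + 1L))  # never wider than the segment
  score_left <- function(c) {
    lo <- max(1L, c - fl); hi <- min(n, c + fl - 1L)
    if (c - 1L < lo || c > hi) return(-Inf)
    abs(mean(r[c:hi]) - mean(r[lo:(c - 1L)]))
  }
  cand <- max(2L, sb - win):min(eb, sb + win)
  sb2 <- cand[which.max(vapply(cand, score_left, numeric(1)))]
  score_right <- function(c) {
    lo <- max(1L, c - fl + 1L); hi <- min(n, c + fl)
    if (c + 1L > hi || c < lo) return(-Inf)
    abs(mean(r[lo:c]) - mean(r[(c + 1L):hi]))
  }
  cand <- max(sb2, eb - win):min(n - 1L, eb + win)
  eb2 <- cand[which.max(vapply(cand, score_right, numeric(1)))]
  c(sb2, max(sb2, eb2))
}

## Two-sided one-sample t-test p-value of bins against mu.
.t_p_value <- function(x, mu) {
  n <- length(x)
  if (n < 2L) return(1)
  s <- stats::sd(x)
  m <- mean(x)
  if (s == 0) return(if (isTRUE(all.equal(m, mu))) 1 else 0)
  2 * stats::pt(-abs((m - mu) / (s / sqrt(n))), df = n - 1L)
}

## Genome-corrected segment significance (CNVnator-style e-value): the
## larger of the within-segment t-test and a z-test with the neutral sigma
## (guards against degenerate within-segment variance on short selected
## runs), multiplied by the genome-to-segment size ratio.
.segment_p <- function(x, mu, sigma, total_bins) {
  pz <- 2 * stats::pnorm(-abs(mean(x) - mu) /
                           max(sigma / sqrt(length(x)), 1e-12))
  p <- max(.t_p_value(x, mu), pz)
  min(1, p * total_bins / length(x))
}

#' Call CNVs from depth segments
#'
#' A segment is a deletion/duplication candidate when a one-sample t-test
#' of its bins against the neutral mean is significant and its mean is
#' below/above the neutral mean; single-bin segments are never called.
#' Significance is genome-corrected: the reported p-value is the raw test
#' probability multiplied by the genome-to-segment size ratio (an e-value
#' in the CNVnator tradition), so short noise runs selected by the
#' segmentation cannot reach significance.
#' Adjacent calls of the same type separated by a neutral gap shorter than
#' half the shorter call are merged only when the merged region is itself
#' significant.  A Gaussian second pass adds deletions where a run of at
#' least 3 bins stays below `mu - 3*sigma`, but never overriding (or
#' overlapping) deletions from the standard pass.
#'
#' @param signal RD signal.
#' @param segments from [segment_depth()].
#' @param mu,sigma neutral statistics.
#' @param ploidy sample ploidy (default 2).
#' @param alpha per-segment significance level (default 0.05).
#' @param min_copy_diff minimum copy-number deviation from ploidy for a
#'   call (default 0.5, i.e. mean depth at least a quarter off neutral for
#'   a diploid); suppresses statistically significant but biologically
#'   meaningless sub-half-copy shifts such as residual GC-scaling noise.
#' @param min_call_bins minimum segment length in bins for a standard-pass
#'   call (default 2; single-bin segments are never callable).
#' @return CNV call table: `rname`, `first`, `last`, `type` ("DEL"/"DUP"),
#'   `copies`, `p_value`, `n_bins`, `source` ("RD").
#' @export
call_cnvs <- function(signal, segments, mu, sigma, ploidy = 2L,
                      alpha = 0.05, min_copy_diff = 0.5,
                      min_call_bins = 2L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  total_bins <- nrow(signal)
  calls <- list()
  for (sq in unique(segments$rname)) {
    r <- signal[rname == sq, corrected_depth]
    sub <- segments[rname == sq]
    cand <- list()
    for (i in seq_len(nrow(sub))) {
      if (sub$n_bins[i] < max(2L, min_call_bins)) next
      x <- r[sub$start_bin[i]:sub$end_bin[i]]
      p <- .segment_p(x, mu, sigma, total_bins)
      m <- mean(x)
      if (p < alpha && abs(ploidy * m / mu - ploidy) >= min_copy_diff) {
        ed <- .refine_edges(r, sub$start_bin[i], sub$end_bin[i])
        m2 <- mean(r[ed[1]:ed[2]])
        cand[[length(cand) + 1L]] <- data.table(
          rname = sq, start_bin = ed[1], end_bin = ed[2],
          type = if (m < mu) "DEL" else "DUP",
          copies = ploidy * m2 / mu, p_value = p)
      }
    }
    if (length(cand) == 0L) next
    cc <- rbindlist(cand)
    setorder(cc, start_bin)
    ## neutral-gap merging (modification: merged region must stay significant)
    repeat {
      merged <- FALSE
      if (nrow(cc) >= 2L) for (i in seq_len(nrow(cc) - 1L)) {
        if (cc$type[i] != cc$type[i + 1L]) next
        gap <- cc$start_bin[i + 1L] - cc$end_bin[i] - 1L
        len1 <- cc$end_bin[i] - cc$start_bin[i] + 1L
        len2 <- cc$end_bin[i + 1L] - cc$start_bin[i + 1L] + 1L
        if (gap >= min(len1, len2) / 2) next
        x <- r[cc$start_bin[i]:cc$end_bin[i + 1L]]
        p <- .segment_p(x, mu, sigma, total_bins)
        if (p < alpha) {
          cc$end_bin[i] <- cc$end_bin[i + 1L]
          cc$p_value[i] <- p
          cc$copies[i] <- ploidy * mean(x) / mu
          cc <- cc[-(i + 1L)]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    calls[[length(calls) + 1L]] <- cc
  }
  std <- if (length(calls) > 0L) rbindlist(calls) else
    data.table(rname = character(), start_bin = integer(),
               end_bin = integer(), type = character(), copies = numeric(),
               p_value = numeric())

  ## Gaussian second pass for deep deletions
  extra <- list()
  for (sq in unique(signal$rname)) {
    r <- signal[rname == sq, corrected_depth]
    low <- r < mu - 3 * sigma
    if (!any(low)) next
    rl <- rle(low)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    runs <- which(rl$values & rl$lengths >= 3L)
    for (ri in runs) {
      sb <- starts[ri]; eb <- ends[ri]
      ovl <- std[rname == sq & type == "DEL" &
                   start_bin <= eb & end_bin >= sb]
      if (nrow(ovl) > 0L) next
      x <- r[sb:eb]
      pg <- min(1, stats::pnorm((mean(x) - mu) / (sigma / sqrt(length(x)))) *
                  total_bins / length(x))
      if (pg >= alpha) next
      extra[[length(extra) + 1L]] <- data.table(
        rname = sq, start_bin = sb, end_bin = eb, type = "DEL",
        copies = ploidy * mean(x) / mu, p_value = pg)
    }
  }
  allc <- rbindlist(c(list(std), extra))
  if (nrow(allc) == 0L)
    return(data.table(rname = character(), first = integer(),
                      last = integer(), type = character(),
                      copies = numeric(), p_value = numeric(),
                      n_bins = integer(), source = character()))
  ## bin coordinates -> genomic coordinates
  allc <- merge(allc,
                signal[, .(rname, bin_index, first, last)],
                by.x = c("rname", "start_bin"),
                by.y = c("rname", "bin_index"), sort = FALSE)
  setnames(allc, "first", "gstart")
  allc[, last := NULL]
  allc <- merge(allc,
                signal[, .(rname, bin_index, last)],
                by.x = c("rname", "end_bin"),
                by.y = c("rname", "bin_index"), sort = FALSE)
  res <- allc[, .(rname, first = gstart, last,
                  type, copies, p_value,
                  n_bins = end_bin - start_bin + 1L, source = "RD")]
  setorder(res, rname, first)
  res[]
}

#' Run the full read-depth CNV caller
#'
#' Convenience wrapper: [gc_correct()], [neutral_stats()],
#' [segment_depth()], [call_cnvs()].
#'
#' @inheritParams call_cnvs
#' @inheritParams gc_correct
#' @return CNV call table (see [call_cnvs()]).
#' @export
discover_cnvs <- function(signal, ploidy = 2L, alpha = 0.05,
                          min_class_bins = 100L, min_copy_diff = 0.5,
                          min_call_bins = 2L) {
  sig <- gc_correct(signal, min_class_bins)
  ns <- neutral_stats(sig)
  seg <- segment_depth(sig, ns$mu, ns$sigma)
  call_cnvs(sig, seg, ns$mu, ns$sigma, ploidy, alpha, min_copy_diff,
            min_call_bins)
}

#' Compare multi-alignment strategies over known repeats
#'
#' For each alignment strategy's RD signal, runs the CNV caller and reports
#' which fraction of the truth repeat bases ends up called duplicated,
#' deleted, or neutral.
#'
#' @param signals named list of RD signals (one per strategy).
#' @param repeat_truth data.table of truth regions (`rname`,`first`,`last`).
#' @param ploidy,alpha passed to [discover_cnvs()].
#' @return data.table: `strategy`, `frac_dup`, `frac_del`, `frac_neutral`.
#' @export
multi_alignment_strategy_report <- function(signals, repeat_truth,
                                            ploidy = 2L, alpha = 0.05) {
  rbindlist(lapply(names(signals), function(st) {
    cnvs <- discover_cnvs(signals[[st]], ploidy = ploidy, alpha = alpha)
    dup <- interval_coverage(cnvs[type == "DUP"], repeat_truth)
    del <- interval_coverage(cnvs[type == "DEL"], repeat_truth)
    data.table(strategy = st,
               frac_dup = dup$covered / dup$total,
               frac_del = del$covered / del$total,
               frac_neutral = 1 - (dup$covered + del$covered) / dup$total)
  }))
}
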