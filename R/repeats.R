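# Detection of repetitive regions from reads with multiple alignments.

#' Detect repetitive regions from multiply-mapped reads
#'
#' Overlapping alignments flagged as multiple placements are merged into
#' maximal candidate intervals; for each candidate the fraction of unique
#' alignments among all alignments overlapping it is computed, and the
#' region is emitted when that fraction is below `threshold`.  Unique reads
#' enter the denominator but do not extend the interval.
#'
#' @param aln alignment table (must include MAPQ-0/secondary records).
#' @param threshold maximum unique-alignment fraction (default 0.2).
#' @return data.table `rname`, `first`, `last`, `unique_fraction`,
#'   `alignment_count`; regions are disjoint and sorted.
#' @export
detect_repeats <- function(aln, threshold = 0.2) {
  empty <- data.table(rname = character(), first = integer(),
                      last = integer(), unique_fraction = numeric(),
                      alignment_count = integer())
  multi <- aln[multiple == TRUE]
  if (nrow(multi) == 0L) return(empty)
  cand <- GenomicRanges::reduce(GenomicRanges::GRanges(
    multi$rname, IRanges::IRanges(multi$pos, multi$end_pos)))
  allg <- GenomicRanges::GRanges(aln$rname,
                                 IRanges::IRanges(aln$pos, aln$end_pos))
  hits <- GenomicRanges::findOverlaps(cand, allg)
  qh <- S4Vectors::queryHits(hits)
  uq <- aln$unique_aln[S4Vectors::subjectHits(hits)]
  tot <- tabulate(qh, nbins = length(cand))
  nun <- tabulate(qh[uq], nbins = length(cand))
  frac <- ifelse(tot > 0L, nun / tot, 0)
  keep <- frac < threshold
  if (!any(keep)) return(empty)
  out <- data.table(
    rname = as.character(GenomicRanges::seqnames(cand))[keep],
    first = BiocGenerics::start(cand)[keep],
    last = BiocGenerics::end(cand)[keep],
    unique_fraction = frac[keep],
    alignment_count = tot[keep])
  setorder(out, rname, first)
  out[]
}

#' Base-level recall of repeat calls against truth regions
#'
#' @param calls repeat calls (`rname`,`first`,`last`), e.g. from
#'   [detect_repeats()].
#' @param truth truth regions on the same reference.
#' @return fraction of truth bases covered by calls, in \[0,1\].
#' @export
repeat_recall <- function(calls, truth) {
  cov <- interval_coverage(calls, truth)
  if (cov$total == 0) return(NA_real_)
  cov$covered / cov$total
}
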