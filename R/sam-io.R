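# Alignment input/output.  Reading goes through Rsamtools (SAM is converted
# to BAM on the fly); writing emits plain coordinate-sorted SAM text.

#' Read a coordinate-sorted SAM/BAM file into an alignment table
#'
#' Loads all alignment records, validates coordinate sorting and applies the
#' read-level admission filters: records whose mapping quality is below
#' `min_mapping_quality` are excluded unless they are flagged as
#' multiple/ambiguous placements (those are still needed by the repeat
#' detector and by the read-depth signal); secondary records are dropped
#' unless `include_secondary` is `TRUE`.
#'
#' @param path SAM or BAM file with `@SQ` headers.
#' @param min_mapping_quality minimum phred mapping quality for uniquely
#'   placed records (default 0 = keep everything).
#' @param include_secondary keep secondary alignment records (default TRUE;
#'   genotyping streams typically set this per run configuration).
#' @return a `data.table` with one row per record: `qname`, `flag`, `rname`,
#'   `pos`, `end_pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`,
#'   `qual` (ASCII-33 string), and logicals `secondary`, `reverse`,
#'   `paired`, `proper`, `first_of_pair`, `unique_aln` (primary, mapq > 0),
#'   `multiple` (secondary or mapq == 0).  The sequence dictionary is
#'   attached as attribute `seq_lengths`.
#' @export
read_alignments <- function(path, min_mapping_quality = 0L,
                            include_secondary = TRUE) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(
      path, destination = dest, overwrite = TRUE, indexDestination = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  seq_lengths <- hdr$targets
  if (length(seq_lengths) == 0L)
    stop("alignment file has no @SQ header lines")
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq", "qual")
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = what, tag = "NH"))[[1]]
  aln <- data.table(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    rnext = as.character(res$mrnm),
    pnext = as.integer(res$mpos),
    tlen = as.integer(res$isize),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    nh = if (!is.null(res$tag$NH)) as.integer(res$tag$NH) else NA_integer_
  )
  aln[is.na(nh), nh := 1L]
  aln <- aln[!is.na(pos)]          # drop unmapped
  if (nrow(aln) > 0L && anyNA(match(aln$rname, names(seq_lengths))))
    stop("alignment references unknown sequence name")
  aln[, mapq := fifelse(is.na(mapq) | mapq == 255L, 0L, mapq)]
  code <- match(aln$rname, names(seq_lengths))
  bad <- which(diff(code) < 0 | (diff(code) == 0 & diff(aln$pos) < 0))
  if (length(bad) > 0L) {
    i <- bad[1] + 1L
    stop(sprintf("input not coordinate-sorted: record %d (%s at %s:%d)",
                 i, aln$qname[i], aln$rname[i], aln$pos[i]))
  }
  aln[, `:=`(
    secondary = bitwAnd(flag, 256L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    paired = bitwAnd(flag, 1L) > 0L,
    proper = bitwAnd(flag, 2L) > 0L,
    first_of_pair = bitwAnd(flag, 64L) > 0L
  )]
  aln[, unique_aln := !secondary & mapq > 0L]
  ## "multiple" = the aligner reported more than one placement (secondary
  ## record, or NH > 1 on the primary); a low MAPQ alone does not qualify.
  aln[, multiple := secondary | nh > 1L]
  aln[, end_pos := pos + cigar_ref_width(cigar) - 1L]
  if (!include_secondary) aln <- aln[secondary == FALSE]
  if (min_mapping_quality > 0L)
    aln <- aln[mapq >= min_mapping_quality | multiple == TRUE]
  setattr(aln, "seq_lengths", seq_lengths)
  aln[]
}

#' Write an alignment table as coordinate-sorted SAM text
#'
#' @param aln alignment table (columns as produced by [read_alignments()] or
#'   the simulator).
#' @param path output `.sam` path.
#' @param seq_lengths named integer vector of reference sequence lengths;
#'   defaults to the `seq_lengths` attribute of `aln`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seq_lengths = attr(aln, "seq_lengths")) {
  stopifnot(!is.null(seq_lengths))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)))
  ord <- order(match(aln$rname, names(seq_lengths)), aln$pos)
  a <- aln[ord]
  rnext <- if ("rnext" %in% names(a)) a$rnext else "*"
  pnext <- if ("pnext" %in% names(a)) a$pnext else 0L
  rnext[is.na(rnext) | rnext == ""] <- "*"
  pnext[is.na(pnext)] <- 0L
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                   a$qname, a$flag, a$rname, a$pos, a$mapq, a$cigar,
                   rnext, pnext,
                   ifelse(is.na(a$tlen), 0L, a$tlen), a$seq, a$qual)
  if ("nh" %in% names(a))
    lines <- paste0(lines, sprintf("\tNH:i:%d",
                                   ifelse(is.na(a$nh), 1L, a$nh)))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Cap the number of reads starting at one reference site
#'
#' PCR amplification artifacts produce stacks of reads with identical start
#' coordinates.  Instead of duplicate marking, at most `max_per_start`
#' records are retained per (sequence, start, orientation) key, keeping the
#' first-seen records in file order so the result is deterministic.
#'
#' @param aln alignment table, coordinate-sorted.
#' @param max_per_start maximum records per start site and orientation
#'   (>= 1); default 2.
#' @return filtered alignment table (attributes preserved).
#' @export
cap_start_duplicates <- function(aln, max_per_start = 2L) {
  if (max_per_start < 1L) stop("max_per_start must be >= 1")
  sl <- attr(aln, "seq_lengths")
  idx <- aln[, .I[seq_len(.N) <= max_per_start],
             by = .(rname, pos, reverse)]$V1
  out <- aln[sort(idx)]
  setattr(out, "seq_lengths", sl)
  out[]
}
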