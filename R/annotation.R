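# Functional annotation of variant calls against gene models, plus
# region/quality filtering and call-set summaries.

EFFECT_SEVERITY <- c(intergenic = 1, intron = 2, synonymous = 3,
                     nonsynonymous = 4, inframe_indel = 5, nonsense = 6,
                     frameshift = 7)

#' Read gene models from GFF3
#'
#' Expects gene / mRNA (or transcript) / CDS features linked by `Parent`
#' attributes.  Transcripts whose CDS lengths do not sum to a multiple of 3
#' are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return list with `cds` (data.table `gene_id`, `transcript_id`,
#'   `strand`, `first`, `last`) and `genes` (`gene_id`, `rname`, `strand`,
#'   `first`, `last`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  typ <- as.character(mc$type)
  dt <- data.table(
    rname = as.character(GenomicRanges::seqnames(gr)),
    first = BiocGenerics::start(gr),
    last = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = typ,
    id = if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_,
    parent = if ("Parent" %in% names(mc))
      vapply(as.list(mc$Parent), function(p)
        if (length(p) == 0L) NA_character_ else as.character(p)[1],
        character(1)) else NA_character_)
  genes <- dt[type == "gene",
              .(gene_id = id, rname, strand, first, last)]
  tx <- dt[type %in% c("mRNA", "transcript"),
           .(transcript_id = id, gene_id = parent)]
  cds <- dt[type == "CDS", .(rname, first, last, strand,
                             transcript_id = parent)]
  cds <- merge(cds, tx, by = "transcript_id")
  bad <- cds[, .(tot = sum(last - first + 1L)), by = transcript_id][
    tot %% 3L != 0L, transcript_id]
  if (length(bad) > 0L) {
    warning(sprintf("skipping %d transcript(s) with CDS length not a multiple of 3",
                    length(bad)))
    cds <- cds[!(transcript_id %in% bad)]
  }
  setorder(cds, transcript_id, first)
  list(cds = cds[], genes = genes[])
}

## Spliced CDS sequence (coding orientation) of one transcript.
.spliced_cds <- function(cds_tx, reference) {
  pieces <- vapply(seq_len(nrow(cds_tx)), function(i)
    as.character(Biostrings::subseq(reference[[cds_tx$rname[i]]],
                                    cds_tx$first[i], cds_tx$last[i])),
    character(1))
  s <- paste(pieces, collapse = "")
  if (cds_tx$strand[1] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

## Offset (0-based, coding orientation) of genomic position `pos` within
## the spliced CDS, or NA when not in any CDS interval.
.cds_offset <- function(cds_tx, pos) {
  lens <- cds_tx$last - cds_tx$first + 1L
  cum <- cumsum(c(0L, lens))
  i <- which(pos >= cds_tx$first & pos <= cds_tx$last)
  if (length(i) == 0L) return(NA_integer_)
  plus_off <- cum[i] + (pos - cds_tx$first[i])
  if (cds_tx$strand[1] == "+") plus_off else sum(lens) - 1L - plus_off
}

## Effect of one call on one transcript.
.transcript_effect <- function(call, cds_tx, reference) {
  is_snv <- nchar(call$ref) == 1L && nchar(call$alt1) == 1L
  if (is_snv) {
    off <- .cds_offset(cds_tx, call$pos)
    if (is.na(off)) return(NA_character_)
    spliced <- .spliced_cds(cds_tx, reference)
    codon_i <- off %/% 3L
    codon <- substr(spliced, codon_i * 3L + 1L, codon_i * 3L + 3L)
    within <- off %% 3L + 1L
    base <- call$alt1
    if (cds_tx$strand[1] == "-")
      base <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(base)))
    mutated <- codon
    substr(mutated, within, within) <- base
    aa0 <- Biostrings::GENETIC_CODE[[codon]]
    aa1 <- Biostrings::GENETIC_CODE[[mutated]]
    if (aa1 == "*" && aa0 != "*") return("nonsense")
    if (aa1 == aa0) return("synonymous")
    return("nonsynonymous")
  }
  ## indel: affected interval (anchored VCF style, event after `pos`)
  ev_first <- call$pos + 1L
  ev_last <- max(call$pos + nchar(call$ref) - 1L, ev_first)
  hit <- any(ev_first <= cds_tx$last & ev_last >= cds_tx$first)
  if (!hit) return(NA_character_)
  indel_len <- abs(nchar(call$ref) - nchar(call$alt1))
  if (indel_len %% 3L != 0L) "frameshift" else "inframe_indel"
}

#' Annotate variant calls against gene models
#'
#' For each call and each overlapping transcript: SNVs inside CDS are
#' classified by codon translation (synonymous / nonsynonymous / nonsense,
#' reverse-complemented on minus-strand transcripts); indels inside CDS are
#' frameshift when their length is not a multiple of 3, else inframe;
#' variants inside a gene span but outside CDS are intronic; everything
#' else is intergenic.  The variant-level effect is the most severe across
#' transcripts (frameshift > nonsense > inframe > nonsynonymous >
#' synonymous > intron > intergenic).
#'
#' @param calls call table ([call_variants()] output).
#' @param models gene models from [read_gene_models()].
#' @param reference named `DNAStringSet`.
#' @return calls with `effect` and `gene_id` columns added.
#' @export
annotate_variants <- function(calls, models, reference) {
  out <- copy(calls)
  if (nrow(out) == 0L) {
    out[, `:=`(effect = character(), gene_id = character())]
    return(out[])
  }
  if (!all(out$rname %in% names(reference)))
    stop("call on a sequence missing from the reference")
  effects <- character(nrow(out))
  genes <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(out))) {
    call <- list(rname = out$rname[i], pos = out$pos[i], ref = out$ref[i],
                 alt1 = strsplit(out$alt[i], ",")[[1]][1])
    if (is.na(call$alt1)) call$alt1 <- call$ref
    g <- models$genes[rname == call$rname &
                        first <= call$pos & last >= call$pos]
    if (nrow(g) == 0L) { effects[i] <- "intergenic"; next }
    best <- "intron"
    best_gene <- g$gene_id[1]
    for (gid in g$gene_id) {
      cds_g <- models$cds[gene_id == gid]
      for (tid in base::unique(cds_g$transcript_id)) {
        eff <- .transcript_effect(call, cds_g[transcript_id == tid],
                                  reference)
        if (!is.na(eff) && EFFECT_SEVERITY[eff] > EFFECT_SEVERITY[best]) {
          best <- eff
          best_gene <- gid
        }
      }
    }
    effects[i] <- best
    genes[i] <- best_gene
  }
  out[, `:=`(effect = effects, gene_id = genes)]
  out[]
}

#' Filter calls by genotype quality and excluded regions
#'
#' Retains calls with `gq >= min_gq` whose position lies outside every
#' excluded region (typically repeats and CNVs); input order is preserved.
#' Idempotent, and the two criteria commute.
#'
#' @param calls call table.
#' @param min_gq minimum genotype quality (default 0).
#' @param exclude_regions data.table (`rname`,`first`,`last`) or NULL.
#' @return filtered call table.
#' @export
filter_calls <- function(calls, min_gq = 0L, exclude_regions = NULL) {
  out <- calls[is.na(gq) | gq >= min_gq]
  out <- out[!is.na(gq)]
  if (!is.null(exclude_regions) && nrow(exclude_regions) > 0L &&
      nrow(out) > 0L) {
    ex <- GenomicRanges::GRanges(
      exclude_regions$rname,
      IRanges::IRanges(exclude_regions$first, exclude_regions$last))
    qq <- GenomicRanges::GRanges(out$rname, IRanges::IRanges(out$pos, out$pos))
    hit <- IRanges::overlapsAny(qq, ex)
    out <- out[!hit]
  }
  out[]
}

#' Summary statistics of a call set
#'
#' Counts and percentages for heterozygous calls, effect classes and
#' excluded-region membership.  Denominators: heterozygosity over all
#' calls, nonsynonymous/nonsense over coding SNVs, frameshift over coding
#' indels.
#'
#' @param calls call table, optionally annotated ([annotate_variants()]).
#' @param exclude_regions optional regions (repeats/CNVs).
#' @return data.table `metric`, `count`, `denominator`, `percent`.
#' @export
summarize_calls <- function(calls, exclude_regions = NULL) {
  n <- nrow(calls)
  if (n == 0L)
    return(data.table(metric = "total", count = 0L, denominator = 0L,
                      percent = 0))
  is_het <- vapply(strsplit(calls$gt, "/"), function(x)
    length(base::unique(x)) > 1L, logical(1))
  res <- list(data.table(metric = "total", count = n, denominator = n,
                         percent = 100),
              data.table(metric = "heterozygous", count = sum(is_het),
                         denominator = n, percent = 100 * sum(is_het) / n))
  if ("effect" %in% names(calls)) {
    coding_snv <- calls$type == "SNV" &
      calls$effect %in% c("synonymous", "nonsynonymous", "nonsense")
    for (eff in c("nonsynonymous", "nonsense")) {
      cnt <- sum(calls$effect == eff & calls$type == "SNV")
      den <- sum(coding_snv)
      res[[length(res) + 1L]] <- data.table(
        metric = eff, count = cnt, denominator = den,
        percent = if (den > 0L) 100 * cnt / den else 0)
    }
    coding_indel <- calls$type %in% c("INS", "DEL") &
      calls$effect %in% c("frameshift", "inframe_indel")
    cnt <- sum(calls$effect == "frameshift")
    den <- sum(coding_indel)
    res[[length(res) + 1L]] <- data.table(
      metric = "frameshift", count = cnt, denominator = den,
      percent = if (den > 0L) 100 * cnt / den else 0)
  }
  if (!is.null(exclude_regions)) {
    inside <- n - nrow(filter_calls(calls, 0L, exclude_regions))
    res[[length(res) + 1L]] <- data.table(
      metric = "in_excluded_regions", count = inside, denominator = n,
      percent = 100 * inside / n)
  }
  rbindlist(res)
}
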