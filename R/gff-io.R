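# Integrated GFF3 output: repeats, CNVs and large indels in one file,
# written and read back through rtracklayer.

FEATURE_TYPES <- c(repeat_region = "repeat_region", DEL = "deletion",
                   DUP = "duplication", INS = "insertion")

#' Write structural features (repeats, CNVs, large indels) as GFF3
#'
#' @param features data.table with `rname`, `first`, `last`, `type`
#'   (`"repeat_region"`, `"DEL"`, `"DUP"`, `"INS"`), `source`, and optional
#'   numeric columns `copies`, `p_value`, `length`, `k`,
#'   `unique_fraction`.
#' @param path output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_sv_gff <- function(features, path) {
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  f <- copy(features)
  gr <- GenomicRanges::GRanges(f$rname, IRanges::IRanges(f$first, f$last))
  S4Vectors::mcols(gr)$source <- f$source
  S4Vectors::mcols(gr)$type <- unname(FEATURE_TYPES[f$type])
  for (col in intersect(c("copies", "p_value", "length", "k",
                          "unique_fraction"), names(f)))
    S4Vectors::mcols(gr)[[col]] <- f[[col]]
  S4Vectors::mcols(gr)$ID <- sprintf("sv%05d", seq_along(gr))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an integrated structural-variant GFF3 file
#'
#' Inverse of [write_sv_gff()]; numeric attributes are coerced back.
#'
#' @param path GFF3 file.
#' @return features data.table as documented in [write_sv_gff()].
#' @export
read_sv_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L)
    return(data.table(rname = character(), first = integer(),
                      last = integer(), type = character(),
                      source = character()))
  rev_types <- setNames(names(FEATURE_TYPES), FEATURE_TYPES)
  mc <- S4Vectors::mcols(gr)
  out <- data.table(
    rname = as.character(GenomicRanges::seqnames(gr)),
    first = BiocGenerics::start(gr),
    last = BiocGenerics::end(gr),
    type = unname(rev_types[as.character(mc$type)]),
    source = as.character(mc$source))
  for (col in c("copies", "p_value", "length", "unique_fraction"))
    if (col %in% names(mc))
      out[, (col) := suppressWarnings(as.numeric(as.character(mc[[col]])))]
  if ("k" %in% names(mc))
    out[, k := suppressWarnings(as.integer(as.character(mc$k)))]
  setorder(out, rname, first)
  out[]
}
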