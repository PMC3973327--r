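# VCF 4.x output/input.  Writing is plain text formatting; reading goes
# through VariantAnnotation and is converted back to the package's
# genotype-matrix data.table.

#' Convert a single-sample call table to a genotype matrix
#'
#' @param calls call table from [call_variants()].
#' @param sample sample name (default "sample1").
#' @return genotype-matrix data.table: `rname`, `pos`, `ref`, `alt` plus
#'   `gt_<sample>`, `gq_<sample>`, `dp_<sample>`.
#' @export
calls_to_matrix <- function(calls, sample = "sample1") {
  m <- calls[, .(rname, pos = as.integer(pos), ref, alt, gt,
                 gq = as.integer(gq), dp = as.integer(dp))]
  setnames(m, c("gt", "gq", "dp"),
           paste(c("gt", "gq", "dp"), sample, sep = "_"))
  m[]
}

## Sample names of a genotype matrix.
matrix_samples <- function(m) {
  sub("^gt_", "", grep("^gt_", names(m), value = TRUE))
}

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Emits GT, GQ and DP per sample; for single-sample files QUAL mirrors GQ.
#' Missing genotypes are written as `./.`.
#'
#' @param m genotype matrix (see [calls_to_matrix()] / [merge_vcfs()]).
#' @param path output path.
#' @param seq_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, seq_lengths = NULL) {
  samples <- matrix_samples(m)
  stopifnot(length(samples) >= 1L)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=vardiscover")
  if (!is.null(seq_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(seq_lengths), as.integer(seq_lengths)))
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  alt <- ifelse(is.na(m$alt) | m$alt == "", ".", m$alt)
  qual <- if (length(samples) == 1L) {
    gq <- m[[paste0("gq_", samples)]]
    ifelse(is.na(gq), ".", as.character(gq))
  } else rep(".", nrow(m))
  cols <- lapply(samples, function(s) {
    gt <- m[[paste0("gt_", s)]]
    gq <- m[[paste0("gq_", s)]]
    dp <- m[[paste0("dp_", s)]]
    miss <- is.na(gt) | gt == "" | gt == "./."
    ifelse(miss, "./.",
           paste0(gt, ":", ifelse(is.na(gq), ".", gq), ":",
                  ifelse(is.na(dp), ".", dp)))
  })
  body <- do.call(paste, c(list(m$rname, m$pos, ".", m$ref, alt, qual,
                                "PASS", ".", "GT:GQ:DP"), cols,
                           list(sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into a genotype matrix
#'
#' @param path VCF file (plain text or bgzipped).
#' @return genotype-matrix data.table as written by [write_vcf()].
#' @export
read_vcf <- function(path) {
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::alt(v)
  alt_chr <- vapply(as.list(alt), function(a)
    paste(as.character(a), collapse = ","), character(1))
  alt_chr[alt_chr == "."] <- ""
  m <- data.table(
    rname = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt_chr)
  g <- VariantAnnotation::geno(v)
  samples <- colnames(v)
  for (s in samples) {
    gt <- as.character(g$GT[, s])
    gt[gt == "." | is.na(gt)] <- "./."
    m[, (paste0("gt_", s)) := gt]
    gq <- if ("GQ" %in% names(g)) suppressWarnings(
      as.integer(g$GQ[, s])) else NA_integer_
    dp <- if ("DP" %in% names(g)) suppressWarnings(
      as.integer(g$DP[, s])) else NA_integer_
    m[, (paste0("gq_", s)) := gq]
    m[, (paste0("dp_", s)) := dp]
  }
  setorder(m, rname, pos)
  m[]
}

#' Merge per-sample call sets into a multi-sample genotype matrix
#'
#' The site universe is the union of all variant sites; each sample
#' contributes its genotype where called and a missing genotype (`./.`)
#' elsewhere.  Alternative alleles are unified across samples (first-seen
#' order) and genotype indices renumbered accordingly.  Conflicting
#' reference alleles at one site are a hard error.
#'
#' @param call_sets named list of call tables ([call_variants()] output).
#' @return multi-sample genotype matrix.
#' @export
merge_vcfs <- function(call_sets) {
  stopifnot(length(call_sets) >= 1L)
  if (is.null(names(call_sets)))
    names(call_sets) <- paste0("sample", seq_along(call_sets))
  sites <- rbindlist(lapply(call_sets, function(x)
    x[, .(rname, pos = as.integer(pos), ref)]), idcol = NULL)
  sites <- base::unique(sites)
  dupsite <- sites[, .N, by = .(rname, pos)][N > 1L]
  if (nrow(dupsite) > 0L)
    stop(sprintf("conflicting reference alleles at %s:%d",
                 dupsite$rname[1], dupsite$pos[1]))
  setorder(sites, rname, pos)
  ## unified alt allele list per site, first-seen across samples
  alt_map <- new.env(parent = emptyenv())
  for (s in names(call_sets)) {
    cs <- call_sets[[s]]
    for (i in seq_len(nrow(cs))) {
      if (is.na(cs$alt[i]) || cs$alt[i] == "") next
      key <- paste(cs$rname[i], cs$pos[i], sep = ":")
      prev <- if (!is.null(alt_map[[key]])) alt_map[[key]] else character(0)
      alt_map[[key]] <- base::union(prev,
                                    strsplit(cs$alt[i], ",")[[1]])
    }
  }
  key_all <- paste(sites$rname, sites$pos, sep = ":")
  sites[, alt := vapply(key_all, function(k)
    paste(if (!is.null(alt_map[[k]])) alt_map[[k]] else character(0),
          collapse = ","), character(1))]
  for (s in names(call_sets)) {
    cs <- call_sets[[s]]
    gt <- rep("./.", nrow(sites))
    gq <- rep(NA_integer_, nrow(sites))
    dp <- rep(NA_integer_, nrow(sites))
    if (nrow(cs) > 0L) {
      key_s <- paste(cs$rname, cs$pos, sep = ":")
      idx <- match(key_s, key_all)
      for (j in seq_along(idx)) {
        i <- idx[j]
        if (is.na(i)) next
        own <- if (is.na(cs$alt[j]) || cs$alt[j] == "") character(0) else
          strsplit(cs$alt[j], ",")[[1]]
        uni <- if (sites$alt[i] == "") character(0) else
          strsplit(sites$alt[i], ",")[[1]]
        ix <- as.integer(strsplit(cs$gt[j], "/")[[1]])
        ix2 <- vapply(ix, function(a)
          if (a == 0L) 0L else match(own[a], uni), integer(1))
        gt[i] <- paste(sort(ix2), collapse = "/")
        gq[i] <- as.integer(cs$gq[j])
        dp[i] <- as.integer(cs$dp[j])
      }
    }
    sites[, (paste0("gt_", s)) := gt]
    sites[, (paste0("gq_", s)) := gq]
    sites[, (paste0("dp_", s)) := dp]
  }
  sites[]
}
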