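# Pileup construction: expand alignment records into per-site base
# observations and indel events, applying the read-level filters
# (3'-end trimming, base-quality capping).

#' Build pileup observations from filtered alignments
#'
#' Expands every aligned base of every record into one observation row and
#' collects indel events from CIGAR I/D operations.  The final
#' `ignore_last_n` sequenced bases of each read (counted from the 3' end in
#' machine-cycle order, i.e. before any reverse complementing) are excluded;
#' base qualities are capped at `q_max` via [cap_base_quality()].
#'
#' @param aln alignment table (see [read_alignments()]); records whose CIGAR
#'   is inconsistent with the read length are skipped with a warning.
#' @param ignore_last_n number of 3'-end sequenced bases to ignore
#'   (default 0).
#' @param q_max maximum base quality retained (default 30).
#' @return list of class `vd_pileup` with elements
#'   * `obs`: data.table `rname`, `pos`, `base`, `qual`, `read_pos`
#'     (0-based machine cycle), `from_unique`, `read_id`
#'   * `indels`: data.table `rname`, `pos` (start column of the event),
#'     `type` ("INS"/"DEL"), `len`, `allele` (inserted bases, or the
#'     deletion length tag `D<len>`), `qual`, `from_unique`, `read_id`
#' @export
build_pileups <- function(aln, ignore_last_n = 0L, q_max = 30L) {
  stopifnot(ignore_last_n >= 0L)
  empty_obs <- data.table(rname = character(), pos = integer(),
                          base = character(), qual = integer(),
                          read_pos = integer(), from_unique = logical(),
                          read_id = integer())
  empty_ind <- data.table(rname = character(), pos = integer(),
                          type = character(), len = integer(),
                          allele = character(), qual = integer(),
                          from_unique = logical(), read_id = integer())
  if (nrow(aln) == 0L)
    return(structure(list(obs = empty_obs, indels = empty_ind),
                     class = "vd_pileup"))
  a <- copy(aln)
  a[, read_id := .I]
  qlen <- nchar(a$seq)
  cq <- cigar_query_width(a$cigar)
  bad <- which(cq != qlen | a$cigar == "*" | a$seq == "*")
  if (length(bad) > 0L) {
    warning(sprintf("skipping %d record(s) with CIGAR/read-length mismatch",
                    length(bad)))
    a <- a[-bad]
    qlen <- qlen[-bad]
  }
  if (nrow(a) == 0L)
    return(structure(list(obs = empty_obs, indels = empty_ind),
                     class = "vd_pileup"))

  simple <- cigar_is_simple(a$cigar)
  obs_parts <- list()
  ind <- empty_ind

  expand_m <- function(sub, qoff_fun) {
    ## sub: rows with pure M cigars; emit one obs per base.
    L <- nchar(sub$seq)
    rid <- rep(sub$read_id, L)
    qoff <- sequence(L) - 1L                     # query offset, 0-based
    data.table(
      rname = rep(sub$rname, L),
      pos = rep(sub$pos, L) + qoff,
      base = strsplit(paste(sub$seq, collapse = ""), "", fixed = TRUE)[[1]],
      qual = utf8ToInt(paste(sub$qual, collapse = "")) - 33L,
      read_pos = 0L,   # placeholder, fixed up by the caller

      from_unique = rep(sub$unique_aln, L),
      read_id = rid,
      qoff = qoff,
      L = rep(L, L)
    )
  }

  if (any(simple)) {
    sub <- a[simple]
    part <- expand_m(sub)
    part[, read_pos := fifelse(rep(sub$reverse, nchar(sub$seq)),
                               L - 1L - qoff, qoff)]
    part[, c("qoff", "L") := NULL]
    obs_parts[[length(obs_parts) + 1L]] <- part
  }

  if (any(!simple)) {
    comp <- a[!simple]
    parsed <- parse_cigar(comp$cigar)
    crows <- vector("list", nrow(comp))
    irows <- vector("list", nrow(comp))
    for (i in seq_len(nrow(comp))) {
      b <- cigar_blocks(parsed[[i]], comp$pos[i])
      L <- nchar(comp$seq[i])
      quals <- utf8ToInt(comp$qual[i]) - 33L
      bases <- strsplit(comp$seq[i], "", fixed = TRUE)[[1]]
      mi <- which(b$op %in% c("M", "=", "X"))
      if (length(mi) > 0L) {
        lens <- b$len[mi]
        qoff <- rep(b$qstart[mi], lens) + sequence(lens) - 1L
        crows[[i]] <- data.table(
          rname = comp$rname[i],
          pos = rep(b$rstart[mi], lens) + sequence(lens) - 1L,
          base = bases[qoff + 1L],
          qual = quals[qoff + 1L],
          read_pos = if (comp$reverse[i]) L - 1L - qoff else qoff,
          from_unique = comp$unique_aln[i],
          read_id = comp$read_id[i])
      }
      ii <- which(b$op %in% c("I", "D"))
      if (length(ii) > 0L) {
        irows[[i]] <- data.table(
          rname = comp$rname[i],
          pos = b$rstart[ii],
          type = fifelse(b$op[ii] == "I", "INS", "DEL"),
          len = b$len[ii],
          allele = vapply(seq_along(ii), function(j) {
            jj <- ii[j]
            if (b$op[jj] == "I")
              paste(bases[(b$qstart[jj] + 1L):(b$qstart[jj] + b$len[jj])],
                    collapse = "")
            else paste0("D", b$len[jj])
          }, character(1)),
          qual = quals[pmin(pmax(b$qstart[ii], 0L) + 1L, L)],
          from_unique = comp$unique_aln[i],
          read_id = comp$read_id[i])
      }
    }
    obs_parts[[length(obs_parts) + 1L]] <- rbindlist(crows)
    ind <- rbindlist(c(list(ind), irows))
  }

  obs <- rbindlist(obs_parts)
  if (ignore_last_n > 0L) {
    keep_len <- nchar(a$seq) - ignore_last_n
    obs <- obs[read_pos < keep_len[match(read_id, a$read_id)]]
  }
  obs[, qual := cap_base_quality(qual, q_max)]
  if (nrow(ind) > 0L) ind[, qual := cap_base_quality(qual, q_max)]
  setorder(obs, rname, pos)
  if (nrow(ind) > 0L) setorder(ind, rname, pos)
  structure(list(obs = obs, indels = ind), class = "vd_pileup")
}

#' Per-cycle mismatch statistics
#'
#' Tabulates, for each 0-based machine cycle (read position in sequencing
#' order), the number of aligned bases, the number of mismatches against the
#' reference, and the mismatch rate.  Useful for deciding how many 3'-end
#' bases to ignore during genotyping.
#'
#' @param aln alignment table.
#' @param reference `DNAStringSet` (named by sequence).
#' @return data.table with `read_pos`, `aligned`, `mismatches`, `rate`.
#' @export
quality_statistics <- function(aln, reference) {
  pile <- build_pileups(aln, ignore_last_n = 0L, q_max = 93L)
  obs <- pile$obs
  if (nrow(obs) == 0L)
    return(data.table(read_pos = integer(), aligned = integer(),
                      mismatches = integer(), rate = numeric()))
  obs[, ref := reference_base(reference, rname, pos)]
  out <- obs[, .(aligned = .N, mismatches = sum(base != ref)),
             by = read_pos]
  setorder(out, read_pos)
  out[, rate := mismatches / aligned]
  out[]
}

## Reference bases at (rname, pos) vectors, as a character vector.
reference_base <- function(reference, rname, pos) {
  out <- character(length(pos))
  for (sq in unique(rname)) {
    i <- which(rname == sq)
    s <- strsplit(as.character(reference[[sq]]), "", fixed = TRUE)[[1]]
    out[i] <- s[pos[i]]
  }
  out
}
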