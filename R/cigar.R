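# Vectorised CIGAR arithmetic.  Supported ops: M I D S H = X N.

## Parse CIGAR strings into a list of (len, op) data.tables.
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar, perl = TRUE)
  toks <- regmatches(cigar, m)
  lapply(toks, function(tk) {
    n <- nchar(tk)
    list(len = as.integer(substr(tk, 1L, n - 1L)),
         op = substr(tk, n, n))
  })
}

QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS   <- c("M", "D", "N", "=", "X")

## Reference-consumed width per CIGAR (vectorised).
cigar_ref_width <- function(cigar) {
  vapply(parse_cigar(cigar), function(p)
    sum(p$len[p$op %in% REF_OPS]), integer(1))
}

## Query-consumed width per CIGAR (vectorised).
cigar_query_width <- function(cigar) {
  vapply(parse_cigar(cigar), function(p)
    sum(p$len[p$op %in% QUERY_OPS]), integer(1))
}

## TRUE when the CIGAR contains none of I/D/N/S/H (pure M/=/X).
cigar_is_simple <- function(cigar) {
  !grepl("[IDNSH]", cigar)
}

## Walk one parsed CIGAR; returns per-op blocks with query offsets (0-based)
## and reference positions for a read starting at `pos`.
cigar_blocks <- function(parsed, pos) {
  len <- parsed$len; op <- parsed$op
  qoff <- cumsum(c(0L, ifelse(op %in% QUERY_OPS, len, 0L)))[seq_along(op)]
  roff <- cumsum(c(0L, ifelse(op %in% REF_OPS, len, 0L)))[seq_along(op)]
  list(len = len, op = op, qstart = qoff, rstart = pos + roff)
}

## Rebuild a CIGAR string from len/op vectors, merging equal adjacent ops
## and dropping zero-length entries.
build_cigar <- function(len, op) {
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (length(op) == 0L) return("")
  j <- 1L
  for (i in seq_along(op)[-1]) {
    if (op[i] == op[j]) {
      len[j] <- len[j] + len[i]
      len[i] <- 0L
    } else {
      j <- i
    }
  }
  keep <- len > 0L
  paste0(len[keep], op[keep], collapse = "")
}
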