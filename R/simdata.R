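# Self-contained synthetic data: reference genomes with GC structure and
# implanted repeats, diploid samples with implanted SNVs/indels/CNVs/large
# deletions, and paired-end alignments with quality-consistent errors.
# Reads are emitted as alignments directly (no external aligner); mapping
# ambiguity over repeat copies is modelled explicitly via the alignment
# strategy parameter (best / k3 / all).

#' Simulation configuration
#'
#' Defaults mirror a typical moderate-coverage resequencing regime:
#' 30x coverage, 100 bp paired reads with inserts ~ Normal(300, 50), a
#' diploid sample on a 1 Mb single-chromosome reference, a flat Q30
#' base-quality profile (error probability `10^(-q/10)` per base), 1000
#' SNVs and 100 small indels (half heterozygous), one two-copy 2 kb repeat,
#' four CNV events (copy numbers 0, 1, 3, 4; 5 kb each) and one homozygous
#' 500 bp large deletion.
#'
#' @param seq_lengths named integer vector of chromosome lengths.
#' @param gc_base,gc_amplitude,gc_period sinusoidal GC profile of the
#'   reference (fraction, fraction, bp).
#' @param n_snvs,snv_het_fraction SNV count and heterozygous fraction.
#' @param n_indels,indel_het_fraction,indel_max_len small-indel parameters.
#' @param cnvs data.table (`copies`, optional `rname`,`first`,`last`,
#'   `length`) or NULL for none; regions are auto-placed when omitted.
#' @param large_deletions data.table (`length`, optional
#'   `rname`,`first`,`last`, `zygosity`) or NULL.
#' @param repeats data.table (`unit_length`, `identity`) or NULL; each row
#'   implants one two-copy repeat into the reference.
#' @param read_length,coverage,insert_mean,insert_sd read simulation.
#' @param quality_profile per-cycle phred scores (recycled to
#'   `read_length`).
#' @param strategy multi-alignment reporting: `"best"`, `"k3"` or `"all"`.
#' @param ploidy sample ploidy (2).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return config list (class `vd_config`).
#' @export
simulation_config <- function(seq_lengths = c(chr1 = 1000000L),
                              gc_base = 0.42, gc_amplitude = 0.12,
                              gc_period = 50000,
                              n_snvs = 1000L, snv_het_fraction = 0.5,
                              n_indels = 100L, indel_het_fraction = 0.5,
                              indel_max_len = 10L,
                              cnvs = data.table(copies = c(0, 1, 3, 4),
                                                length = 5000L),
                              large_deletions = data.table(
                                length = 500L, zygosity = "hom"),
                              repeats = data.table(unit_length = 2000L,
                                                   identity = 0.995),
                              read_length = 100L, coverage = 30,
                              insert_mean = 300, insert_sd = 50,
                              quality_profile = 30L,
                              strategy = c("best", "k3", "all"),
                              ploidy = 2L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(coverage > 0, all(seq_lengths > 0), read_length >= 20L,
            insert_mean > 2 * read_length * 0.9)
  qp <- rep_len(as.integer(quality_profile), read_length)
  structure(list(
    seq_lengths = seq_lengths, gc_base = gc_base,
    gc_amplitude = gc_amplitude, gc_period = gc_period,
    n_snvs = as.integer(n_snvs), snv_het_fraction = snv_het_fraction,
    n_indels = as.integer(n_indels),
    indel_het_fraction = indel_het_fraction,
    indel_max_len = as.integer(indel_max_len),
    cnvs = cnvs, large_deletions = large_deletions, repeats = repeats,
    read_length = as.integer(read_length), coverage = coverage,
    insert_mean = insert_mean, insert_sd = insert_sd,
    quality_profile = qp, strategy = strategy,
    ploidy = as.integer(ploidy), seed = as.integer(seed)),
    class = "vd_config")
}

BASES <- c("A", "C", "G", "T")

## Random reference chromosome with a sinusoidal GC gradient.
.random_chromosome <- function(len, gc_base, gc_amp, period) {
  i <- seq_len(len)
  pgc <- pmin(pmax(gc_base + gc_amp * sin(2 * pi * i / period), 0.05), 0.95)
  is_gc <- runif(len) < pgc
  second <- runif(len) < 0.5
  chars <- ifelse(is_gc, ifelse(second, "G", "C"),
                  ifelse(second, "A", "T"))
  chars
}

## Place `n` non-overlapping intervals of widths `w` on the genome, away
## from previously occupied regions (margin in bp).
.place_intervals <- function(occupied, seq_lengths, w, margin = 400L) {
  out <- vector("list", length(w))
  for (i in seq_along(w)) {
    for (try in 1:2000) {
      sq <- sample(names(seq_lengths), 1L,
                   prob = as.numeric(seq_lengths))
      maxs <- seq_lengths[[sq]] - w[i] - margin
      if (maxs < margin + 1L) next
      s <- sample.int(maxs - margin, 1L) + margin
      cand <- data.table(rname = sq, first = s, last = s + w[i] - 1L)
      clash <- occupied[rname == sq & first <= cand$last + margin &
                          last >= cand$first - margin]
      if (nrow(clash) == 0L) {
        out[[i]] <- cand
        occupied <- rbind(occupied, cand)
        break
      }
    }
    if (is.null(out[[i]]))
      stop("could not place implants without overlap; genome too small")
  }
  list(placed = rbindlist(out), occupied = occupied)
}

#' Simulate a reference genome and a diploid sample
#'
#' Generates the reference (with GC gradient and implanted near-identical
#' repeat copies), picks positions for SNVs, small indels, CNV events and
#' large deletions, and assembles the two sample haplotypes with full
#' coordinate maps (used later to emit alignments with exact CIGARs).
#' Heterozygous variants sit on one randomly chosen haplotype, homozygous
#' variants on both.  CNV events are modelled as coverage multipliers
#' (`copies / ploidy`) during read simulation; large deletions are physical
#' sequence losses.
#'
#' @param config from [simulation_config()].
#' @return list (class `vd_genome`): `reference` (`DNAStringSet`),
#'   `seq_lengths`, `haplotypes`, `truth` (tables `snvs`, `indels`, `cnvs`,
#'   `large_deletions`, `repeats`), `config`.
#' @export
simulate_genome <- function(config) {
  with_seed(config$seed, .simulate_genome_impl(config))
}

## Error when user-specified implant regions overlap each other.
.check_implant_overlaps <- function(config) {
  regions <- list()
  for (nm in c("cnvs", "large_deletions")) {
    x <- config[[nm]]
    if (!is.null(x) && nrow(x) > 0L &&
        all(c("rname", "first", "last") %in% names(x)))
      regions[[nm]] <- x[, .(rname, first, last)]
  }
  if (length(regions) == 0L) return(invisible())
  r <- rbindlist(regions)
  setorder(r, rname, first)
  bad <- which(r$rname[-1] == r$rname[-nrow(r)] &
                 r$first[-1] <= r$last[-nrow(r)])
  if (length(bad) > 0L)
    stop(sprintf("implant regions overlap: %s:%d-%d and %s:%d-%d",
                 r$rname[bad[1]], r$first[bad[1]], r$last[bad[1]],
                 r$rname[bad[1] + 1L], r$first[bad[1] + 1L],
                 r$last[bad[1] + 1L]))
  invisible()
}

.simulate_genome_impl <- function(config) {
  .check_implant_overlaps(config)
  sl <- config$seq_lengths
  chroms <- lapply(names(sl), function(sq)
    .random_chromosome(sl[[sq]], config$gc_base, config$gc_amplitude,
                       config$gc_period))
  names(chroms) <- names(sl)
  occupied <- data.table(rname = character(), first = integer(),
                         last = integer())
  ## guard chromosome edges
  occupied <- rbind(occupied, rbindlist(lapply(names(sl), function(sq)
    data.table(rname = sq, first = c(1L, sl[[sq]] - 1000L),
               last = c(1000L, sl[[sq]])))))

  ## repeats: implant copy B as a mutated copy of A
  rep_truth <- data.table(rname = character(), first = integer(),
                          last = integer(), copy = integer(),
                          pair_id = integer())
  if (!is.null(config$repeats) && nrow(config$repeats) > 0L) {
    for (ri in seq_len(nrow(config$repeats))) {
      ulen <- as.integer(config$repeats$unit_length[ri])
      idn <- config$repeats$identity[ri]
      pl <- .place_intervals(occupied, sl, c(ulen, ulen))
      occupied <- pl$occupied
      a <- pl$placed[1]; b <- pl$placed[2]
      unit <- chroms[[a$rname]][a$first:a$last]
      mut <- runif(ulen) > idn
      unit[mut] <- vapply(which(mut), function(j)
        sample(setdiff(BASES, unit[j]), 1L), character(1))
      chroms[[b$rname]][b$first:b$last] <- unit
      rep_truth <- rbind(rep_truth,
                         data.table(rname = c(a$rname, b$rname),
                                    first = c(a$first, b$first),
                                    last = c(a$last, b$last),
                                    copy = c(1L, 2L), pair_id = ri))
    }
  }

  ## CNV events
  cnv_truth <- data.table(rname = character(), first = integer(),
                          last = integer(), copies = numeric())
  if (!is.null(config$cnvs) && nrow(config$cnvs) > 0L) {
    cn <- copy(config$cnvs)
    if (!("length" %in% names(cn))) cn[, length := 5000L]
    if (all(c("rname", "first", "last") %in% names(cn))) {
      cnv_truth <- cn[, .(rname, first, last, copies)]
      occupied <- rbind(occupied, cnv_truth[, .(rname, first, last)])
    } else {
      pl <- .place_intervals(occupied, sl, as.integer(cn$length))
      occupied <- pl$occupied
      cnv_truth <- cbind(pl$placed, copies = cn$copies)
    }
  }

  ## large deletions (physical)
  ldel_truth <- data.table(rname = character(), first = integer(),
                           last = integer(), zygosity = character(),
                           hap = integer())
  if (!is.null(config$large_deletions) &&
      nrow(config$large_deletions) > 0L) {
    ld <- copy(config$large_deletions)
    if (!("zygosity" %in% names(ld))) ld[, zygosity := "hom"]
    if (all(c("rname", "first", "last") %in% names(ld))) {
      ldel_truth <- ld[, .(rname, first, last, zygosity)]
      ldel_truth[, hap := sample(1:2, .N, replace = TRUE)]
      occupied <- rbind(occupied, ldel_truth[, .(rname, first, last)])
    } else {
      pl <- .place_intervals(occupied, sl, as.integer(ld$length))
      occupied <- pl$occupied
      ldel_truth <- cbind(pl$placed, zygosity = ld$zygosity,
                          hap = sample(1:2, nrow(ld), replace = TRUE))
    }
  }

  ## small indels
  ind_truth <- data.table()
  if (config$n_indels > 0L) {
    pl <- .place_intervals(occupied, sl,
                           rep(config$indel_max_len + 2L, config$n_indels),
                           margin = 60L)
    occupied <- pl$occupied
    p <- pl$placed
    typ <- sample(c("INS", "DEL"), config$n_indels, replace = TRUE)
    lenv <- sample.int(config$indel_max_len, config$n_indels,
                       replace = TRUE)
    het <- runif(config$n_indels) < config$indel_het_fraction
    ind_truth <- data.table(
      rname = p$rname, pos = p$first, type = typ, len = lenv,
      zygosity = fifelse(het, "het", "hom"),
      hap = sample(1:2, config$n_indels, replace = TRUE))
    ind_truth[, ins_seq := fifelse(
      type == "INS",
      vapply(len, function(l)
        paste(sample(BASES, l, replace = TRUE), collapse = ""),
      character(1)), "")]
    ## VCF-style ref/alt
    ind_truth[, ref := vapply(seq_len(.N), function(i) {
      ch <- chroms[[rname[i]]]
      if (type[i] == "DEL")
        paste(ch[pos[i]:(pos[i] + len[i])], collapse = "")
      else ch[pos[i]]
    }, character(1))]
    ind_truth[, alt := vapply(seq_len(.N), function(i) {
      ch <- chroms[[rname[i]]]
      if (type[i] == "DEL") ch[pos[i]]
      else paste0(ch[pos[i]], ins_seq[i])
    }, character(1))]
    ind_truth[, gt := fifelse(zygosity == "het", "0/1", "1/1")]
  }

  ## SNVs
  snv_truth <- data.table()
  if (config$n_snvs > 0L) {
    pl <- .place_intervals(occupied, sl, rep(1L, config$n_snvs),
                           margin = 25L)
    occupied <- pl$occupied
    p <- pl$placed
    refb <- vapply(seq_len(nrow(p)), function(i)
      chroms[[p$rname[i]]][p$first[i]], character(1))
    altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L),
                   character(1))
    het <- runif(config$n_snvs) < config$snv_het_fraction
    snv_truth <- data.table(
      rname = p$rname, pos = p$first, ref = refb, alt = unname(altb),
      zygosity = fifelse(het, "het", "hom"),
      hap = sample(1:2, config$n_snvs, replace = TRUE),
      gt = fifelse(het, "0/1", "1/1"))
  }

  ## assemble haplotypes with coordinate maps
  haplotypes <- list()
  for (sq in names(sl)) {
    haplotypes[[sq]] <- lapply(1:2, function(h) {
      ch <- chroms[[sq]]
      if (nrow(snv_truth) > 0L) {
        sv <- snv_truth[rname == sq & (zygosity == "hom" | hap == h)]
        if (nrow(sv) > 0L) ch[sv$pos] <- sv$alt
      }
      ev <- data.table(pos = integer(), type = character(),
                       len = integer(), ins_seq = character())
      if (nrow(ind_truth) > 0L) {
        iv <- ind_truth[rname == sq & (zygosity == "hom" | hap == h)]
        if (nrow(iv) > 0L)
          ev <- rbind(ev, iv[, .(pos, type, len, ins_seq)])
      }
      if (nrow(ldel_truth) > 0L) {
        lv <- ldel_truth[rname == sq & (zygosity == "hom" | hap == h)]
        if (nrow(lv) > 0L)
          ev <- rbind(ev, lv[, .(pos = first - 1L, type = "DEL",
                                 len = last - first + 1L, ins_seq = "")])
      }
      .assemble_haplotype(ch, ev)
    })
  }

  reference <- Biostrings::DNAStringSet(vapply(chroms, paste,
                                               character(1), collapse = ""))
  names(reference) <- names(sl)
  structure(list(reference = reference, seq_lengths = sl,
                 haplotypes = haplotypes,
                 truth = list(snvs = snv_truth, indels = ind_truth,
                              cnvs = cnv_truth,
                              large_deletions = ldel_truth,
                              repeats = rep_truth),
                 config = config),
            class = "vd_genome")
}

## Build one haplotype string + segment map from reference chars and
## sequence-edit events (anchored indels; DEL removes pos+1..pos+len).
.assemble_haplotype <- function(refchars, events) {
  n <- length(refchars)
  refstr <- paste(refchars, collapse = "")
  if (nrow(events) == 0L) {
    return(list(seq = refstr,
                segmap = data.table(kind = "M", hap_first = 1L,
                                    hap_last = n, ref_first = 1L),
                length = n))
  }
  setorder(events, pos)
  pieces <- character(0)
  rows <- list()
  cur_ref <- 1L; hap_pos <- 1L
  for (i in seq_len(nrow(events))) {
    a <- events$pos[i]
    span <- a - cur_ref + 1L
    if (span > 0L) {
      pieces <- c(pieces, substr(refstr, cur_ref, a))
      rows[[length(rows) + 1L]] <- data.table(
        kind = "M", hap_first = hap_pos, hap_last = hap_pos + span - 1L,
        ref_first = cur_ref)
      hap_pos <- hap_pos + span
    }
    if (events$type[i] == "INS") {
      l <- events$len[i]
      pieces <- c(pieces, events$ins_seq[i])
      rows[[length(rows) + 1L]] <- data.table(
        kind = "I", hap_first = hap_pos, hap_last = hap_pos + l - 1L,
        ref_first = NA_integer_)
      hap_pos <- hap_pos + l
      cur_ref <- a + 1L
    } else {
      cur_ref <- a + events$len[i] + 1L
    }
  }
  if (cur_ref <= n) {
    span <- n - cur_ref + 1L
    pieces <- c(pieces, substr(refstr, cur_ref, n))
    rows[[length(rows) + 1L]] <- data.table(
      kind = "M", hap_first = hap_pos, hap_last = hap_pos + span - 1L,
      ref_first = cur_ref)
    hap_pos <- hap_pos + span
  }
  list(seq = paste(pieces, collapse = ""), segmap = rbindlist(rows),
       length = hap_pos - 1L)
}

## Map reference coordinates to haplotype coordinates (NA when deleted).
.ref2hap <- function(segmap, refpos) {
  m <- segmap[kind == "M"]
  idx <- findInterval(refpos, m$ref_first)
  out <- rep(NA_integer_, length(refpos))
  ok <- idx >= 1L
  span <- m$hap_last - m$hap_first
  within <- ok & refpos <= m$ref_first[pmax(idx, 1L)] + span[pmax(idx, 1L)]
  out[within] <- m$hap_first[idx[within]] +
    (refpos[within] - m$ref_first[idx[within]])
  out
}

## Map one haplotype read interval [a,b] to (ref pos, cigar); NULL when the
## read crosses a large-deletion junction (gap > 50 bp).
.map_read <- function(segmap, a, b) {
  rows <- segmap[hap_last >= a & hap_first <= b]
  if (nrow(rows) == 1L && rows$kind == "M") {
    return(list(pos = rows$ref_first + (a - rows$hap_first),
                cigar = paste0(b - a + 1L, "M")))
  }
  ops <- character(0); lens <- integer(0)
  pos <- NA_integer_; prev_ref_end <- NA_integer_
  for (i in seq_len(nrow(rows))) {
    lo <- max(a, rows$hap_first[i]); hi <- min(b, rows$hap_last[i])
    l <- hi - lo + 1L
    if (rows$kind[i] == "I") {
      ops <- c(ops, "I"); lens <- c(lens, l)
    } else {
      rstart <- rows$ref_first[i] + (lo - rows$hap_first[i])
      if (!is.na(prev_ref_end)) {
        gap <- rstart - prev_ref_end - 1L
        if (gap > 50L) return(NULL)
        if (gap > 0L) { ops <- c(ops, "D"); lens <- c(lens, gap) }
      }
      if (is.na(pos)) pos <- rstart
      prev_ref_end <- rstart + l - 1L
      ops <- c(ops, "M"); lens <- c(lens, l)
    }
  }
  if (is.na(pos)) return(NULL)
  ## leading/trailing insertion material becomes soft clips
  if (ops[1] == "I") ops[1] <- "S"
  if (ops[length(ops)] == "I") ops[length(ops)] <- "S"
  if (ops[1] == "D" || ops[length(ops)] == "D") return(NULL)
  list(pos = pos, cigar = build_cigar(lens, ops))
}

## Sample `n` integer positions from weighted intervals (data.table
## lo/hi/w, disjoint and sorted).
.sample_weighted <- function(n, iv) {
  iv <- iv[w > 0]
  wlen <- iv$w * (iv$hi - iv$lo + 1)
  cum <- cumsum(wlen)
  u <- runif(n) * cum[length(cum)]
  idx <- findInterval(u, cum) + 1L
  off <- (u - c(0, cum)[idx]) / iv$w[idx]
  pmin(iv$lo[idx] + as.integer(floor(off)), iv$hi[idx])
}

#' Simulate coordinate-sorted paired-end alignments
#'
#' Emits aligned read pairs at the configured coverage: insert sizes are
#' drawn from `Normal(insert_mean, insert_sd)`; base errors are injected
#' per cycle with probability `10^(-q/10)` from the quality profile;
#' positions and CIGARs are computed exactly from the known haplotype of
#' origin (no aligner is invoked).  CNV regions receive proportionally
#' more/fewer pairs (`copies/ploidy`); pairs crossing a large-deletion
#' junction are re-coordinated across the gap (elevated template length)
#' or dropped when a read overlaps the junction itself.  Reads falling
#' entirely inside a repeat copy are ambiguous: under `strategy = "best"`
#' they are reported once at a random copy with MAPQ 0; under `"k3"`/
#' `"all"` the true placement is primary and the other copies are
#' secondary records, all with MAPQ 0 and an `NH` count > 1.
#'
#' @param genome from [simulate_genome()].
#' @param config defaults to `genome$config`.
#' @param path optional output SAM path (written via [write_sam()]).
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return alignment table in the schema of [read_alignments()] (attribute
#'   `seq_lengths` set); written to `path` when given.
#' @export
simulate_alignments <- function(genome, config = genome$config,
                                path = NULL, seed = config$seed + 1L) {
  aln <- with_seed(seed, .simulate_alignments_impl(genome, config, NULL))
  if (!is.null(path)) write_sam(aln, path)
  aln
}

## hap_chooser: NULL (fair diploid) or function(sq, ref_positions) -> 1/2.
.simulate_alignments_impl <- function(genome, config, hap_chooser) {
  L <- config$read_length
  sl <- genome$seq_lengths
  recs <- list()
  pair_id <- 0L
  fwd_q <- intToUtf8(config$quality_profile + 33L)
  rev_q <- intToUtf8(rev(config$quality_profile) + 33L)
  err_p <- phred_to_prob(config$quality_profile)

  for (sq in names(sl)) {
    haps <- genome$haplotypes[[sq]]
    cnvs <- genome$truth$cnvs
    cnvs_sq <- if (nrow(cnvs) > 0L) cnvs[rname == sq] else cnvs
    for (h in 1:2) {
      hp <- haps[[h]]
      maxstart <- hp$length - L   # inserts are clamped to fit below
      if (maxstart < 1L) next
      ## weight intervals in haplotype coordinates
      iv <- data.table(lo = 1, hi = as.numeric(maxstart), w = 1)
      if (nrow(cnvs_sq) > 0L) {
        pts <- sort(c(1, maxstart + 1,
                      .ref2hap(hp$segmap, cnvs_sq$first),
                      .ref2hap(hp$segmap, cnvs_sq$last + 1L)))
        pts <- pts[!is.na(pts) & pts >= 1 & pts <= maxstart + 1]
        pts <- base::unique(pts)
        lo <- pts[-length(pts)]; hi <- pts[-1] - 1
        mid <- (lo + hi) / 2
        midref <- mid  # events are placed outside CNVs; offsets small
        wts <- rep(1, length(lo))
        for (ci in seq_len(nrow(cnvs_sq))) {
          c_lo <- .ref2hap(hp$segmap, cnvs_sq$first[ci])
          c_hi <- .ref2hap(hp$segmap, cnvs_sq$last[ci])
          inside <- !is.na(c_lo) & !is.na(c_hi) & mid >= c_lo & mid <= c_hi
          wts[inside] <- cnvs_sq$copies[ci] / config$ploidy
        }
        iv <- data.table(lo = lo, hi = hi, w = wts)
      }
      ## pairs carry weights <= 1 (deletions); duplication surplus is
      ## emitted as extra single reads so start-depth edges stay sharp
      iv_pair <- copy(iv)[, w := pmin(w, 1)]
      iv_dup <- copy(iv)[w > 1][, w := w - 1]
      wlen <- sum(iv_pair$w * (iv_pair$hi - iv_pair$lo + 1))
      n_pairs <- round((config$coverage / 2) * wlen / (2 * L))
      if (n_pairs < 1L) next
      a <- .sample_weighted(n_pairs, iv_pair)
      if (!is.null(hap_chooser)) {
        keep <- hap_chooser(sq, a) == h
        a <- a[keep]
        if (length(a) == 0L) next
      }
      ins <- pmax(as.integer(round(rnorm(length(a), config$insert_mean,
                                         config$insert_sd))), L)
      ## clamp the pair position, not the insert, so the template-length
      ## distribution carries no chromosome-end artifact
      a <- pmin(a, hp$length - ins + 1L)
      ok <- a >= 1L
      a <- a[ok]; ins <- ins[ok]
      recs[[length(recs) + 1L]] <-
        .emit_pairs(sq, hp, a, ins, L, pair_id, fwd_q, rev_q, err_p,
                    genome, config)
      pair_id <- pair_id + length(a)
      if (nrow(iv_dup) > 0L) {
        dlen <- sum(iv_dup$w * (iv_dup$hi - iv_dup$lo + 1))
        n_extra <- round((config$coverage / 2) * dlen / L)
        if (n_extra >= 1L) {
          s <- .sample_weighted(n_extra, iv_dup)
          s <- pmin(s, hp$length - L + 1L)
          recs[[length(recs) + 1L]] <-
            .emit_singles(sq, hp, s, L, pair_id, fwd_q, rev_q, err_p)
          pair_id <- pair_id + length(s)
        }
      }
    }
  }
  aln <- rbindlist(recs)
  ord <- order(match(aln$rname, names(sl)), aln$pos)
  aln <- aln[ord]
  aln[, `:=`(
    secondary = bitwAnd(flag, 256L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    paired = bitwAnd(flag, 1L) > 0L,
    proper = bitwAnd(flag, 2L) > 0L,
    first_of_pair = bitwAnd(flag, 64L) > 0L
  )]
  aln[, unique_aln := !secondary & mapq > 0L]
  aln[, multiple := secondary | nh > 1L]
  aln[, end_pos := pos + cigar_ref_width(cigar) - 1L]
  setattr(aln, "seq_lengths", sl)
  aln[]
}

## Emit SAM-like records for one batch of pairs on one haplotype.
.emit_pairs <- function(sq, hp, a, ins, L, pair_id0, fwd_q, rev_q, err_p,
                        genome, config) {
  n <- length(a)
  l_start <- a; l_end <- a + L - 1L
  r_start <- a + ins - L; r_end <- a + ins - 1L
  segmap <- hp$segmap
  simple <- nrow(segmap) == 1L

  map_many <- function(s, e) {
    if (simple) {
      return(list(pos = segmap$ref_first + (s - segmap$hap_first),
                  cigar = rep(paste0(L, "M"), length(s)),
                  ok = rep(TRUE, length(s))))
    }
    idx_s <- findInterval(s, segmap$hap_first)
    idx_e <- findInterval(e, segmap$hap_first)
    fast <- idx_s == idx_e & segmap$kind[idx_s] == "M"
    pos <- integer(length(s)); cig <- character(length(s))
    ok <- logical(length(s))
    pos[fast] <- segmap$ref_first[idx_s[fast]] +
      (s[fast] - segmap$hap_first[idx_s[fast]])
    cig[fast] <- paste0(e[fast] - s[fast] + 1L, "M")
    ok[fast] <- TRUE
    for (i in which(!fast)) {
      m <- .map_read(segmap, s[i], e[i])
      if (!is.null(m)) { pos[i] <- m$pos; cig[i] <- m$cigar; ok[i] <- TRUE }
    }
    list(pos = pos, cigar = cig, ok = ok)
  }

  ml <- map_many(l_start, l_end)
  mr <- map_many(r_start, r_end)
  keep <- ml$ok & mr$ok
  if (!any(keep)) return(NULL)
  a <- a[keep]; ins <- ins[keep]
  l_start <- l_start[keep]; l_end <- l_end[keep]
  r_start <- r_start[keep]; r_end <- r_end[keep]
  lpos <- ml$pos[keep]; lcig <- ml$cigar[keep]
  rpos <- mr$pos[keep]; rcig <- mr$cigar[keep]
  n <- length(a)

  lseq <- substring(hp$seq, l_start, l_end)
  rseq_f <- substring(hp$seq, r_start, r_end)   # aligned orientation

  ## sequencing errors per machine cycle
  inject <- function(seqs, reverse) {
    for (cyc in seq_len(L)) {
      hit <- which(runif(length(seqs)) < err_p[cyc])
      if (length(hit) == 0L) next
      p <- if (reverse) L + 1L - cyc else cyc
      for (i in hit) {
        old <- substr(seqs[i], p, p)
        if (!(old %in% BASES)) next
        substr(seqs[i], p, p) <- sample(setdiff(BASES, old), 1L)
      }
    }
    seqs
  }
  lseq <- inject(lseq, FALSE)
  rseq_f <- inject(rseq_f, TRUE)

  lend_ref <- lpos + cigar_ref_width(lcig) - 1L
  rend_ref <- rpos + cigar_ref_width(rcig) - 1L
  tlen <- rend_ref - lpos + 1L

  ## repeat-copy ambiguity (in reference coordinates)
  reps <- genome$truth$repeats
  alt_pos_of <- function(p_, e_) {
    out <- rep(NA_integer_, length(p_))
    if (nrow(reps) == 0L) return(out)
    for (pid in base::unique(reps$pair_id)) {
      pr <- reps[pair_id == pid & rname == sq]
      if (nrow(pr) < 2L) next
      for (ci in 1:2) {
        this <- pr[ci]; other <- pr[3L - ci]
        inside <- p_ >= this$first & e_ <= this$last
        out[inside] <- other$first + (p_[inside] - this$first)
      }
    }
    out
  }
  l_alt <- alt_pos_of(lpos, lend_ref)
  r_alt <- alt_pos_of(rpos, rend_ref)

  qn <- sprintf("sim%08d", pair_id0 + seq_len(n))
  mk <- function(pos_, cig_, seq_, qual_, mate_pos_, tlen_, flag_, mapq_,
                 nh_, qname_ = qn) {
    data.table(qname = qname_, flag = flag_, rname = sq, pos = pos_,
               mapq = mapq_, cigar = cig_, rnext = "=", pnext = mate_pos_,
               tlen = tlen_, seq = seq_, qual = qual_, nh = nh_)
  }

  mapq_l <- fifelse(is.na(l_alt), 60L, 0L)
  mapq_r <- fifelse(is.na(r_alt), 60L, 0L)
  amb_pair <- !is.na(l_alt) | !is.na(r_alt)

  if (config$strategy == "best") {
    flip_l <- !is.na(l_alt) & runif(n) < 0.5
    flip_r <- !is.na(r_alt) & runif(n) < 0.5
    lpos2 <- ifelse(flip_l, l_alt, lpos)
    rpos2 <- ifelse(flip_r, r_alt, rpos)
    proper <- !amb_pair
    tl <- ifelse(proper, tlen, 0L)
    left <- mk(lpos2, lcig, lseq, fwd_q, rpos2,
               ifelse(proper, tl, 0L),
               1L + ifelse(proper, 2L, 0L) + 32L + 64L, mapq_l, 1L)
    right <- mk(rpos2, rcig, rseq_f, rev_q, lpos2,
                -ifelse(proper, tl, 0L),
                1L + ifelse(proper, 2L, 0L) + 16L + 128L, mapq_r, 1L)
    return(rbind(left, right))
  }

  ## k3 / all: primary at the true placement (+ secondary at other copies)
  nh_l <- fifelse(is.na(l_alt), 1L, 2L)
  nh_r <- fifelse(is.na(r_alt), 1L, 2L)
  left <- mk(lpos, lcig, lseq, fwd_q, rpos, tlen,
             1L + 2L + 32L + 64L, mapq_l, nh_l)
  right <- mk(rpos, rcig, rseq_f, rev_q, lpos, -tlen,
              1L + 2L + 16L + 128L, mapq_r, nh_r)
  out <- list(left, right)
  sec_l <- which(!is.na(l_alt))
  if (length(sec_l) > 0L)
    out[[length(out) + 1L]] <- mk(l_alt[sec_l], lcig[sec_l], lseq[sec_l],
                                  fwd_q, rpos[sec_l], 0L,
                                  1L + 32L + 64L + 256L, 0L, 2L,
                                  qname_ = qn[sec_l])
  sec_r <- which(!is.na(r_alt))
  if (length(sec_r) > 0L)
    out[[length(out) + 1L]] <- mk(r_alt[sec_r], rcig[sec_r], rseq_f[sec_r],
                                  rev_q, lpos[sec_r], 0L,
                                  1L + 16L + 128L + 256L, 0L, 2L,
                                  qname_ = qn[sec_r])
  rbindlist(out)
}

## Emit unpaired single reads (duplication surplus coverage).
.emit_singles <- function(sq, hp, s, L, id0, fwd_q, rev_q, err_p) {
  e <- s + L - 1L
  segmap <- hp$segmap
  n <- length(s)
  pos <- integer(n); cig <- character(n); ok <- logical(n)
  if (nrow(segmap) == 1L) {
    pos <- segmap$ref_first + (s - segmap$hap_first)
    cig <- rep(paste0(L, "M"), n)
    ok <- rep(TRUE, n)
  } else {
    idx_s <- findInterval(s, segmap$hap_first)
    idx_e <- findInterval(e, segmap$hap_first)
    fast <- idx_s == idx_e & segmap$kind[idx_s] == "M"
    pos[fast] <- segmap$ref_first[idx_s[fast]] +
      (s[fast] - segmap$hap_first[idx_s[fast]])
    cig[fast] <- paste0(L, "M")
    ok[fast] <- TRUE
    for (i in which(!fast)) {
      m <- .map_read(segmap, s[i], e[i])
      if (!is.null(m)) { pos[i] <- m$pos; cig[i] <- m$cigar; ok[i] <- TRUE }
    }
  }
  s <- s[ok]; e <- e[ok]; pos <- pos[ok]; cig <- cig[ok]
  n <- length(s)
  if (n == 0L) return(NULL)
  seqs <- substring(hp$seq, s, e)
  rev <- runif(n) < 0.5
  for (cyc in seq_len(L)) {
    hit <- which(runif(n) < err_p[cyc])
    for (i in hit) {
      p <- if (rev[i]) L + 1L - cyc else cyc
      old <- substr(seqs[i], p, p)
      if (!(old %in% BASES)) next
      substr(seqs[i], p, p) <- sample(setdiff(BASES, old), 1L)
    }
  }
  data.table(qname = sprintf("sim%08d", id0 + seq_len(n)),
             flag = fifelse(rev, 16L, 0L), rname = sq, pos = pos,
             mapq = 60L, cigar = cig, rnext = "*", pnext = 0L, tlen = 0L,
             seq = seqs, qual = fifelse(rev, rev_q, fwd_q), nh = 1L)
}

#' Simulate a pooled-segregant sample
#'
#' The two haplotypes of the simulated genome act as the two haploid
#' parents.  Each of `n_segregants` segregants inherits parent 1 or
#' parent 2 independently per `block_length` block (recombination-free
#' blocks); each read pair is drawn from a random segregant.  Sites where
#' the parents differ are expected heterozygous in the pool, with allele
#' proportions governed by the per-block segregant counts (genetic drift).
#'
#' @param genome from [simulate_genome()] (variants should be heterozygous
#'   so the parents differ).
#' @param n_segregants pool size (default 20).
#' @param block_length recombination-free block length (default 5000 bp).
#' @param config,path,seed as in [simulate_alignments()].
#' @return list: `aln` (alignment table), `truth` (site table with
#'   `expected_class`), `parent_blocks` (segregant x block inheritance).
#' @export
simulate_pool_alignments <- function(genome, n_segregants = 20L,
                                     block_length = 5000L,
                                     config = genome$config, path = NULL,
                                     seed = config$seed + 2L) {
  res <- with_seed(seed, {
    sl <- genome$seq_lengths
    blocks <- lapply(names(sl), function(sq) {
      nb <- ceiling(sl[[sq]] / block_length)
      matrix(sample(1:2, nb * n_segregants, replace = TRUE),
             nrow = nb, ncol = n_segregants)
    })
    names(blocks) <- names(sl)
    chooser <- function(sq, positions) {
      bl <- pmin(((positions - 1L) %/% block_length) + 1L,
                 nrow(blocks[[sq]]))
      seg <- sample.int(n_segregants, length(positions), replace = TRUE)
      blocks[[sq]][cbind(bl, seg)]
    }
    aln <- .simulate_alignments_impl(genome, config, chooser)
    list(aln = aln, blocks = blocks)
  })
  sn <- genome$truth$snvs
  truth <- if (nrow(sn) > 0L)
    sn[, .(rname, pos, ref, alt,
           expected_class = fifelse(zygosity == "het", "heterozygous",
                                    "homozygous_alt"))]
  else data.table()
  if (!is.null(path)) write_sam(res$aln, path)
  list(aln = res$aln, truth = truth, parent_blocks = res$blocks)
}

#' Write a reference genome as FASTA
#'
#' @param reference named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' Write simulation truth as VCF + GFF
#'
#' @param genome from [simulate_genome()].
#' @param prefix output path prefix; writes `<prefix>.truth.vcf` (SNVs and
#'   small indels) and `<prefix>.truth.gff3` (repeats, CNVs, large
#'   deletions).
#' @return named character vector of paths, invisibly.
#' @export
write_truth <- function(genome, prefix) {
  tr <- genome$truth
  calls <- rbindlist(list(
    if (nrow(tr$snvs) > 0L)
      tr$snvs[, .(rname, pos, ref, alt, gt, gq = 99L, dp = 0L)],
    if (nrow(tr$indels) > 0L)
      tr$indels[, .(rname, pos, ref, alt, gt, gq = 99L, dp = 0L)]))
  setorder(calls, rname, pos)
  vcf <- paste0(prefix, ".truth.vcf")
  write_vcf(calls_to_matrix(calls, "truth"), vcf,
            seq_lengths = genome$seq_lengths)
  feats <- rbindlist(list(
    if (nrow(tr$repeats) > 0L)
      tr$repeats[, .(rname, first, last, type = "repeat_region",
                     source = "truth")],
    if (nrow(tr$cnvs) > 0L)
      tr$cnvs[, .(rname, first, last,
                  type = fifelse(copies < 2, "DEL", "DUP"),
                  source = "truth", copies)],
    if (nrow(tr$large_deletions) > 0L)
      tr$large_deletions[, .(rname, first, last, type = "DEL",
                             source = "truth")]),
    fill = TRUE)
  gff <- paste0(prefix, ".truth.gff3")
  if (is.null(feats)) feats <- data.table()
  write_sv_gff(feats, gff)
  invisible(c(vcf = vcf, gff = gff))
}
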