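# End-to-end discovery pipeline and command-line entry point.

#' Run configuration defaults
#'
#' @return named list of pipeline defaults: `h = 0.001`, `q_max = 30`,
#'   `max_per_start = 2`, `ignore_last_n = 0`, `min_gq = 40`, `bin_size =
#'   100`, `alpha_rd = 0.05`, `t = 3`, `alpha_rp = 0.001`,
#'   `repeat_threshold = 0.2`, `ploidy = 2`, `min_mapping_quality = 10`,
#'   `emit_all = FALSE`, `include_secondary = FALSE`.
#' @export
run_defaults <- function() {
  list(h = 0.001, q_max = 30L, max_per_start = 2L, ignore_last_n = 0L,
       min_gq = 40L, bin_size = 100L, alpha_rd = 0.05, t = 3,
       alpha_rp = 0.001, repeat_threshold = 0.2, ploidy = 2L,
       min_mapping_quality = 10L, emit_all = FALSE,
       include_secondary = FALSE, min_insert_pairs = 1000L)
}

#' Integrated variant discovery
#'
#' Executes repeat detection, read-depth CNV calling, read-pair large-indel
#' calling, indel realignment and Bayesian genotyping, and (optionally)
#' functional annotation, producing one VCF (SNVs + small indels) and one
#' integrated GFF3 (repeats + CNVs + large indels) per run.
#'
#' @param reference named `DNAStringSet` or FASTA path.
#' @param alignments alignment table or SAM/BAM path.
#' @param output_prefix when given, writes `<prefix>.vcf`, `<prefix>.gff3`
#'   and `<prefix>.stats.json`.
#' @param gene_models gene models ([read_gene_models()] output) or GFF3
#'   path, or NULL to skip annotation.
#' @param sample sample name for the VCF column.
#' @param ... overrides of [run_defaults()].
#' @return list: `calls`, `features`, `stats`, plus `vcf`/`gff` paths when
#'   written.
#' @export
run_discovery <- function(reference, alignments, output_prefix = NULL,
                          gene_models = NULL, sample = "sample1", ...) {
  cfg <- utils::modifyList(run_defaults(), list(...))
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  aln <- if (is.character(alignments))
    read_alignments(alignments, cfg$min_mapping_quality,
                    include_secondary = TRUE)
  else alignments
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)

  message("detecting repetitive regions ...")
  reps <- detect_repeats(aln, cfg$repeat_threshold)

  message("read-depth CNV discovery ...")
  signal <- bin_depth(aln, reference, cfg$bin_size)
  cnvs <- discover_cnvs(signal, ploidy = cfg$ploidy, alpha = cfg$alpha_rd)

  message("read-pair SV discovery ...")
  svs <- tryCatch({
    dist <- estimate_insert_distribution(aln, cfg$min_insert_pairs)
    cl <- cluster_discordant_pairs(aln, dist, cfg$t,
                                   cfg$min_mapping_quality)
    call_large_indels(cl, dist, cfg$alpha_rp)
  }, error = function(e) {
    warning("read-pair stage skipped: ", conditionMessage(e))
    NULL
  })
  combined <- combine_rd_rp(cnvs, svs)

  message("genotyping SNVs and small indels ...")
  calls <- call_variants(aln, reference, h = cfg$h, q_max = cfg$q_max,
                         max_per_start = cfg$max_per_start,
                         ignore_last_n = cfg$ignore_last_n,
                         min_gq = cfg$min_gq,
                         min_mapping_quality = max(1L,
                                                   cfg$min_mapping_quality),
                         emit_all = cfg$emit_all,
                         include_secondary = cfg$include_secondary)
  if (!is.null(gene_models))
    calls <- annotate_variants(calls, gene_models, reference)

  features <- rbindlist(list(
    if (nrow(reps) > 0L)
      reps[, .(rname, first, last, type = "repeat_region",
               source = "repeat_finder", unique_fraction)],
    if (!is.null(combined) && nrow(combined) > 0L) combined),
    fill = TRUE)
  if (is.null(features)) features <- data.table()
  if (nrow(features) > 0L) {
    features <- base::unique(features,
                             by = c("rname", "first", "last", "type",
                                    "source"))
    setorder(features, rname, first)
  }

  stats <- list(
    n_alignments = nrow(aln),
    n_repeats = nrow(reps),
    n_cnvs = if (is.null(cnvs)) 0L else nrow(cnvs),
    n_large_indels = if (is.null(svs)) 0L else nrow(svs),
    n_snvs = sum(calls$type == "SNV"),
    n_small_indels = sum(calls$type %in% c("INS", "DEL")),
    n_het = sum(vapply(strsplit(calls$gt, "/"), function(x)
      length(base::unique(x)) > 1L, logical(1))))

  out <- list(calls = calls, features = features, stats = stats)
  if (!is.null(output_prefix)) {
    out$vcf <- paste0(output_prefix, ".vcf")
    write_vcf(calls_to_matrix(calls, sample), out$vcf,
              seq_lengths = setNames(
                Biostrings::width(reference), names(reference)))
    out$gff <- paste0(output_prefix, ".gff3")
    write_sv_gff(features, out$gff)
    jsonlite::write_json(stats, paste0(output_prefix, ".stats.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

## ---- command line interface -------------------------------------------

.cli_opts <- function(args) {
  opts <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE
      } else {
        opts[[key]] <- args[i + 1L]
        i <- i + 1L
      }
    } else pos <- c(pos, a)
    i <- i + 1L
  }
  list(opts = opts, pos = pos)
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `call` (integrated discovery), `repeats`, `cnv`, `sv`,
#' `genotype`, `annotate`, `filter`, `merge`, `evaluate`, `simulate`,
#' `qualstats`.  Run without arguments for usage.  Exit codes: 0 ok,
#' 2 configuration error, 3 data error.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: vardiscover <command> [options]",
    "commands:",
    "  call      --ref FA --aln SAM/BAM --out PREFIX [--gff GENES]",
    "  repeats   --aln SAM/BAM [--threshold 0.2]",
    "  cnv       --ref FA --aln SAM/BAM [--bin 100] [--alpha 0.05]",
    "  sv        --aln SAM/BAM [--t 3] [--alpha 0.001]",
    "  genotype  --ref FA --aln SAM/BAM --out VCF [--min-gq 40]",
    "  annotate  --ref FA --vcf VCF --gff GENES --out VCF",
    "  filter    --vcf VCF --out VCF [--min-gq Q] [--exclude GFF]",
    "  merge     --out VCF VCF1 VCF2 [...]",
    "  evaluate  --gold VCF --test VCF [--thresholds 0,20,40,...]",
    "  simulate  --out PREFIX [--seed 1] [--coverage 30] [--length 1e6]",
    "  qualstats --ref FA --aln SAM/BAM",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  pa <- .cli_opts(args[-1L])
  o <- pa$opts
  status <- tryCatch({
    switch(cmd,
      call = {
        res <- run_discovery(o$ref, o$aln, output_prefix = o$out,
                             gene_models = o$gff)
        message(sprintf("wrote %s and %s", res$vcf, res$gff))
        0L
      },
      repeats = {
        aln <- read_alignments(o$aln)
        print(detect_repeats(aln, .cli_num(o, "threshold", 0.2)))
        0L
      },
      cnv = {
        ref <- Biostrings::readDNAStringSet(o$ref)
        names(ref) <- sub("\\s.*", "", names(ref))
        aln <- read_alignments(o$aln)
        sig <- bin_depth(aln, ref, as.integer(.cli_num(o, "bin", 100)))
        print(discover_cnvs(sig, alpha = .cli_num(o, "alpha", 0.05)))
        0L
      },
      sv = {
        aln <- read_alignments(o$aln)
        dist <- estimate_insert_distribution(aln)
        cl <- cluster_discordant_pairs(aln, dist, .cli_num(o, "t", 3))
        print(call_large_indels(cl, dist, .cli_num(o, "alpha", 0.001)))
        0L
      },
      genotype = {
        ref <- Biostrings::readDNAStringSet(o$ref)
        names(ref) <- sub("\\s.*", "", names(ref))
        aln <- read_alignments(o$aln, 1L)
        calls <- call_variants(aln, ref,
                               min_gq = as.integer(.cli_num(o, "min-gq", 40)))
        write_vcf(calls_to_matrix(calls), o$out)
        0L
      },
      annotate = {
        ref <- Biostrings::readDNAStringSet(o$ref)
        names(ref) <- sub("\\s.*", "", names(ref))
        m <- read_vcf(o$vcf)
        s <- matrix_samples(m)[1]
        calls <- m[, .(rname, pos, ref, alt, gt = get(paste0("gt_", s)),
                       gq = get(paste0("gq_", s)),
                       dp = get(paste0("dp_", s)))]
        calls[, type := fifelse(nchar(ref) == 1 &
                                  nchar(sub(",.*", "", alt)) <= 1, "SNV",
                                "INDEL")]
        ann <- annotate_variants(calls, read_gene_models(o$gff), ref)
        print(ann[, .N, by = effect])
        write_vcf(calls_to_matrix(ann, s), o$out)
        0L
      },
      filter = {
        m <- read_vcf(o$vcf)
        s <- matrix_samples(m)[1]
        calls <- m[, .(rname, pos, ref, alt, gt = get(paste0("gt_", s)),
                       gq = get(paste0("gq_", s)),
                       dp = get(paste0("dp_", s)))]
        ex <- if (!is.null(o$exclude)) read_sv_gff(o$exclude) else NULL
        out <- filter_calls(calls, as.integer(.cli_num(o, "min-gq", 0)), ex)
        write_vcf(calls_to_matrix(out, s), o$out)
        0L
      },
      merge = {
        sets <- lapply(pa$pos, function(p) {
          m <- read_vcf(p)
          s <- matrix_samples(m)[1]
          m[, .(rname, pos, ref, alt, gt = get(paste0("gt_", s)),
                gq = get(paste0("gq_", s)), dp = get(paste0("dp_", s)))]
        })
        names(sets) <- tools::file_path_sans_ext(basename(pa$pos))
        write_vcf(merge_vcfs(sets), o$out)
        0L
      },
      evaluate = {
        gold_m <- read_vcf(o$gold)
        s <- matrix_samples(gold_m)[1]
        gold <- gold_m[, .(rname, pos, ref,
                           gt = get(paste0("gt_", s)))]
        gold[, expected_class := fifelse(gt_class(gt) == "het",
                                         "heterozygous", "homozygous_ref")]
        test_m <- read_vcf(o$test)
        st <- matrix_samples(test_m)[1]
        test <- test_m[, .(rname, pos, ref, alt,
                           gt = get(paste0("gt_", st)),
                           gq = get(paste0("gq_", st)))]
        thr <- as.numeric(strsplit(
          if (is.null(o$thresholds)) "0,20,40,60,80" else o$thresholds,
          ",")[[1]])
        print(evaluate_genotypes(gold, test, thr))
        0L
      },
      simulate = {
        len <- as.integer(.cli_num(o, "length", 1e6))
        small <- len < 200000L
        cfg <- simulation_config(
          seq_lengths = c(chr1 = len),
          n_snvs = max(10L, as.integer(len * 1e-3)),
          n_indels = max(2L, as.integer(len * 1e-4)),
          cnvs = if (small) NULL else
            data.table(copies = c(0, 1, 3, 4), length = 5000L),
          large_deletions = if (small) NULL else
            data.table(length = 500L, zygosity = "hom"),
          repeats = if (small) NULL else
            data.table(unit_length = 2000L, identity = 0.995),
          coverage = .cli_num(o, "coverage", 30),
          seed = as.integer(.cli_num(o, "seed", 1)))
        g <- simulate_genome(cfg)
        write_fasta(g$reference, paste0(o$out, ".fa"))
        simulate_alignments(g, path = paste0(o$out, ".sam"))
        write_truth(g, o$out)
        message("wrote ", o$out, ".{fa,sam,truth.vcf,truth.gff3}")
        0L
      },
      qualstats = {
        ref <- Biostrings::readDNAStringSet(o$ref)
        names(ref) <- sub("\\s.*", "", names(ref))
        aln <- read_alignments(o$aln)
        print(quality_statistics(aln, ref))
        0L
      },
      { message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(status)
}
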