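# Small shared helpers: phred conversions, seeded RNG scopes, interval maths.

#' Convert phred score to error probability
#'
#' @param q numeric vector of phred-scaled qualities.
#' @return numeric vector of error probabilities `10^(-q/10)`.
#' @export
phred_to_prob <- function(q) 10^(-q / 10)

#' Convert error probability to phred score
#'
#' @param p numeric vector of probabilities.
#' @return phred scores `-10*log10(p)`.
#' @export
prob_to_phred <- function(p) -10 * log10(p)

#' Cap a base quality score
#'
#' Scores larger than `q_max` are equalised to `q_max`; this guards the
#' genotyper against miscalibrated (overconfident) base qualities.
#'
#' @param q phred score(s), must be >= 0.
#' @param q_max maximum allowed phred score.
#' @return `pmin(q, q_max)`.
#' @export
cap_base_quality <- function(q, q_max) {
  stopifnot(all(q >= 0), q_max >= 0)
  pmin(q, q_max)
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a child seed from a base seed, kept < 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 + 97 * k) %% 2147483647)
}

## Population standard deviation.
pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

## log(sum(exp(x))) stable.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Phred-scaled genotype quality from a posterior probability
#'
#' `GQ = min(255, round(-10*log10(1 - posterior)))`, 255 when the posterior
#' rounds to 1 at double precision.
#'
#' @param posterior posterior probability of the called genotype.
#' @return integer GQ in \[0, 255\].
#' @export
genotype_quality <- function(posterior) {
  err <- 1 - posterior
  gq <- ifelse(err <= 1e-26, 255, round(-10 * log10(pmax(err, 1e-300))))
  as.integer(pmin(255, pmax(0, gq)))
}

## Total bases of `truth` intervals covered by `calls` intervals, and the
## truth total.  Both are data.tables with rname/first/last.
interval_coverage <- function(calls, truth) {
  if (nrow(truth) == 0L) return(list(covered = 0, total = 0))
  tr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    truth$rname, IRanges::IRanges(truth$first, truth$last)))
  total <- sum(BiocGenerics::width(tr))
  if (is.null(calls) || nrow(calls) == 0L)
    return(list(covered = 0, total = total))
  cl <- GenomicRanges::reduce(GenomicRanges::GRanges(
    calls$rname, IRanges::IRanges(calls$first, calls$last)))
  covered <- sum(BiocGenerics::width(GenomicRanges::intersect(tr, cl)))
  list(covered = covered, total = total)
}
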