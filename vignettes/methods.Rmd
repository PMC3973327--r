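---
title: "Models and methods behind vardiscover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vardiscover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vardiscover` performs integrated discovery of genomic variants from
coordinate-sorted short-read alignments: SNVs and small indels by Bayesian
genotyping of filtered pileups, copy-number variants from the read-depth
(RD) signal, large deletions and mid-size insertions from read-pair (RP)
insert-length outliers, and repetitive regions from multiply-mapped reads.
This vignette records the models, the tunable parameters and their
defaults, the design decisions taken where the design was genuinely open,
and what the bundled simulator does and does not establish.

## 1. Read-level filters

Three inexpensive filters replace heavyweight preprocessing:

* **Duplicate start capping** (`max_per_start`, default 2 records per
  (sequence, start, orientation) key). PCR amplification artifacts appear
  as stacks of reads with identical start coordinates; capping the stack
  bounds their influence on genotype likelihoods without duplicate-marking
  machinery, which interacts badly with multiply-mapped reads. Retention
  is first-seen in file order, so the operation is deterministic and
  idempotent.
* **Base-quality capping** (`q_max`, default 30). Miscalibrated,
  overconfident base qualities are the dominant source of high-confidence
  error support; scores above the cap are equalised to it. Below ~20 the
  sensitivity cost outweighs the specificity gain, so 30 is a deliberate
  middle ground.
* **3'-end trimming** (`ignore_last_n`, default 0). Machine-cycle error
  rates rise toward the end of a read; `quality_statistics()` tabulates
  per-cycle mismatch rates so users can pick a value empirically.
  Trimming counts sequenced bases from the 3' end in sequencing order —
  for reverse-strand alignments that is the *left* end of the aligned
  interval.

A record is **unique** when it is a primary alignment with mapping
quality above zero. It is flagged **multiple** when the aligner reported
more than one placement: a secondary record, or a primary with `NH > 1`.
A low mapping quality alone does not make a record "multiple" — an
aligner running in best-match mode reports one placement and no
multiplicity evidence, which is exactly why repeat detection fails under
that alignment strategy (section 5).

## 2. Bayesian genotyping

For a diploid genotype $\{X, Y\}$ at a pileup column with observations
$o_1..o_n$ (base qualities $q_i$, error probabilities
$e_i = 10^{-q_i/10}$) over an allele universe of size $k$:

$$P(o_i \mid A) = \begin{cases} 1 - e_i & o_i = A \\ e_i/(k-1) &
\text{otherwise} \end{cases},\qquad
L(\{X,Y\}) = \sum_i \log\left(\tfrac12 P(o_i \mid X) + \tfrac12
P(o_i \mid Y)\right).$$

The prior places $1-h$ on the homozygous-reference genotype and splits
the heterozygosity rate $h$ (default $10^{-3}$; inbred material warrants
$10^{-4}$) uniformly over every genotype containing a non-reference
allele — the simplest allocation consistent with a single scalar prior.
The call is the maximum-a-posteriori genotype;
$GQ = \min(255, \operatorname{round}(-10\log_{10}(1-\text{posterior})))$.
Calls are emitted when variant (or always, under `emit_all`) and
$GQ \ge$ `min_gq` (default 40). Spreading the error mass as $e/(k-1)$
generalises the familiar $e/3$ for four bases to indel allele sets.

**Indel columns.** The allele universe is the reference span plus the
distinct indel alleles observed at the (realigned) start column, keeping
the two best-supported when more occur. Reference support must *span*
the event junction — a read aligned at both the anchor and the following
base crossed the site without the indel. Reads merely starting at the
first base after an insertion carry no information about it and are
excluded; counting them as reference support systematically deflates
homozygous-insertion genotype qualities.

**Local realignment.** Each indel start is screened a few base pairs
ahead — 5 for insertions, deletion length + 2 for deletions — for the
same event (same type and length; the literal inserted/deleted strings
differ between shifted copies inside tandem context, so type+length is
the faithful equality notion) at other starts. All matching events are
relocated, by CIGAR rewriting, to the start with the highest read
support; ties break to the leftmost start; records that cannot be
rewritten consistently are left alone. Grouping anchors at the leftmost
start of a cluster: events are *not* chained transitively beyond the
scan window.

## 3. Read-depth CNV discovery

The RD signal counts alignment starts per `bin_size` (default 100 bp)
bin, including multiple placements. Bins overlapped by any
multiple-flagged record are marked non-unique, and the neutral mean and
variance are computed over *unique bins only*, which keeps samples with
recorded multiple alignments processable. GC correction rescales each
integer GC class by `m_global/m_gc` over unique bins; classes with fewer
than 100 unique bins or `m_gc < 0.1 * m_global` are left uncorrected
because the scaling would be noise.

Segmentation is mean-shift over a doubling bandwidth schedule
(2..128 bins). At each bandwidth a per-bin vector accumulates
neighbour attractions weighted by a Gaussian kernel in both index and
depth (depth variance scaled Poisson-like with the bin's level);
boundaries appear where the vector flips from leftward to rightward
pull. Segments whose mean deviates from the neutral mean by at least
$2\sigma/\sqrt{len}$ freeze their boundaries. Afterwards, adjacent
segments that do not differ significantly (Welch test backed by a
z-test against the neutral $\sigma$, Bonferroni-corrected by the local
window length because the boundary was *selected* among those
positions; `merge_alpha = 0.001`) are re-merged, so spuriously frozen
noise runs dissolve and a neutral chromosome collapses to one segment.

Calling: a segment becomes a candidate when a one-sample t-test of its
bins against the neutral mean is significant at `alpha_rd` (default
0.05) *after genome-size correction* — the reported p-value is the raw
test probability multiplied by the genome-to-segment size ratio, an
e-value in the CNVnator tradition. Without that correction the
segmentation's selection of extreme runs, together with the clustering
of mate-pair starts across neighbouring bins, makes a raw per-segment
t-test badly anti-conservative. Two further gates: single-bin segments
are never called, and the copy-number estimate
(`copies = ploidy * mean/mu`) must deviate from ploidy by at least 0.5
(the classical RD < 0.75 / RD > 1.25 call rule for a diploid).
Breakpoints are refined within ±6 bins by maximising local step
contrast. Adjacent same-type calls separated by a neutral gap shorter
than half the shorter call are merged only when the merged region stays
significant. A Gaussian second pass adds deletions where at least 3
consecutive bins sit below $\mu - 3\sigma$, never overriding or
overlapping standard-pass deletions.

## 4. Read-pair large indels

The library insert distribution is estimated from unique, properly
oriented pairs after discarding the 1% most extreme template lengths.
Pairs deviating from the mean by more than `t` standard deviations
(default 3) are clustered greedily by genomic overlap and insert
agreement (pairwise difference at most $2\sigma_I$); clusters need at
least two pairs. Event length is the cluster's mean insert minus the
library mean; the region is the interval between innermost read ends.
Significance follows the BreakDancerMax Poisson model:
$\lambda = D\,(span + \mu_I)/G$ with $D$ the genome-wide discordant
pair count and $G$ the genome size; the p-value is the upper Poisson
tail at the cluster size, thresholded at `alpha_rp` (default 0.001).
Insertions are detectable only up to roughly $\mu_I$ minus the read
lengths, by construction of the evidence. RD and RP deletion calls with
reciprocal overlap of at least 0.5 merge into a `combined` record with
the intersection breakpoints.

## 5. Repeats and alignment strategies

Overlapping multiple-flagged alignments merge into candidate intervals;
a candidate is repetitive when fewer than 20% of all alignments
overlapping it are unique. Unique reads widen the denominator but not
the interval. Secondary placements count per placement, matching the
"alignments, not reads" reading.

The alignment *strategy* decides what the detector can see. When only
the best alignment per read is kept, ambiguous reads carry MAPQ 0 with
no multiplicity evidence: the stream-level mapping-quality filter drops
them, repeat regions lose their coverage and surface as spurious
deletions, and the repeat finder finds nothing. Keeping all (or up to
three) alignments flags them as multiple: they survive the stream
filter, double the repeat-region depth into duplication calls, and feed
the repeat finder. The package's simulator reproduces both regimes.

## 6. Benchmarking machinery

Gold-standard construction takes per-parent call sets from two haploid
samples: a site enters when every call set of both parents reports one
allele with quality above 90 and the allele agrees within each parent.
Sites where parents agree are expected homozygous in an F1 pool, sites
where they differ heterozygous. Evaluation ignores sites outside the
gold standard, treats calls under the quality threshold as uncalled,
and tallies four error types (hom→het, het→hom, homref→homalt,
homalt→homref). For the heterozygous class,
$S = |G_e \cap C_e|/|G_e|$, $FDR = |G_o \cap C_e|/|C_e|$,
$FPR = |G_o \cap C_e|/|G_o|$, and symmetrically for homozygous; ROC
curves are the (FPR, S) pairs along the threshold sweep.
Zero-denominator rates are reported as 0 with an explicit flag rather
than dropped.

The pooled-segregant drift simulation draws, per site, the number of
reference-carrying segregants $n_i \sim Bin(20, 0.5)$, a depth
$d_i \sim Pois(\text{median coverage})$ and a reference read count
$\sim Bin(d_i, n_i/20)$. The published description of the third draw
("binomial with $n = n_i$ and $p = n_i/20$") is dimensionally
inconsistent — read counts must be drawn at the site's depth — and is
implemented as $Bin(d_i, n_i/20)$. Variant runs with 200 segregants or
a fixed allele frequency of 0.5 isolate the drift contribution to the
allele-frequency variance.

## 7. The simulator: what a green test establishes

`simulate_genome()`/`simulate_alignments()` generate a reference with a
sinusoidal GC gradient and an implanted near-identical (99.5%) two-copy
repeat; a diploid sample with SNVs, anchored small indels and physical
large deletions (heterozygous events on one random haplotype); and
paired 100 bp reads at 30x with inserts $\sim N(300, 50)$, per-cycle
base errors at $10^{-q/10}$, exact CIGARs from the known haplotype of
origin, and explicit multi-placement emission per strategy. Defaults
mirror a moderate-coverage resequencing regime with a flat Q30 profile.

Deliberate modelling choices:

* CNV events are *coverage multipliers* (`copies/ploidy`), not physically
  rearranged haplotypes; duplication surplus is emitted as unpaired
  single reads so start-depth edges stay sharp at the event boundaries
  (pair-position weighting alone smears apparent duplication edges by
  several bins — an artifact of the weighting, not a caller property).
  Large deletions *are* physical: pairs re-coordinate across the gap and
  junction-overlapping reads are dropped.
* Pairs whose insert would overrun the chromosome end are moved left
  rather than having their insert clamped, so the template-length
  distribution carries no chromosome-end artifact that the RP caller
  would mistake for an insertion.
* Reads falling entirely within a repeat copy are ambiguous; `best`
  reports one placement at random with MAPQ 0 and NH 1, `k3`/`all` keep
  the true placement as primary plus secondaries, all at MAPQ 0 with
  NH 2.
* The pooled-segregant mode assigns each read pair a random segregant
  whose parent-of-origin is drawn independently per recombination-free
  block (default 5 kb).

The simulator does **not** model PCR chimeras, error motifs, indel
sequencing errors, mappability structure beyond the implanted repeat, or
aligner-induced soft-clip noise. Green tests therefore establish
correctness of the statistical machinery under calibrated inputs, not
robustness to every real-library pathology.

## 8. Numerical and testing notes

* Likelihoods are computed in log space; posteriors via a stable
  log-sum-exp. The genotyper is checked against an exhaustive
  probability-space enumeration oracle to $10^{-9}$ absolute in log
  space.
* Poisson tails come from `ppois(k-1, lambda, lower.tail = FALSE)` and
  are checked against an explicit term-by-term tail summation to
  $10^{-12}$.
* The segmentation oracle (exhaustive minimal within-segment
  sum-of-squares partition) is run on toy windows where events are dense,
  so the toys pass the *neutral* noise level as $\sigma$ — on a real
  genome `neutral_stats()` estimates it from unique bins where events
  are sparse. Toy events are at least 3 bins long; single-bin events are
  below the caller's stated resolution.
* Null calibration of the RD caller is checked on independent
  Poisson bin-count replicates — the null its significance test is
  defined against; read-based fixtures add mate-pair start clustering,
  which the genome-size e-value correction absorbs.
* Scaled-down sizes in the test suite (e.g. 200 RP replicates on a 30 kb
  genome, pool agreement at ~400 sites instead of 10^4) keep the default
  run inside its time budget; the statistical content of each check is
  unchanged.

## 9. Known limitations

Multi-allelic sites are capped at 3 alternative alleles; no phasing, no
base-quality recalibration, no inversion/translocation/tandem-duplication
calling, no split-read breakpoint refinement, no re-genotyping of missing
cells during multi-sample merging. RD resolution is bounded below by the
bin size and the effect-size gate; RP insertion reach is bounded by the
insert length. The GFF/VCF writers emit minimal, standard-conforming
headers rather than the full metadata vocabulary.
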