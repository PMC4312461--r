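#' Trim-length distribution for degraded-DNA fragment sizes
#'
#' Two-sided exponential (geometric) length distribution around a mean:
#' the mean length carries `peak_fraction` of reads (the largest class) and
#' each 1 bp step away multiplies the probability by `step_factor`, truncated
#' at `mean_len +- span` and renormalized. The defaults reproduce fragment
#' sizes typical of highly degraded ancient DNA: 15% of reads at the mean
#' and a 25% decrease per bp.
#'
#' @param mean_len Mean (and modal) trimmed length, one of 40, 60, 80 in the
#'   study design, though any positive value is accepted.
#' @param span Half-width of the support (default 10 bp).
#' @param peak_fraction Raw probability at the mean (default 0.15).
#' @param step_factor Multiplicative decrease per bp (default 0.75).
#' @return A `trim_distribution` list.
#' @export
trim_distribution <- function(mean_len, span = 10L, peak_fraction = 0.15,
                              step_factor = 0.75) {
  if (step_factor <= 0 || step_factor > 1)
    stop("'step_factor' must be in (0, 1]")
  if (span < 0) stop("'span' must be >= 0")
  if (mean_len - span < 1) stop("support extends below 1 bp")
  out <- list(mean_len = as.integer(mean_len), span = as.integer(span),
              peak_fraction = peak_fraction, step_factor = step_factor)
  class(out) <- "trim_distribution"
  out
}

#' Probability mass function of trimmed read lengths
#'
#' @param dist A [trim_distribution()].
#' @return Named numeric vector over lengths `mean-span .. mean+span`,
#'   summing to 1.
#' @export
trim_length_pmf <- function(dist) {
  lens <- (dist$mean_len - dist$span):(dist$mean_len + dist$span)
  raw <- dist$peak_fraction * dist$step_factor^abs(lens - dist$mean_len)
  p <- raw / sum(raw)
  names(p) <- lens
  p
}

# Convert a Phred score to an error probability.
phred_to_error <- function(q) 10^(-q / 10)

#' Generate raw single-end reads from a diploid sample
#'
#' Draws fixed-length reads uniformly from both strands of both chromosomes,
#' reverse-complementing minus-strand reads, with a uniform per-base
#' substitution error model at constant base quality.
#'
#' @param pair A `ref_sample_pair` (or list with `chromosome1`,
#'   `chromosome2`).
#' @param raw_read_len Read length in bp (default 100).
#' @param raw_coverage Per-chromosome coverage depth of the raw pool; the
#'   combined pool has `raw_coverage * total chromosome bases / read length`
#'   reads drawn from the two chromosomes at random.
#' @param error_rate Per-base substitution error probability (default
#'   corresponds to Q35).
#' @return A `read_pool` data.frame: `chrom` (1 or 2), `start` (0-based
#'   footprint start on the source chromosome), `len`, `strand`, `n_err`,
#'   `seq`.
#' @export
generate_raw_reads <- function(pair, raw_read_len = 100L, raw_coverage,
                               error_rate = phred_to_error(35)) {
  if (raw_coverage <= 0) stop("'raw_coverage' must be positive")
  chroms <- list(pair$chromosome1, pair$chromosome2)
  if (any(nchar(unlist(chroms)) < raw_read_len))
    stop("'raw_read_len' exceeds a chromosome length")
  n <- round(raw_coverage * sum(nchar(unlist(chroms))) / raw_read_len)
  res <- cpp_generate_pool(chroms, -1, as.integer(raw_read_len), 1.0,
                           as.integer(raw_read_len), error_rate,
                           0, 0.75, 0.01, rep(1, 4), rep(1, 4), 1.0, FALSE,
                           as.integer(n))
  pool_df(res)
}

pool_df <- function(res) {
  df <- data.frame(chrom = res$chrom, start = res$start, len = res$len,
                   strand = ifelse(res$minus, "-", "+"), n_err = res$n_err,
                   seq = res$seq, stringsAsFactors = FALSE)
  attr(df, "damage_ledger") <- list(opp5 = res$opp5, flip5 = res$flip5,
                                    opp3 = res$opp3, flip3 = res$flip3)
  if (length(res$edits)) attr(df, "damage_edits") <- res$edits
  attr(df, "fragments_tried") <- res$tried
  class(df) <- c("read_pool", "data.frame")
  df
}

#' Trim reads to target lengths
#'
#' Truncates each read to its first `target_len` bases (the 5' end is kept,
#' as reads are sequenced 5' to 3'), updating the footprint coordinates so
#' the trimmed fragment's origin on the source chromosome stays exact:
#' plus-strand footprints keep their start; minus-strand footprints keep
#' their end.
#'
#' @param reads A `read_pool` data.frame.
#' @param target_len Integer vector (recycled) of target lengths; draw from
#'   [trim_length_pmf()] to reproduce the study's distributions.
#' @return The trimmed `read_pool`.
#' @export
trim_reads <- function(reads, target_len) {
  target_len <- as.integer(rep_len(target_len, nrow(reads)))
  if (any(target_len > reads$len)) stop("target_len exceeds a read length")
  if (any(target_len < 1)) stop("target_len must be >= 1")
  minus <- reads$strand == "-"
  reads$start <- ifelse(minus, reads$start + reads$len - target_len,
                        reads$start)
  reads$seq <- substr(reads$seq, 1L, target_len)
  reads$len <- target_len
  reads
}

#' Simulate a trimmed, damaged read pool from a sample
#'
#' Fused pipeline for one treatment: raw 100 bp fragments are drawn from
#' both strands of both chromosomes, trimmed to the fragment-length
#' distribution (5' end kept), retained according to the damage level's
#' fragmentation-bias acceptance rule applied to the genomic neighbours of
#' the trimmed footprint, given uniform sequencing errors, and subjected to
#' terminal deamination. Reads accumulate until the accepted pool holds
#' `target_bases` bases. Statistically identical to composing
#' [generate_raw_reads()], [trim_reads()], [accept_fragment()] and
#' [apply_misincorporation()], without materializing rejected fragments.
#'
#' @param pair A `ref_sample_pair`.
#' @param trim_dist A [trim_distribution()].
#' @param damage A [damage_config()].
#' @param target_bases Total accepted read bases to generate (e.g.
#'   `depth * reference length` plus head-room for subsampling).
#' @param raw_read_len Raw read length before trimming (default 100).
#' @param error_rate Per-base sequencing error probability.
#' @param keep_edits Keep per-read damage edit positions (list column
#'   attribute); off by default as it is memory-heavy for large pools.
#' @return A `read_pool` data.frame with a `damage_ledger` attribute holding
#'   per-offset misincorporation opportunity/event counts.
#' @export
simulate_read_pool <- function(pair, trim_dist, damage,
                               target_bases, raw_read_len = 100L,
                               error_rate = phred_to_error(35),
                               keep_edits = FALSE) {
  pmf <- trim_length_pmf(trim_dist)
  res <- cpp_generate_pool(list(pair$chromosome1, pair$chromosome2),
                           target_bases, as.integer(names(pmf)),
                           unname(pmf), as.integer(raw_read_len), error_rate,
                           damage$p0, damage$decay, damage$cutoff,
                           damage$frag_weights_5p, damage$frag_weights_3p,
                           damage$base_accept, keep_edits, -1L)
  pool_df(res)
}
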