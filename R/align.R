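#' Build a k-mer position index over a reference
#'
#' Exact k-mer index used by the built-in seed-and-extend mapper. K-mers
#' containing ambiguous bases are excluded.
#'
#' @param reference Reference sequence: a character string or a
#'   `ref_sample_pair`.
#' @param k K-mer size (4..16, default 13).
#' @return An external-pointer index object (class `pv_index`).
#' @export
build_index <- function(reference, k = 13L) {
  if (inherits(reference, "ref_sample_pair")) reference <- reference$reference
  idx <- cpp_build_index(reference, as.integer(k))
  attr(idx, "ref") <- reference
  idx
}

#' Look up a k-mer in an index
#'
#' @param index Index from [build_index()].
#' @param kmer K-mer string of length `k`.
#' @return Integer vector of 0-based reference positions (possibly empty).
#' @export
index_lookup <- function(index, kmer) cpp_index_lookup(index, kmer)

#' Map reads to the reference with the built-in aligner
#'
#' Seed-and-extend mapping emulating a BWA-aln-style contract: candidate
#' loci from exact k-mer seed hits on both strands, banded global alignment
#' of the read against each candidate window (band covers indels up to the
#' band width), and a unique-best policy -- a read whose best alignment is
#' tied between distinct loci is reported unmapped, as multi-mapping reads
#' are discarded. A read maps only if its best edit distance is at most
#' `ceiling(max_mismatch_frac * length)`.
#'
#' @param index Index from [build_index()].
#' @param reads A `read_pool` data.frame or character vector of sequences.
#' @param max_mismatch_frac Maximum edit distance as a fraction of read
#'   length (default 0.06).
#' @param band Alignment band half-width (default 6; covers indels <= 5 bp).
#' @param seed_step Offset between successive seed k-mers along the read
#'   (default 2).
#' @return data.frame: `mapped`, `pos` (0-based leftmost reference
#'   coordinate), `nm` (edit distance), `mapq`, `strand`, `cigar`, plus the
#'   read length `len`.
#' @export
map_reads <- function(index, reads, max_mismatch_frac = 0.06, band = 6L,
                      seed_step = 2L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  res <- cpp_map_reads(index, seqs, max_mismatch_frac, as.integer(band),
                       as.integer(seed_step))
  data.frame(mapped = res$mapped, pos = res$pos, nm = res$nm,
             mapq = res$mapq, strand = res$strand, cigar = res$cigar,
             ref_span = res$ref_span, len = nchar(seqs), seq = seqs,
             stringsAsFactors = FALSE)
}

#' Exhaustive-alignment reference mapper (validation oracle)
#'
#' Aligns every read against every reference position on both strands with a
#' full unbanded edit-distance DP -- no seeding heuristics. Used in tests as
#' an independent check of [map_reads()]; far too slow for production use.
#'
#' @param reference Reference string.
#' @param reads Character vector of read sequences.
#' @inheritParams map_reads
#' @return data.frame with `mapped`, `pos`, `score`.
#' @export
exhaustive_map <- function(reference, reads, max_mismatch_frac = 0.06,
                           band = 6L) {
  res <- cpp_exhaustive_map(reference, reads, max_mismatch_frac,
                            as.integer(band))
  data.frame(mapped = res$mapped, pos = res$pos, score = res$score)
}

#' Call diploid variants from a pileup of mapped reads
#'
#' Per reference column, genotype likelihoods over hom-ref / het / hom-alt
#' are computed from base observations with a per-base error rate derived
#' from the base quality (capped at `error_floor`), combined with a
#' samtools-style prior on non-reference genotypes (`theta` for het,
#' `theta/2` for hom-alt). A call is emitted when a non-reference genotype
#' is the maximum a posteriori genotype; its quality is the Phred-scaled
#' posterior against the hom-ref genotype. Indels are called from
#' consistent inserted/deleted CIGAR observations with the same machinery
#' on supporting vs spanning read counts.
#'
#' @param mapped Mapping table from [map_reads()] joined with read
#'   sequences: needs columns `mapped`, `pos`, `strand`, `cigar`, `seq`.
#' @param reference Reference string (or `ref_sample_pair`).
#' @param base_qual Constant Phred base quality of the pool (default 35).
#' @param error_floor Phred cap on per-base confidence (default 40).
#' @param theta_snp,theta_indel Prior probability of a heterozygous site.
#' @param eps_indel Per-read probability of an incorrect indel observation
#'   at a true indel-bearing column (default 0.05). This is dominated not by
#'   sequencing error but by alignment ambiguity: reads whose ends fall at
#'   or inside the event align without the indel op and masquerade as
#'   reference support, so the genotyper must tolerate a few such reads
#'   without flipping a homozygous call to heterozygous.
#' @return data.frame of candidate calls: `ref_pos` (0-based; for indels the
#'   anchor base before the event), `kind`, `ref_allele`, `alt_allele`,
#'   `genotype`, `qual`, `depth`, strand counts (`ref_fwd` ... `alt_rev`)
#'   and distance-to-read-end summary statistics used by
#'   [filter_pileup_bias()].
#' @export
pileup_and_call <- function(mapped, reference, base_qual = 35,
                            error_floor = 40, theta_snp = 1e-3,
                            theta_indel = 1e-4, eps_indel = 0.05) {
  if (inherits(reference, "ref_sample_pair")) reference <- reference$reference
  m <- mapped[mapped$mapped, , drop = FALSE]
  if (nrow(m) == 0) return(empty_calls())
  o <- order(m$pos)
  m <- m[o, , drop = FALSE]
  eps <- max(phred_to_error(base_qual), phred_to_error(error_floor))
  res <- cpp_pileup_call(reference, m$pos, m$strand, m$cigar, m$seq, eps,
                         eps_indel, theta_snp, theta_indel)
  calls <- data.frame(ref_pos = res$pos, kind = res$type,
                      ref_allele = res$ref, alt_allele = res$alt,
                      genotype = ifelse(res$gt == 2, "hom", "het"),
                      qual = res$qual, depth = res$depth,
                      ref_fwd = res$ref_fwd, ref_rev = res$ref_rev,
                      alt_fwd = res$alt_fwd, alt_rev = res$alt_rev,
                      n_ref = res$n_ref, n_alt = res$n_alt,
                      tail_mean_ref = res$tail_mean_ref,
                      tail_var_ref = res$tail_var_ref,
                      tail_mean_alt = res$tail_mean_alt,
                      tail_var_alt = res$tail_var_alt,
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$ref_pos, calls$kind), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(ref_pos = integer(0), kind = character(0),
             ref_allele = character(0), alt_allele = character(0),
             genotype = character(0), qual = numeric(0), depth = integer(0),
             ref_fwd = integer(0), ref_rev = integer(0),
             alt_fwd = integer(0), alt_rev = integer(0),
             n_ref = integer(0), n_alt = integer(0),
             tail_mean_ref = numeric(0), tail_var_ref = numeric(0),
             tail_mean_alt = numeric(0), tail_var_alt = numeric(0),
             stringsAsFactors = FALSE)
}

#' Filter calls on depth and quality
#'
#' Retains calls with depth in `[min_depth, max_depth]` and quality at least
#' `min_qual` (the study's quality filter: QUAL >= 20, depth 1..30).
#'
#' @param calls Call table from [pileup_and_call()].
#' @param min_depth,max_depth Depth bounds (defaults 1 and 30).
#' @param min_qual Minimum call quality (default 20).
#' @return Filtered call table.
#' @export
filter_calls <- function(calls, min_depth = 1, max_depth = 30,
                         min_qual = 20) {
  if (min_depth > max_depth) stop("'min_depth' must be <= 'max_depth'")
  keep <- calls$depth >= min_depth & calls$depth <= max_depth &
    calls$qual >= min_qual
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand- and end-distance-bias filters for SNP calls
#'
#' Removes SNP calls whose supporting evidence is biased the way damage
#' artifacts are: alt observations significantly closer to read ends than
#' ref observations (Welch t-test on distance to the nearest read end), or
#' significantly imbalanced between strands (Fisher exact test on the
#' ref/alt by strand table). Tests are skipped (call kept) when either
#' allele has fewer than `min_obs` observations, so low-depth calls are
#' never filtered on bias alone. Indel calls pass through untouched.
#'
#' @param calls Call table from [pileup_and_call()].
#' @param alpha_strand,alpha_tail P-value thresholds (default 1e-4, the
#'   conventional pileup-filter defaults).
#' @param min_obs Minimum ref and alt observation count for testing.
#' @return Filtered call table.
#' @export
filter_pileup_bias <- function(calls, alpha_strand = 1e-4,
                               alpha_tail = 1e-4, min_obs = 2L) {
  if (nrow(calls) == 0) return(calls)
  snp <- calls$kind == "snp"
  drop <- rep(FALSE, nrow(calls))

  testable <- snp & calls$n_ref >= min_obs & calls$n_alt >= min_obs
  # Welch t-test: alt bases nearer read ends than ref bases
  tt <- testable & is.finite(calls$tail_var_ref) &
    is.finite(calls$tail_var_alt) &
    (calls$tail_var_ref + calls$tail_var_alt) > 0
  if (any(tt)) {
    se <- sqrt(calls$tail_var_ref[tt] / calls$n_ref[tt] +
                 calls$tail_var_alt[tt] / calls$n_alt[tt])
    tstat <- (calls$tail_mean_ref[tt] - calls$tail_mean_alt[tt]) / se
    vr <- calls$tail_var_ref[tt] / calls$n_ref[tt]
    va <- calls$tail_var_alt[tt] / calls$n_alt[tt]
    dfree <- (vr + va)^2 /
      (vr^2 / pmax(calls$n_ref[tt] - 1, 1) +
         va^2 / pmax(calls$n_alt[tt] - 1, 1))
    p_tail <- pt(tstat, dfree, lower.tail = FALSE) # one-sided: alt nearer end
    drop[tt][p_tail < alpha_tail] <- TRUE
  }
  # Fisher strand bias, with a vectorized chi-square screen so the exact
  # test only runs on rows that could possibly fall below alpha
  ft <- which(testable & !drop &
                is.finite(calls$ref_fwd) & is.finite(calls$alt_fwd))
  if (length(ft)) {
    a <- calls$ref_fwd[ft]; b <- calls$ref_rev[ft]
    cc <- calls$alt_fwd[ft]; d <- calls$alt_rev[ft]
    n <- a + b + cc + d
    chi <- (a * d - b * cc)^2 * n /
      pmax((a + b) * (cc + d) * (a + cc) * (b + d), 1e-12)
    screen <- ft[stats::pchisq(chi, 1, lower.tail = FALSE) < 10 * alpha_strand]
    for (i in screen) {
      tab <- matrix(c(calls$ref_fwd[i], calls$ref_rev[i],
                      calls$alt_fwd[i], calls$alt_rev[i]), 2, 2)
      if (fisher.test(tab)$p.value < alpha_strand) drop[i] <- TRUE
    }
  }
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
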