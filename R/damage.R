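#' Post-mortem damage model configuration
#'
#' Bundles the parameters of the damage model for a named level: the
#' 5'-terminal C->T misincorporation probability `p0` with its positional
#' `decay` and `cutoff`, and the fragmentation-bias weight tables for the
#' genomic base immediately 5' of the fragment start (purines favoured,
#' G over A by ~2x) and immediately 3' of the fragment end (the pyrimidine
#' mirror). Preset levels:
#'
#' * `none`: no misincorporation, unbiased fragment acceptance at 0.5.
#' * `low`:  p0 = 0.12 (damage reaches 9 positions per end);
#'   5' weights G 1.2, A 1.1, T 0.9, C 0.8 (+20%/+10% G/A enrichment).
#' * `high`: p0 = 0.40 (13 positions per end);
#'   5' weights G 1.6, A 1.3, T 0.7, C 0.4 (+60%/+30%).
#'
#' Acceptance probability is `base_accept * w5 * w3 / max(w5) / max(w3)`, so
#' the most-favoured context is accepted at `base_accept` and only relative
#' weights shape the composition.
#'
#' @param level `"none"`, `"low"` or `"high"`.
#' @param p0,decay,cutoff Misincorporation model overrides.
#' @param frag_weights_5p,frag_weights_3p Length-4 weight vectors in
#'   A, C, G, T order.
#' @param base_accept Acceptance probability of the most-favoured context.
#' @return A `damage_config` list.
#' @export
damage_config <- function(level = c("none", "low", "high"), p0 = NULL,
                          decay = 0.75, cutoff = 0.01,
                          frag_weights_5p = NULL, frag_weights_3p = NULL,
                          base_accept = 0.5) {
  level <- match.arg(level)
  if (is.null(p0)) p0 <- switch(level, none = 0, low = 0.12, high = 0.4)
  if (is.null(frag_weights_5p))
    frag_weights_5p <- switch(level,
      none = c(A = 1, C = 1, G = 1, T = 1),
      low  = c(A = 1.1, C = 0.8, G = 1.2, T = 0.9),
      high = c(A = 1.3, C = 0.4, G = 1.6, T = 0.7))
  if (is.null(frag_weights_3p))
    frag_weights_3p <- switch(level,
      none = c(A = 1, C = 1, G = 1, T = 1),
      low  = c(A = 0.9, C = 1.2, G = 0.8, T = 1.1),
      high = c(A = 0.7, C = 1.6, G = 0.4, T = 1.3))
  if (p0 < 0 || p0 > 1) stop("'p0' must be in [0, 1]")
  if (decay <= 0 || decay > 1) stop("'decay' must be in (0, 1]")
  if (any(frag_weights_5p <= 0) || any(frag_weights_3p <= 0))
    stop("fragmentation weights must be positive")
  out <- list(level = level, p0 = p0, decay = decay, cutoff = cutoff,
              frag_weights_5p = frag_weights_5p,
              frag_weights_3p = frag_weights_3p, base_accept = base_accept)
  class(out) <- "damage_config"
  out
}

#' Number of read positions eligible for misincorporation
#'
#' The largest n such that `p0 * decay^(n-1) >= cutoff` -- the number of
#' positions from each read end where deamination damage can be introduced
#' (9 for the low preset, 13 for the high preset).
#'
#' @param p0 Terminal misincorporation probability.
#' @param decay Per-position decay factor.
#' @param cutoff Probability below which damage is no longer introduced.
#' @return Integer count (0 when `p0 < cutoff`).
#' @export
eligible_positions <- function(p0, decay, cutoff) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  if (p0 < cutoff) return(0L)
  if (decay >= 1) stop("decay >= 1 with p0 >= cutoff gives unbounded damage")
  if (decay <= 0) stop("'decay' must be in (0, 1)")
  n <- 0L
  p <- p0
  while (p >= cutoff) {
    n <- n + 1L
    p <- p * decay
  }
  n
}

#' Fragmentation-bias acceptance probability
#'
#' Probability that a trimmed fragment is retained, given the genomic bases
#' flanking it on its source strand: `base_5p` immediately 5' of the
#' fragment start, `base_3p` immediately 3' of the fragment end. `NA` (a
#' fragment at a contig end) has weight 1.
#'
#' @param base_5p,base_3p Character vectors of single bases (or `NA`).
#' @param config A [damage_config()].
#' @return Numeric vector of acceptance probabilities.
#' @export
accept_fragment_prob <- function(base_5p, base_3p, config) {
  w <- function(b, tab) {
    out <- rep(1, length(b))
    m <- match(toupper(b), c("A", "C", "G", "T"))
    out[!is.na(m)] <- tab[m[!is.na(m)]]
    out
  }
  config$base_accept * w(base_5p, config$frag_weights_5p) *
    w(base_3p, config$frag_weights_3p) /
    (max(config$frag_weights_5p) * max(config$frag_weights_3p))
}

#' Accept or reject fragments by their flanking genomic context
#'
#' @inheritParams accept_fragment_prob
#' @return Logical vector: `TRUE` for accepted fragments.
#' @export
accept_fragment <- function(base_5p, base_3p, config) {
  p <- accept_fragment_prob(base_5p, base_3p, config)
  runif(length(p)) < p
}

#' Apply terminal deamination misincorporations to reads
#'
#' Scans each read (as sequenced) from the 5' end flipping C->T with
#' probability `p0 * decay^i` at offset i, and symmetrically from the 3' end
#' flipping G->A, until the probability falls below `cutoff`. No other
#' changes are made.
#'
#' @param reads A `read_pool` data.frame or character vector of sequences.
#' @param config A [damage_config()].
#' @param keep_edits Record per-read flipped positions (1-based).
#' @return Object of the same type with damaged sequences; attributes
#'   `damage_ledger` (per-offset opportunity/flip counts) and, if requested,
#'   `damage_edits`.
#' @export
apply_misincorporation <- function(reads, config, keep_edits = TRUE) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  res <- cpp_apply_damage(seqs, config$p0, config$decay, config$cutoff,
                          keep_edits)
  ledger <- list(opp5 = res$opp5, flip5 = res$flip5, opp3 = res$opp3,
                 flip3 = res$flip3)
  if (is.data.frame(reads)) {
    reads$seq <- res$seq
    attr(reads, "damage_ledger") <- ledger
    if (keep_edits) attr(reads, "damage_edits") <- res$edits
    reads
  } else {
    out <- res$seq
    attr(out, "damage_ledger") <- ledger
    if (keep_edits) attr(out, "damage_edits") <- res$edits
    out
  }
}

#' Subsample a read pool to a target coverage depth
#'
#' Draws reads without replacement, in random order, until the cumulative
#' trimmed bases reach `depth * ref_len` (coverage depth is counted as drawn
#' read bases over the haploid reference length). Deterministic given the
#' RNG state.
#'
#' @param pool A `read_pool` data.frame.
#' @param depth Target coverage depth (x).
#' @param ref_len Reference length in bp.
#' @return The subsampled `read_pool` with attribute `realized_depth`.
#' @export
subsample_to_depth <- function(pool, depth, ref_len) {
  if (depth < 0) stop("'depth' must be >= 0")
  need <- depth * ref_len
  if (need == 0) {
    out <- pool[integer(0), , drop = FALSE]
    attr(out, "realized_depth") <- 0
    return(out)
  }
  if (sum(as.numeric(pool$len)) < need)
    stop("pool holds fewer bases than depth * ref_len; ",
         "increase the generated pool size (raw coverage)")
  ord <- sample.int(nrow(pool))
  cum <- cumsum(as.numeric(pool$len[ord]))
  k <- which(cum >= need)[1]
  out <- pool[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "realized_depth") <- cum[k] / ref_len
  class(out) <- c("read_pool", "data.frame")
  out
}
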