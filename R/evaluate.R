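# Maximum-cardinality one-to-one matching of called to truth positions on a
# line with a +-window tolerance: called events in increasing position order
# are matched to the leftmost unmatched truth position within the window
# (optimal for this convex structure).
match_positions <- function(called_pos, truth_pos, window) {
  nc <- length(called_pos)
  nt <- length(truth_pos)
  cm <- rep(NA_integer_, nc)
  if (nc == 0 || nt == 0)
    return(list(called_match = cm, n_matched = 0L))
  oc <- order(called_pos)
  ot <- order(truth_pos)
  ts <- truth_pos[ot]
  used <- logical(nt)
  ti <- 1L
  for (c in oc) {
    p <- called_pos[c]
    while (ti <= nt && (used[ti] || ts[ti] < p - window)) ti <- ti + 1L
    if (ti <= nt && ts[ti] <= p + window) {
      cm[c] <- ot[ti]
      used[ti] <- TRUE
    }
  }
  list(called_match = cm, n_matched = sum(!is.na(cm)))
}

#' Match called indels to truth indels within a position window
#'
#' One-to-one maximum matching: a called indel is correct when its (left
#' aligned) position lies within `window` bp of an unmatched truth indel --
#' position only, since placement may legitimately differ between the
#' truth alignment and the read alignment. Events outside the edge margin
#' are excluded first.
#'
#' @param called,truth data.frames with `ref_pos` (0-based) and `genotype`;
#'   typically the indel rows of a call table and a truth catalog.
#' @param window Matching window in bp (default 3).
#' @param edge_margin,ref_len Evaluation window (margin ignored when
#'   `ref_len` is NULL).
#' @return List with the filtered `called`/`truth` tables, `called_match`
#'   (index into `truth` for each called row, NA = unmatched/incorrect) and
#'   `n_matched`.
#' @export
match_indels <- function(called, truth, window = 3L, edge_margin = 500L,
                         ref_len = NULL) {
  if (!is.null(ref_len)) {
    called <- pos_in_window(called, ref_len, edge_margin)
    truth <- pos_in_window(truth, ref_len, edge_margin)
  }
  m <- match_positions(called$ref_pos, truth$ref_pos, window)
  list(called = called, truth = truth, called_match = m$called_match,
       n_matched = m$n_matched)
}

pos_in_window <- function(df, ref_len, margin) {
  pos1 <- df$ref_pos + 1L
  out <- df[pos1 >= margin & pos1 <= ref_len - margin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# distance from each position to the nearest position in `anchors`
nearest_distance <- function(pos, anchors) {
  if (length(anchors) == 0) return(rep(Inf, length(pos)))
  a <- sort(anchors)
  i <- findInterval(pos, a)
  lo <- ifelse(i >= 1, abs(pos - a[pmax(i, 1)]), Inf)
  hi <- ifelse(i < length(a), abs(a[pmin(i + 1L, length(a))] - pos), Inf)
  pmin(lo, hi)
}

#' Match called SNPs to truth SNPs
#'
#' A SNP call is correct when both its position and its alternate base match
#' a truth SNP. SNPs (called and truth) within `indel_exclusion` bp of any
#' indel position -- truth or called -- are excluded from both sets before
#' matching. Heterozygous positions are treated at the allele level: a
#' homozygous record contributes two allele calls, a heterozygous record
#' one, so a truth het called hom yields one correct and one spurious
#' allele call.
#'
#' @param called,truth SNP tables with `ref_pos`, `alt_allele`, `genotype`.
#' @param indel_pos Integer vector of indel positions (truth and called).
#' @param indel_exclusion Exclusion radius in bp (default 5: only SNPs
#'   more than 5 bp from an indel are scored).
#' @param edge_margin,ref_len Evaluation window (margin ignored when
#'   `ref_len` is NULL).
#' @return List with filtered tables and allele-level tallies:
#'   `called_alleles`, `correct_alleles`, `truth_alleles`, plus per-record
#'   `called_correct` flags.
#' @export
match_snps <- function(called, truth, indel_pos = integer(0),
                       indel_exclusion = 5L, edge_margin = 500L,
                       ref_len = NULL) {
  if (!is.null(ref_len)) {
    called <- pos_in_window(called, ref_len, edge_margin)
    truth <- pos_in_window(truth, ref_len, edge_margin)
  }
  if (length(indel_pos)) {
    called <- called[nearest_distance(called$ref_pos, indel_pos) >
                       indel_exclusion, , drop = FALSE]
    truth <- truth[nearest_distance(truth$ref_pos, indel_pos) >
                     indel_exclusion, , drop = FALSE]
  }
  mult <- function(g) ifelse(g == "hom", 2L, 1L)
  called$mult <- mult(called$genotype)
  truth$mult <- mult(truth$genotype)
  key_c <- paste(called$ref_pos, called$alt_allele)
  key_t <- paste(truth$ref_pos, truth$alt_allele)
  j <- match(key_c, key_t)
  called_correct <- !is.na(j)
  correct_alleles <- sum(pmin(called$mult[called_correct],
                              truth$mult[j[called_correct]]))
  list(called = called, truth = truth, called_correct = called_correct,
       truth_matched = j,
       called_alleles = sum(called$mult),
       correct_alleles = correct_alleles,
       truth_alleles = sum(truth$mult))
}

#' Score one read pool's calls against the truth
#'
#' Applies the study's matching rules -- exact position+base for SNPs with a
#' >5 bp indel-exclusion zone, a +-3 bp position window for indels, a 500 bp
#' edge margin -- and computes per-kind accuracy (% of calls that are
#' correct), completeness (% of true variants recovered) and the
#' homozygous:heterozygous ratio of ratios (observed hom:het among correct
#' calls over true hom:het; 1 = unbiased zygosity recovery). Accuracy is NA,
#' not 0, when no calls of a kind were made.
#'
#' @param calls Filtered call table ([pileup_and_call()] +
#'   [filter_calls()]).
#' @param truth Truth catalog from [simulate_pair()].
#' @param ref_len Reference length.
#' @param edge_margin Flank exclusion in bp (default 500).
#' @param indel_window Indel matching window (default 3).
#' @param indel_exclusion SNP-near-indel exclusion radius (default 5).
#' @return One-row data.frame with `snp_accuracy`, `snp_completeness`,
#'   `indel_accuracy`, `indel_completeness`, `snp_homhet_rr`,
#'   `indel_homhet_rr` and the underlying counts.
#' @export
evaluate_pool <- function(calls, truth, ref_len, edge_margin = 500L,
                          indel_window = 3L, indel_exclusion = 5L) {
  is_indel_c <- calls$kind %in% c("insertion", "deletion")
  is_indel_t <- truth$kind %in% c("insertion", "deletion")
  called_snp <- calls[!is_indel_c, , drop = FALSE]
  called_ind <- calls[is_indel_c, , drop = FALSE]
  truth_snp <- truth[!is_indel_t, , drop = FALSE]
  truth_ind <- truth[is_indel_t, , drop = FALSE]

  im <- match_indels(called_ind, truth_ind, window = indel_window,
                     edge_margin = edge_margin, ref_len = ref_len)
  ind_mult_c <- ifelse(im$called$genotype == "hom", 2L, 1L)
  ind_mult_t <- ifelse(im$truth$genotype == "hom", 2L, 1L)
  matched <- !is.na(im$called_match)
  ind_correct <- sum(pmin(ind_mult_c[matched],
                          ind_mult_t[im$called_match[matched]]))
  ind_called <- sum(ind_mult_c)
  ind_truth <- sum(ind_mult_t)

  sm <- match_snps(called_snp, truth_snp,
                   indel_pos = c(im$called$ref_pos, im$truth$ref_pos),
                   indel_exclusion = indel_exclusion,
                   edge_margin = edge_margin, ref_len = ref_len)

  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rr <- function(cor_gt, truth_gt) {
    oh <- sum(cor_gt == "hom")
    oe <- sum(cor_gt == "het")
    th <- sum(truth_gt == "hom")
    te <- sum(truth_gt == "het")
    if (oe == 0 || te == 0 || th == 0) return(NA_real_)
    (oh / oe) / (th / te)
  }

  data.frame(
    snp_accuracy = pct(sm$correct_alleles, sm$called_alleles),
    snp_completeness = pct(sm$correct_alleles, sm$truth_alleles),
    indel_accuracy = pct(ind_correct, ind_called),
    indel_completeness = pct(ind_correct, ind_truth),
    snp_homhet_rr = rr(sm$called$genotype[sm$called_correct],
                       sm$truth$genotype),
    indel_homhet_rr = rr(im$called$genotype[matched], im$truth$genotype),
    n_snp_called = nrow(sm$called), n_snp_truth = nrow(sm$truth),
    n_snp_correct_alleles = sm$correct_alleles,
    n_indel_called = nrow(im$called), n_indel_truth = nrow(im$truth),
    n_indel_matched = im$n_matched)
}

#' Mappability statistics of a mapped pool
#'
#' @param mapped Mapping table from [map_reads()].
#' @return One-row data.frame: `pct_reads_mapped`, `mean_mapped_read_len`,
#'   `pct_unique_5prime_starts` (fraction of mapped reads whose 5' mapping
#'   coordinate, with strand, is not shared with any other mapped read).
#' @export
mapping_stats <- function(mapped) {
  n <- nrow(mapped)
  m <- mapped[mapped$mapped, , drop = FALSE]
  if (nrow(m) == 0)
    return(data.frame(pct_reads_mapped = 0, mean_mapped_read_len = NA_real_,
                      pct_unique_5prime_starts = NA_real_))
  span <- if ("ref_span" %in% names(m)) m$ref_span else cigar_ref_span(m$cigar)
  p5 <- ifelse(m$strand == "-", m$pos + span - 1L, m$pos)
  key <- 2 * p5 + (m$strand == "-")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  data.frame(pct_reads_mapped = 100 * nrow(m) / n,
             mean_mapped_read_len = mean(m$len),
             pct_unique_5prime_starts = 100 * mean(!dup))
}
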