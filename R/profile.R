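#' Reference base composition around mapped fragment ends
#'
#' Tabulates the reference base at relative positions around the 5' starts
#' (-window .. -1) and 3' ends (+1 .. +window) of mapped reads, strand-aware
#' (reverse-strand reads are complemented and mirrored so positions are in
#' read orientation), and reports each base's frequency and its ratio to the
#' genomic background. Fragmentation bias shows up as purine enrichment
#' immediately 5' of fragment starts and pyrimidine enrichment immediately
#' 3' of fragment ends.
#'
#' @param mapped Mapping table from [map_reads()] (mapped rows are used).
#' @param reference Reference string or `ref_sample_pair`.
#' @param window Number of flanking positions per side (default 10).
#' @return A `composition_profile` list with `freq` (data.frame: `end`
#'   \{"5p","3p"\}, `offset` (negative = outside the fragment before its 5'
#'   start; positive = outside past its 3' end), base frequencies, `ratio_*`
#'   columns) and `background`.
#' @export
composition_around_ends <- function(mapped, reference, window = 10L) {
  if (inherits(reference, "ref_sample_pair")) reference <- reference$reference
  m <- mapped[mapped$mapped, , drop = FALSE]
  if (nrow(m) == 0) stop("no mapped reads to profile")
  refv <- strsplit(reference, "", fixed = TRUE)[[1]]
  L <- length(refv)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bg <- table(factor(refv, levels = bases)) / L

  ref_span <- if ("ref_span" %in% names(m)) m$ref_span
              else cigar_ref_span(m$cigar)
  # genomic coordinate of the base at distance d outside each fragment end,
  # on the read's strand
  start_ <- m$pos                # 0-based leftmost
  end_ <- m$pos + ref_span - 1L  # 0-based rightmost
  minus <- m$strand == "-"

  tab_one <- function(d, five_prime) {
    # five_prime: positions before the read's 5' start; else after 3' end
    if (five_prime) {
      g <- ifelse(minus, end_ + d, start_ - d)
    } else {
      g <- ifelse(minus, start_ - d, end_ + d)
    }
    ok <- g >= 0 & g < L
    b <- refv[g[ok] + 1L]
    b <- ifelse(minus[ok], comp[b], b)
    table(factor(b, levels = bases))
  }

  rows <- list()
  for (d in seq_len(window)) {
    t5 <- tab_one(d, TRUE)
    t3 <- tab_one(d, FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(end = "5p", offset = -d, t(as.numeric(t5 / sum(t5))))
    rows[[length(rows) + 1L]] <-
      data.frame(end = "3p", offset = d, t(as.numeric(t3 / sum(t3))))
  }
  freq <- do.call(rbind, rows)
  names(freq)[3:6] <- bases
  for (b in bases) freq[[paste0("ratio_", b)]] <- freq[[b]] / as.numeric(bg[b])
  freq <- freq[order(freq$end, freq$offset), , drop = FALSE]
  rownames(freq) <- NULL
  out <- list(freq = freq, background = bg, n_reads = nrow(m))
  class(out) <- "composition_profile"
  out
}

# Reference bases consumed by each CIGAR string (M and D ops).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MID]", cg))[[1]]
    sum(lens[ops != "I"])
  }, integer(1), USE.NAMES = FALSE)
}

#' Misincorporation frequency by read position
#'
#' Observed C->T rate by offset from the 5' end and G->A rate by offset from
#' the 3' end of mapped reads, in read orientation, counting only CIGAR
#' match columns where the reference provides the opportunity (a C or G
#' respectively). If an injected-damage ledger is supplied (attribute
#' `damage_ledger` of the pool, or passed directly), the injected rates are
#' reported alongside so mapping attrition of damaged reads is visible.
#'
#' @param mapped Mapping table from [map_reads()].
#' @param reference Reference string or `ref_sample_pair`.
#' @param max_offset Offsets 0..max_offset-1 are profiled (default 25).
#' @param ledger Optional injected-damage ledger (list with `opp5`, `flip5`,
#'   `opp3`, `flip3`).
#' @return data.frame: `end`, `offset`, `opportunities`, `events`,
#'   `rate`, and `injected_rate` when a ledger is available.
#' @export
misincorporation_by_position <- function(mapped, reference, max_offset = 25L,
                                         ledger = NULL) {
  if (inherits(reference, "ref_sample_pair")) reference <- reference$reference
  if (is.null(ledger)) ledger <- attr(mapped, "damage_ledger")
  m <- mapped[mapped$mapped, , drop = FALSE]
  res <- cpp_misincorporation_profile(reference, m$pos, m$strand, m$cigar,
                                      m$seq, as.integer(max_offset))
  out <- rbind(
    data.frame(end = "5p", offset = 0:(max_offset - 1L),
               opportunities = res$opp5, events = res$ct5,
               rate = ifelse(res$opp5 > 0, res$ct5 / res$opp5, NA_real_)),
    data.frame(end = "3p", offset = 0:(max_offset - 1L),
               opportunities = res$opp3, events = res$ga3,
               rate = ifelse(res$opp3 > 0, res$ga3 / res$opp3, NA_real_)))
  if (!is.null(ledger)) {
    k <- min(max_offset, length(ledger$opp5))
    inj <- rep(NA_real_, nrow(out))
    r5 <- ifelse(ledger$opp5[1:k] > 0, ledger$flip5[1:k] / ledger$opp5[1:k],
                 NA_real_)
    r3 <- ifelse(ledger$opp3[1:k] > 0, ledger$flip3[1:k] / ledger$opp3[1:k],
                 NA_real_)
    inj[out$end == "5p"][1:k] <- r5
    inj[out$end == "3p"][1:k] <- r3
    out$injected_rate <- inj
  }
  out
}
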