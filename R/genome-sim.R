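#' Discrete-gamma rate categories
#'
#' Equal-probability discretization of a mean-1 gamma distribution by quantile
#' midpoints, the standard approximation for among-site rate heterogeneity.
#' Rates are renormalized so their mean is exactly 1.
#'
#' @param shape Gamma shape parameter (> 0). Shape 1 gives strongly skewed
#'   rates; large shapes approach rate homogeneity.
#' @param ncat Number of categories (>= 1).
#' @return Numeric vector of `ncat` strictly increasing rate multipliers with
#'   mean 1.
#' @examples
#' discrete_gamma_rates(1, 4)
#' @export
discrete_gamma_rates <- function(shape, ncat) {
  if (!is.numeric(shape) || length(shape) != 1 || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a positive number")
  if (!is.numeric(ncat) || length(ncat) != 1 || ncat < 1 || ncat != round(ncat))
    stop("'ncat' must be a positive integer")
  p <- (seq_len(ncat) - 0.5) / ncat
  r <- qgamma(p, shape = shape, rate = shape)
  r / mean(r)
}

#' HKY85 transition probability matrix
#'
#' Closed-form substitution probabilities under the HKY model (unequal base
#' frequencies, transition/transversion ratio `kappa`), computed by spectral
#' decomposition of the reversible rate matrix. The rate matrix is scaled so
#' one unit of branch length equals one expected substitution per site at
#' relative rate 1.
#'
#' @param kappa Transition/transversion rate multiplier (> 0).
#' @param base_freqs Stationary frequencies in A, C, G, T order (sum to 1).
#' @param branch_length Expected substitutions per site (>= 0).
#' @param rate Site-specific rate multiplier (default 1).
#' @return 4x4 row-stochastic matrix with rows/columns named A, C, G, T;
#'   `P[i, j]` is the probability that base i is base j after the branch.
#' @export
hky_transition_matrix <- function(kappa, base_freqs, branch_length, rate = 1) {
  if (kappa <= 0) stop("'kappa' must be positive")
  if (length(base_freqs) != 4 || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-8)
    stop("'base_freqs' must be 4 non-negative values summing to 1")
  if (branch_length < 0) stop("'branch_length' must be non-negative")
  if (rate < 0) stop("'rate' must be non-negative")
  pi <- as.numeric(base_freqs)
  bases <- c("A", "C", "G", "T")
  # transitions: A<->G, C<->T
  R <- matrix(1, 4, 4)
  R[1, 3] <- R[3, 1] <- kappa
  R[2, 4] <- R[4, 2] <- kappa
  Q <- R * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu > 0) Q <- Q / mu
  t <- branch_length * rate
  # reversible Q: symmetrize with sqrt(pi) similarity transform
  sp <- sqrt(pmax(pi, 1e-300))
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- diag(1 / sp) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sp)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(bases, bases)
  P
}

#' Truncated power-law indel lengths
#'
#' Lengths k in 1..max_len with probability proportional to k^(-a).
#'
#' @param a Power-law exponent (a = 0 gives uniform lengths).
#' @param max_len Maximum indel length (>= 1).
#' @param n Number of lengths to draw.
#' @return Integer vector of `n` lengths.
#' @export
sample_indel_length <- function(a, max_len, n = 1) {
  if (max_len < 1 || max_len != round(max_len)) stop("'max_len' must be a positive integer")
  k <- seq_len(max_len)
  sample.int(max_len, n, replace = TRUE, prob = k^(-a))
}

#' Configuration for a reference/diploid-sample simulation
#'
#' @param length_bp Target sequence length. The full study scale is
#'   10,001,000 bp; reduced lengths are appropriate for desk-scale runs.
#' @param gc_content Stationary GC fraction; G and C each get half.
#' @param divergence_level `"low"` (~2.6 variant positions per kb) or
#'   `"high"` (~29 per kb).
#' @param kappa,gamma_shape,n_rate_categories,prop_invariant HKY +
#'   discrete-gamma + invariant-sites parameters.
#' @param indel_power_a,indel_max_len_bp Truncated power-law indel length
#'   model.
#' @param branch_scale Expected substitutions per site per tree unit `x` in
#'   the tree (reference:1x,(chr1:0.5x,chr2:0.5x):0.5x). Leave `NULL` and
#'   call [calibrate_branch_scale()] to solve for the value matching the
#'   divergence level's variant-position density.
#' @param seed Integer seed for the simulation.
#' @return A `genome_sim_config` list.
#' @export
genome_sim_config <- function(length_bp = 10001000L, gc_content = 0.5,
                              divergence_level = c("low", "high"), kappa = 2,
                              gamma_shape = 1, n_rate_categories = 4L,
                              prop_invariant = 0.1, indel_power_a = 1.7,
                              indel_max_len_bp = 5L, branch_scale = NULL,
                              seed = 1L) {
  divergence_level <- match.arg(divergence_level)
  if (gc_content <= 0 || gc_content >= 1) stop("'gc_content' must be in (0, 1)")
  if (prop_invariant < 0 || prop_invariant >= 1)
    stop("'prop_invariant' must be in [0, 1)")
  if (indel_max_len_bp < 1) stop("'indel_max_len_bp' must be >= 1")
  if (kappa <= 0) stop("'kappa' must be positive")
  cfg <- list(length_bp = as.integer(length_bp), gc_content = gc_content,
              divergence_level = divergence_level, kappa = kappa,
              gamma_shape = gamma_shape,
              n_rate_categories = as.integer(n_rate_categories),
              prop_invariant = prop_invariant, indel_power_a = indel_power_a,
              indel_max_len_bp = as.integer(indel_max_len_bp),
              branch_scale = branch_scale, seed = as.integer(seed))
  class(cfg) <- "genome_sim_config"
  cfg
}

# Stationary frequencies in A,C,G,T order for a GC fraction.
gc_base_freqs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

# Target variant positions per bp by divergence level.
divergence_target_density <- function(level) {
  switch(level, low = 2.6 / 1000, high = 2.9 / 100,
         stop("unknown divergence level"))
}

# Mean of the truncated power-law indel length distribution.
indel_mean_length <- function(a, max_len) {
  k <- seq_len(max_len)
  w <- k^(-a)
  sum(k * w) / sum(w)
}

# Expected variant-position density (per aligned position) as a function of
# the tree unit x: SNP positions from the exact probability that either
# chromosome differs from the reference at a site, averaged over rate
# categories; indel positions are set equal to the SNP density by
# construction (events at SNP density / mean indel length).
expected_variant_density <- function(cfg, x) {
  snp <- expected_snp_density(cfg, x)
  snp * 2
}

expected_snp_density <- function(cfg, x) {
  freqs <- gc_base_freqs(cfg$gc_content)
  rates <- discrete_gamma_rates(cfg$gamma_shape, cfg$n_rate_categories)
  p_var <- vapply(rates, function(r) {
    P_int <- hky_transition_matrix(cfg$kappa, freqs, 1.5 * x, r)
    P_ter <- hky_transition_matrix(cfg$kappa, freqs, 0.5 * x, r)
    same <- 0
    for (a in 1:4) {
      # both chromosomes equal to the reference base a
      same <- same + freqs[a] * sum(P_int[a, ] * P_ter[, a]^2)
    }
    1 - same
  }, numeric(1))
  (1 - cfg$prop_invariant) * mean(p_var)
}

#' Calibrate the tree scale to a divergence level's variant density
#'
#' Solves for the tree unit `x` such that the expected variant-position
#' density (SNP positions plus an equal share of indel-affected positions)
#' matches the divergence level's target: ~2.6 per kb for low divergence and
#' ~29 per kb for high divergence.
#'
#' @param config A [genome_sim_config()].
#' @param target_density Variant positions per bp; defaults to the level's
#'   target.
#' @return The config with `branch_scale` filled in.
#' @export
calibrate_branch_scale <- function(config, target_density = NULL) {
  if (is.null(target_density))
    target_density <- divergence_target_density(config$divergence_level)
  f <- function(x) expected_variant_density(config, x) - target_density
  sol <- stats::uniroot(f, interval = c(1e-8, 2), tol = 1e-10)
  config$branch_scale <- sol$root
  config
}

# Substitute along one branch: child base sampled from the HKY transition
# matrix of the site's rate category. seq is an integer vector in 1..4;
# cat_idx is 0 for invariant sites.
branch_substitute <- function(seq, t_sub, cat_idx, rates, kappa, freqs) {
  if (t_sub <= 0) return(seq)
  out <- seq
  for (cc in seq_along(rates)) {
    P <- hky_transition_matrix(kappa, freqs, t_sub, rates[cc])
    for (b in 1:4) {
      ii <- which(cat_idx == cc & seq == b)
      if (length(ii))
        out[ii] <- sample.int(4, length(ii), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

# Draw indel event positions (1-based anchors) with a minimum spacing, by
# resampling collisions so the event count is preserved.
draw_indel_positions <- function(n, L, spacing) {
  if (n == 0) return(integer(0))
  lo <- spacing + 1L
  hi <- L - spacing - 1L
  if (hi <= lo) stop("sequence too short for requested indel count")
  pos <- integer(0)
  attempts <- 0L
  while (length(pos) < n) {
    need <- n - length(pos)
    cand <- lo + sample.int(hi - lo + 1L, need, replace = TRUE) - 1L
    ok <- rep(TRUE, need)
    all_pos <- c(pos, cand)
    o <- order(all_pos)
    sorted <- all_pos[o]
    bad <- which(diff(sorted) < spacing)
    bad_ids <- unique(c(o[bad], o[bad + 1L]))
    bad_ids <- bad_ids[bad_ids > length(pos)] - length(pos)
    if (length(bad_ids)) ok[bad_ids] <- FALSE
    pos <- c(pos, cand[ok])
    attempts <- attempts + 1L
    if (attempts > 1000L) stop("could not place indels at requested density")
  }
  sort(pos[seq_len(n)])
}

#' Simulate a reference and divergent diploid sample pair
#'
#' Evolves sequences along the tree
#' (reference:1x,(chromosome1:0.5x,chromosome2:0.5x):0.5x) under HKY with
#' discrete-gamma rate heterogeneity and invariant sites, plus power-law
#' indels placed uniformly. Substitutions on the shared reference-to-ancestor
#' path appear on both chromosomes (homozygous); substitutions on a terminal
#' branch appear on one (heterozygous). Every event is recorded in a truth
#' catalog keyed to reference coordinates.
#'
#' @param config A [genome_sim_config()] with `branch_scale` set (see
#'   [calibrate_branch_scale()]).
#' @return An object of class `ref_sample_pair`: list with `reference`,
#'   `chromosome1`, `chromosome2` (character strings), `truth` (data.frame
#'   with 0-based `ref_pos`, `kind`, `ref_allele`, `alt_allele`, `genotype`,
#'   `on_chr1`, `on_chr2`), `site_rates`, and `config`.
#' @export
simulate_pair <- function(config) {
  cfg <- config
  if (is.null(cfg$branch_scale))
    stop("config$branch_scale is NULL; run calibrate_branch_scale() first")
  set.seed(cfg$seed)
  L <- cfg$length_bp
  x <- cfg$branch_scale
  freqs <- gc_base_freqs(cfg$gc_content)
  rates <- discrete_gamma_rates(cfg$gamma_shape, cfg$n_rate_categories)

  # per-site rate categories; 0 = invariant
  cat_idx <- sample.int(cfg$n_rate_categories, L, replace = TRUE)
  cat_idx[runif(L) < cfg$prop_invariant] <- 0L
  site_rates <- ifelse(cat_idx == 0L, 0, rates[pmax(cat_idx, 1L)])

  ref <- sample.int(4, L, replace = TRUE, prob = freqs)
  internal <- branch_substitute(ref, 1.5 * x, cat_idx, rates, cfg$kappa, freqs)
  chr1 <- branch_substitute(internal, 0.5 * x, cat_idx, rates, cfg$kappa, freqs)
  chr2 <- branch_substitute(internal, 0.5 * x, cat_idx, rates, cfg$kappa, freqs)

  # indel events: total count set so indel-affected positions match SNP
  # positions in expectation; branch shares proportional to branch length
  mean_len <- indel_mean_length(cfg$indel_power_a, cfg$indel_max_len_bp)
  snp_density <- expected_snp_density(cfg, x)
  n_events <- if (x > 0) rpois(1, L * snp_density / mean_len) else 0L
  spacing <- 2L * cfg$indel_max_len_bp + 2L
  events <- NULL
  if (n_events > 0) {
    pos <- draw_indel_positions(n_events, L, spacing)
    branch <- sample(c("hom", "chr1", "chr2"), n_events, replace = TRUE,
                     prob = c(1.5, 0.5, 0.5))
    kind <- sample(c("insertion", "deletion"), n_events, replace = TRUE)
    len <- sample_indel_length(cfg$indel_power_a, cfg$indel_max_len_bp,
                               n_events)
    ins_seq <- vapply(seq_len(n_events), function(i) {
      if (kind[i] == "insertion")
        paste(c("A", "C", "G", "T")[sample.int(4, len[i], replace = TRUE,
                                               prob = freqs)], collapse = "")
      else ""
    }, character(1))
    events <- data.frame(pos = pos, branch = branch, kind = kind, len = len,
                         ins_seq = ins_seq, stringsAsFactors = FALSE)
  }

  base_chr <- c("A", "C", "G", "T")
  ref_chars <- base_chr[ref]

  # deleted reference positions per chromosome (1-based): deletion anchored
  # at pos removes pos+1 .. pos+len
  del_mask <- function(which_chr) {
    m <- logical(L)
    if (!is.null(events)) {
      ev <- events[events$kind == "deletion" &
                     (events$branch == "hom" | events$branch == which_chr), ]
      for (i in seq_len(nrow(ev)))
        m[(ev$pos[i] + 1L):(ev$pos[i] + ev$len[i])] <- TRUE
    }
    m
  }
  del1 <- del_mask("chr1")
  del2 <- del_mask("chr2")

  # SNP truth: compare substituted chromosomes to the reference, excluding
  # positions deleted on the carrier chromosome
  d1 <- which(chr1 != ref & !del1)
  d2 <- which(chr2 != ref & !del2)
  both <- intersect(d1, d2)
  hom_pos <- both[chr1[both] == chr2[both]]
  het1 <- setdiff(d1, hom_pos)
  het2 <- setdiff(d2, hom_pos)
  truth_snp <- rbind(
    if (length(hom_pos)) data.frame(
      ref_pos = hom_pos - 1L, kind = "snp", ref_allele = ref_chars[hom_pos],
      alt_allele = base_chr[chr1[hom_pos]], genotype = "hom",
      on_chr1 = TRUE, on_chr2 = TRUE, stringsAsFactors = FALSE),
    if (length(het1)) data.frame(
      ref_pos = het1 - 1L, kind = "snp", ref_allele = ref_chars[het1],
      alt_allele = base_chr[chr1[het1]], genotype = "het",
      on_chr1 = TRUE, on_chr2 = FALSE, stringsAsFactors = FALSE),
    if (length(het2)) data.frame(
      ref_pos = het2 - 1L, kind = "snp", ref_allele = ref_chars[het2],
      alt_allele = base_chr[chr2[het2]], genotype = "het",
      on_chr1 = FALSE, on_chr2 = TRUE, stringsAsFactors = FALSE))

  truth_indel <- NULL
  if (!is.null(events) && nrow(events)) {
    ref_str_of <- function(a, b) paste(ref_chars[a:b], collapse = "")
    anchor <- events$pos # 1-based anchor base before the event
    ref_allele <- character(nrow(events))
    alt_allele <- character(nrow(events))
    for (i in seq_len(nrow(events))) {
      if (events$kind[i] == "deletion") {
        ref_allele[i] <- ref_str_of(anchor[i], anchor[i] + events$len[i])
        alt_allele[i] <- ref_chars[anchor[i]]
      } else {
        ref_allele[i] <- ref_chars[anchor[i]]
        alt_allele[i] <- paste0(ref_chars[anchor[i]], events$ins_seq[i])
      }
    }
    truth_indel <- data.frame(
      ref_pos = anchor - 1L, kind = events$kind, ref_allele = ref_allele,
      alt_allele = alt_allele,
      genotype = ifelse(events$branch == "hom", "hom", "het"),
      on_chr1 = events$branch %in% c("hom", "chr1"),
      on_chr2 = events$branch %in% c("hom", "chr2"), stringsAsFactors = FALSE)
  }
  truth <- rbind(truth_snp, truth_indel)
  if (is.null(truth)) {
    truth <- data.frame(ref_pos = integer(0), kind = character(0),
                        ref_allele = character(0), alt_allele = character(0),
                        genotype = character(0), on_chr1 = logical(0),
                        on_chr2 = logical(0), stringsAsFactors = FALSE)
  } else {
    truth <- truth[order(truth$ref_pos), , drop = FALSE]
    rownames(truth) <- NULL
  }

  build_chromosome <- function(sub_seq, which_chr) {
    if (is.null(events) || !nrow(events))
      return(paste(base_chr[sub_seq], collapse = ""))
    ev <- events[events$branch == "hom" | events$branch == which_chr, ,
                 drop = FALSE]
    if (!nrow(ev)) return(paste(base_chr[sub_seq], collapse = ""))
    ev <- ev[order(ev$pos), , drop = FALSE]
    pieces <- character(2L * nrow(ev) + 1L)
    prev <- 1L
    pi_ <- 1L
    for (i in seq_len(nrow(ev))) {
      a <- ev$pos[i] # keep 1..a, event after a
      pieces[pi_] <- paste(base_chr[sub_seq[prev:a]], collapse = "")
      pi_ <- pi_ + 1L
      if (ev$kind[i] == "insertion") {
        pieces[pi_] <- ev$ins_seq[i]
        prev <- a + 1L
      } else {
        pieces[pi_] <- ""
        prev <- a + ev$len[i] + 1L
      }
      pi_ <- pi_ + 1L
    }
    pieces[pi_] <- if (prev <= L) paste(base_chr[sub_seq[prev:L]], collapse = "") else ""
    paste(pieces, collapse = "")
  }

  pair <- list(reference = paste(ref_chars, collapse = ""),
               chromosome1 = build_chromosome(chr1, "chr1"),
               chromosome2 = build_chromosome(chr2, "chr2"),
               truth = truth, site_rates = site_rates, config = cfg)
  class(pair) <- "ref_sample_pair"
  pair
}

#' @export
print.ref_sample_pair <- function(x, ...) {
  cat("ref_sample_pair:", nchar(x$reference), "bp reference,",
      nrow(x$truth), "truth variants",
      sprintf("(%s divergence, GC %.0f%%)\n", x$config$divergence_level,
              100 * x$config$gc_content))
  invisible(x)
}

#' Reconstruct the sample chromosomes from the truth catalog
#'
#' Replays SNPs and indels recorded in `pair$truth` against the reference.
#' Used to verify that the truth catalog is complete: the result must equal
#' the simulated chromosomes exactly.
#'
#' @param pair A `ref_sample_pair`.
#' @return List with `chromosome1` and `chromosome2` strings.
#' @export
replay_truth <- function(pair) {
  ref <- strsplit(pair$reference, "", fixed = TRUE)[[1]]
  replay_one <- function(on_col) {
    tr <- pair$truth[pair$truth[[on_col]], , drop = FALSE]
    seq <- ref
    snps <- tr[tr$kind == "snp", , drop = FALSE]
    seq[snps$ref_pos + 1L] <- snps$alt_allele
    ind <- tr[tr$kind != "snp", , drop = FALSE]
    ind <- ind[order(ind$ref_pos, decreasing = TRUE), , drop = FALSE]
    out <- seq
    for (i in seq_len(nrow(ind))) {
      a <- ind$ref_pos[i] + 1L # 1-based anchor
      if (ind$kind[i] == "insertion") {
        ins <- substring(ind$alt_allele[i], 2L)
        out <- c(out[1:a], strsplit(ins, "", fixed = TRUE)[[1]],
                 out[(a + 1L):length(out)])
      } else {
        dl <- nchar(ind$ref_allele[i]) - 1L
        out <- out[-((a + 1L):(a + dl))]
      }
    }
    paste(out, collapse = "")
  }
  list(chromosome1 = replay_one("on_chr1"), chromosome2 = replay_one("on_chr2"))
}

#' Filter truth variants to the evaluation window
#'
#' Drops variants closer than `edge_margin` to either end of the reference,
#' mirroring the exclusion of reference flanks from variant accounting.
#'
#' @param truth Truth data.frame from [simulate_pair()].
#' @param ref_len Reference length in bp.
#' @param edge_margin Flank size in bp (default 500).
#' @return Filtered truth data.frame.
#' @export
truth_in_window <- function(truth, ref_len, edge_margin = 500L) {
  if (edge_margin < 0) stop("'edge_margin' must be >= 0")
  if (edge_margin >= ref_len / 2) stop("'edge_margin' must be < ref_len/2")
  pos1 <- truth$ref_pos + 1L
  truth[pos1 >= edge_margin & pos1 <= ref_len - edge_margin, , drop = FALSE]
}
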