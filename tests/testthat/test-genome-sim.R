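test_that("discrete gamma rates are quantile midpoints normalized to mean 1", {
  expect_equal(discrete_gamma_rates(1, 1), 1.0)
  r <- discrete_gamma_rates(1, 4)
  # independent oracle: gamma inverse CDF at probabilities (2i-1)/8
  q <- qgamma(c(0.125, 0.375, 0.625, 0.875), shape = 1, rate = 1)
  expect_equal(r, q / mean(q), tolerance = 1e-12)
  expect_equal(mean(r), 1)
  expect_true(all(diff(r) > 0))
  # rate-homogeneity limit
  expect_true(all(abs(discrete_gamma_rates(1e6, 4) - 1) < 1e-2))
  for (shape in c(0.2, 0.5, 2, 10)) {
    r <- discrete_gamma_rates(shape, 8)
    expect_equal(mean(r), 1)
    expect_true(all(diff(r) > 0))
  }
  expect_error(discrete_gamma_rates(0, 4), "positive")
  expect_error(discrete_gamma_rates(1, 0), "positive")
})

test_that("HKY transition matrix has the model's analytic properties", {
  pis <- list(rep(0.25, 4), c(0.325, 0.175, 0.175, 0.325),
              c(0.175, 0.325, 0.325, 0.175))
  for (pi in pis) {
    P0 <- hky_transition_matrix(2, pi, 0)
    expect_equal(unname(P0), diag(4), tolerance = 1e-12)
    for (t in c(0.01, 0.3, 2)) {
      P <- hky_transition_matrix(2, pi, t)
      expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
      # stationarity and detailed balance
      expect_equal(as.numeric(pi %*% P), pi, tolerance = 1e-10)
      expect_equal(pi * P, t(pi * P), tolerance = 1e-10)
    }
  }
  # transitions occur at twice the transversion probability as t -> 0
  P <- hky_transition_matrix(2, rep(0.25, 4), 1e-6)
  expect_equal(P["A", "G"] / P["A", "C"], 2, tolerance = 1e-3)
  # rate multiplies branch length
  expect_equal(hky_transition_matrix(2, rep(0.25, 4), 0.2, rate = 3),
               hky_transition_matrix(2, rep(0.25, 4), 0.6), tolerance = 1e-12)
  expect_error(hky_transition_matrix(2, rep(0.25, 4), -1), "non-negative")
})

test_that("indel lengths follow the truncated power law", {
  set.seed(5)
  expect_true(all(sample_indel_length(1.7, 1, 100) == 1))
  n <- 2e5
  x <- sample_indel_length(1.7, 5, n)
  k <- 1:5
  p <- k^(-1.7) / sum(k^(-1.7)) # oracle pmf; P(1) ~ 0.6166
  expect_equal(p[1], 0.6166, tolerance = 1e-4)
  obs <- tabulate(x, 5) / n
  expect_true(all(abs(obs - p) < 3 * sqrt(p * (1 - p) / n)))
  # degenerate exponent: uniform lengths
  x0 <- sample_indel_length(0, 5, n)
  expect_equal(mean(x0), 3, tolerance = 3 * sqrt(2 / n) * 2)
  expect_error(sample_indel_length(1.7, 0), "positive")
})

test_that("zero divergence gives identical chromosomes and empty truth", {
  pair <- flat_pair(20000L, seed = 2)
  expect_identical(pair$reference, pair$chromosome1)
  expect_identical(pair$reference, pair$chromosome2)
  expect_equal(nrow(pair$truth), 0)
})

test_that("simulated pairs replay, match GC and calibrated density", {
  for (case in list(list(div = "low", gc = 0.5, target = 2.6e-3),
                    list(div = "high", gc = 0.35, target = 2.9e-2))) {
    cfg <- calibrate_branch_scale(genome_sim_config(
      length_bp = 150000L, gc_content = case$gc,
      divergence_level = case$div, seed = 101))
    pair <- simulate_pair(cfg)
    # truth catalog replays byte-exactly
    rp <- replay_truth(pair)
    expect_identical(rp$chromosome1, pair$chromosome1)
    expect_identical(rp$chromosome2, pair$chromosome2)
    # reference base composition
    gc_obs <- mean(strsplit(pair$reference, "")[[1]] %in% c("G", "C"))
    expect_lt(abs(gc_obs - case$gc), 0.01)
    # realized variant-position density within 20% of the target level
    expect_lt(abs(variant_position_density(pair) / case$target - 1), 0.2)
    # no SNP ever lands on an invariant (rate-0) site
    snp_pos <- pair$truth$ref_pos[pair$truth$kind == "snp"] + 1L
    expect_true(all(pair$site_rates[snp_pos] > 0))
    # indel lengths within bounds
    ind <- pair$truth[pair$truth$kind != "snp", ]
    lens <- abs(nchar(ind$ref_allele) - nchar(ind$alt_allele))
    expect_true(all(lens >= 1 & lens <= cfg$indel_max_len_bp))
  }
})

test_that("hom:het event ratio matches the per-branch expectation", {
  cfg <- calibrate_branch_scale(genome_sim_config(
    length_bp = 200000L, gc_content = 0.5, divergence_level = "high",
    seed = 17))
  pair <- simulate_pair(cfg)
  snp <- pair$truth[pair$truth$kind == "snp", ]
  obs <- sum(snp$genotype == "hom") / sum(snp$genotype == "het")
  # independent oracle: hom = both chromosomes differ from the reference
  # with the same base; het = exactly one differs (or both, differently),
  # computed from the HKY transition matrices along the three branches
  x <- cfg$branch_scale
  freqs <- c(0.25, 0.25, 0.25, 0.25)
  rates <- discrete_gamma_rates(1, 4)
  p_hom <- 0
  p_het <- 0
  for (r in rates) {
    Pi <- hky_transition_matrix(2, freqs, 1.5 * x, r)
    Pt <- hky_transition_matrix(2, freqs, 0.5 * x, r)
    for (a in 1:4) {
      for (i in 1:4) {
        for (b1 in 1:4) {
          for (b2 in 1:4) {
            pr <- freqs[a] * Pi[a, i] * Pt[i, b1] * Pt[i, b2] / length(rates)
            if (b1 != a && b2 != a && b1 == b2) p_hom <- p_hom + pr
            else if (xor(b1 != a, b2 != a)) p_het <- p_het + pr
            else if (b1 != a && b2 != a) p_het <- p_het + 2 * pr
          }
        }
      }
    }
  }
  expect_lt(abs(obs / (p_hom / p_het) - 1), 0.1)
})

test_that("truth export respects the edge margin and genotype encoding", {
  cfg <- calibrate_branch_scale(genome_sim_config(
    length_bp = 60000L, gc_content = 0.5, divergence_level = "high",
    seed = 4))
  pair <- simulate_pair(cfg)
  tw <- truth_in_window(pair$truth, 60000L, 500L)
  expect_true(all(tw$ref_pos + 1L >= 500 & tw$ref_pos + 1L <= 59500))
  expect_equal(nrow(truth_in_window(pair$truth, 60000L, 0L)),
               nrow(pair$truth))
  expect_error(truth_in_window(pair$truth, 60000L, 40000L), "margin")
  f <- tempfile(fileext = ".vcf")
  export_truth(pair, edge_margin = 500L, file = f)
  back <- read_vcf(f)
  expect_equal(nrow(back), nrow(tw))
  expect_equal(back$ref_pos, tw$ref_pos)
  expect_equal(back$genotype, tw$genotype)
  expect_equal(back$alt_allele, tw$alt_allele)
  # a chr2-only het SNP is a single 0/1 record
  het2 <- tw[tw$kind == "snp" & !tw$on_chr1 & tw$on_chr2, ]
  if (nrow(het2) > 0)
    expect_true(all(back$genotype[match(het2$ref_pos, back$ref_pos)] == "het"))
  unlink(f)
})
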