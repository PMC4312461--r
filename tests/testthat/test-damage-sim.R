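test_that("eligible positions match the damage-model geometry", {
  expect_identical(eligible_positions(0.12, 0.75, 0.01), 9L)
  expect_identical(eligible_positions(0.4, 0.75, 0.01), 13L)
  expect_identical(eligible_positions(0.005, 0.75, 0.01), 0L)
  expect_identical(eligible_positions(0, 0.75, 0.01), 0L)
  expect_error(eligible_positions(0.4, 1, 0.01), "unbounded")
  expect_error(eligible_positions(0.4, 0.75, 0), "positive")
  # property: returned n satisfies p0*decay^(n-1) >= cutoff > p0*decay^n
  set.seed(3)
  for (i in 1:50) {
    p0 <- runif(1, 0.02, 0.9)
    decay <- runif(1, 0.3, 0.95)
    n <- eligible_positions(p0, decay, 0.01)
    expect_gte(p0 * decay^(n - 1), 0.01)
    expect_lt(p0 * decay^n, 0.01)
  }
})

test_that("fragment acceptance probabilities follow the weight tables", {
  none <- damage_config("none")
  expect_equal(accept_fragment_prob(c("A", "C", "G", NA),
                                    c("T", "G", "C", NA), none),
               rep(0.5, 4))
  low <- damage_config("low")
  # most favoured context attains base_accept exactly
  expect_equal(accept_fragment_prob("G", "C", low), 0.5)
  high <- damage_config("high")
  # least favoured context: 0.5 * (0.4/1.6)^2
  expect_equal(accept_fragment_prob("C", "G", high), 0.03125)
  # missing neighbour has weight 1
  expect_equal(accept_fragment_prob(NA, "C", high), 0.5 / 1.6)
  set.seed(4)
  acc <- accept_fragment(rep("G", 2e4), rep("C", 2e4), low)
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / 2e4))
})

test_that("misincorporation flips only terminal C->T and G->A", {
  set.seed(5)
  none <- damage_config("none")
  seqs <- vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE), collapse = ""),
    character(1))
  out0 <- apply_misincorporation(seqs, none)
  expect_identical(as.character(out0), seqs)

  high <- damage_config("high")
  out <- apply_misincorporation(seqs, high, keep_edits = TRUE)
  n5 <- eligible_positions(high$p0, high$decay, high$cutoff)
  for (i in seq_along(seqs)) {
    a <- strsplit(seqs[i], "")[[1]]
    b <- strsplit(out[i], "")[[1]]
    ch <- which(a != b)
    L <- length(a)
    for (p in ch) {
      from5 <- p - 1L
      from3 <- L - p
      expect_true((a[p] == "C" && b[p] == "T" && from5 < n5) ||
                    (a[p] == "G" && b[p] == "A" && from3 < n5))
    }
    expect_setequal(attr(out, "damage_edits")[[i]], ch)
  }
})

test_that("misincorporation rates realize p0 and the positional decay", {
  set.seed(6)
  n <- 1e5
  seqs <- rep(strrep("C", 20), n / 2)
  low <- damage_config("low")
  out <- apply_misincorporation(seqs, low, keep_edits = FALSE)
  led <- attr(out, "damage_ledger")
  r0 <- led$flip5[1] / led$opp5[1]
  r1 <- led$flip5[2] / led$opp5[2]
  expect_lt(abs(r0 - 0.12), 3 * sqrt(0.12 * 0.88 / led$opp5[1]))
  expect_lt(abs(r1 - 0.09), 3 * sqrt(0.09 * 0.91 / led$opp5[2]))
  expect_lt(abs(r1 / r0 - 0.75), 0.03)
  # high damage on reads starting CC...: offsets 0 and 1 at 0.4 and 0.3
  high <- damage_config("high")
  out2 <- apply_misincorporation(seqs, high, keep_edits = FALSE)
  led2 <- attr(out2, "damage_ledger")
  expect_lt(abs(led2$flip5[1] / led2$opp5[1] - 0.4),
            3 * sqrt(0.4 * 0.6 / led2$opp5[1]))
  expect_lt(abs(led2$flip5[2] / led2$opp5[2] - 0.3),
            3 * sqrt(0.3 * 0.7 / led2$opp5[2]))
  # no flips beyond the eligible window (opportunity but zero events)
  expect_true(all(led2$flip5[14:32] == 0))
})

test_that("subsampling reaches the target depth deterministically", {
  pair <- flat_pair(20000L, seed = 6)
  set.seed(13)
  pool <- simulate_read_pool(pair, trim_distribution(40),
                             damage_config("none"), target_bases = 3e6,
                             error_rate = 0)
  set.seed(99)
  sub <- subsample_to_depth(pool, 1, 20000L)
  expect_lt(abs(nrow(sub) - 20000 / 40), 20000 / 40 * 0.1)
  rd <- attr(sub, "realized_depth")
  expect_gte(rd, 1)
  expect_lt(rd - 1, max(pool$len) / 20000) # within one read of target
  set.seed(99)
  sub2 <- subsample_to_depth(pool, 1, 20000L)
  expect_identical(sub$seq, sub2$seq)
  expect_equal(nrow(subsample_to_depth(pool, 0, 20000L)), 0)
  expect_error(subsample_to_depth(pool, 1000, 20000L), "fewer bases")
})

test_that("damage in generated pools is strand-free on the read sequence", {
  pair <- flat_pair(20000L, seed = 7)
  set.seed(14)
  pool <- simulate_read_pool(pair, trim_distribution(40),
                             damage_config("high"), target_bases = 4e5,
                             error_rate = 0, keep_edits = TRUE)
  chr <- c(pair$chromosome1, pair$chromosome2)
  n5 <- eligible_positions(0.4, 0.75, 0.01)
  for (i in sample.int(nrow(pool), 300)) {
    orig <- substr(chr[pool$chrom[i]], pool$start[i] + 1L,
                   pool$start[i] + pool$len[i])
    if (pool$strand[i] == "-") orig <- revcomp_str(orig)
    a <- strsplit(orig, "")[[1]]
    b <- strsplit(pool$seq[i], "")[[1]]
    ch <- which(a != b)
    for (p in ch) {
      expect_true((a[p] == "C" && b[p] == "T" && p - 1L < n5) ||
                    (a[p] == "G" && b[p] == "A" && length(a) - p < n5))
    }
  }
})
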