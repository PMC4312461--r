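mk_var <- function(pos, kind = "snp", alt = "T", genotype = "het",
                   ref = "C") {
  data.frame(ref_pos = pos, kind = kind, ref_allele = ref, alt_allele = alt,
             genotype = genotype, stringsAsFactors = FALSE)
}

test_that("indel matching honours the +-3 bp window, one-to-one", {
  called <- mk_var(c(1002L), kind = "deletion")
  truth <- mk_var(c(1000L), kind = "deletion")
  m <- match_indels(called, truth, ref_len = NULL)
  expect_equal(m$n_matched, 1)
  m2 <- match_indels(mk_var(1004L, kind = "deletion"), truth, ref_len = NULL)
  expect_equal(m2$n_matched, 0)
  # two called flanking one truth: exactly one matches
  m3 <- match_indels(mk_var(c(998L, 1002L), kind = "insertion"), truth,
                     ref_len = NULL)
  expect_equal(m3$n_matched, 1)
})

test_that("greedy matcher attains the optimal assignment cardinality", {
  # adversarial case where nearest-first greedy fails: truth {0,4},
  # called {4,8}, window 4 -- optimum pairs (4,0) and (8,4)
  m <- match_indels(mk_var(c(4L, 8L), kind = "deletion"),
                    mk_var(c(0L, 4L), kind = "deletion"),
                    window = 4L, ref_len = NULL)
  expect_equal(m$n_matched, 2)
  set.seed(41)
  for (i in 1:2000) {
    nc <- sample(0:6, 1)
    nt <- sample(0:6, 1)
    called <- sort(sample(0:30, nc))
    truth <- sort(sample(0:30, nt))
    w <- sample(1:4, 1)
    got <- match_positions(called, truth, w)$n_matched
    expect_identical(got, optimal_match_count(called, truth, w))
  }
})

test_that("SNP matching is exact on position and allele, allele-aware", {
  truth <- mk_var(5000L, alt = "T", genotype = "het")
  ok <- match_snps(mk_var(5000L, alt = "T"), truth)
  expect_equal(ok$correct_alleles, 1)
  bad <- match_snps(mk_var(5000L, alt = "G"), truth)
  expect_equal(bad$correct_alleles, 0)
  expect_equal(bad$called_alleles, 1)
  expect_equal(bad$truth_alleles, 1)
  # truth het called hom: one correct allele plus one spurious call
  hom <- match_snps(mk_var(5000L, alt = "T", genotype = "hom"), truth)
  expect_equal(hom$correct_alleles, 1)
  expect_equal(hom$called_alleles, 2)
  # truth hom called het: half the truth alleles recovered
  th <- match_snps(mk_var(5000L, alt = "T", genotype = "het"),
                   mk_var(5000L, alt = "T", genotype = "hom"))
  expect_equal(th$correct_alleles, 1)
  expect_equal(th$truth_alleles, 2)
})

test_that("SNPs within 5 bp of an indel are excluded from both sets", {
  truth <- mk_var(c(5000L, 5100L), alt = "T")
  called <- mk_var(c(5000L, 5100L), alt = "T")
  m <- match_snps(called, truth, indel_pos = 5004L)
  expect_equal(nrow(m$called), 1)
  expect_equal(nrow(m$truth), 1)
  expect_equal(m$called$ref_pos, 5100L)
  # exactly 6 bp away survives (("> 5 bp distant"))
  m2 <- match_snps(called, truth, indel_pos = 5006L)
  expect_equal(nrow(m2$called), 2)
})

test_that("pool summary arithmetic matches hand-computed values", {
  # 10 SNP calls, 9 correct
  truth <- mk_var(seq(1000L, 1900L, by = 100L), alt = "T")
  called <- truth
  called$alt_allele[10] <- "G"
  ev <- evaluate_pool(called, truth, ref_len = 100000L, edge_margin = 0L)
  expect_equal(ev$snp_accuracy, 90)
  expect_equal(ev$snp_completeness, 90)
  # hom:het ratio of ratios: truth 100 hom + 50 het, correct 40 hom + 10 het
  truth2 <- mk_var(seq(10000L, by = 50L, length.out = 150), alt = "T",
                   genotype = rep(c("hom", "het"), c(100, 50)))
  called2 <- truth2[c(1:40, 101:110), ]
  ev2 <- evaluate_pool(called2, truth2, ref_len = 100000L, edge_margin = 0L)
  expect_equal(ev2$snp_homhet_rr, (40 / 10) / (100 / 50))
  # perfect calling: completeness 100, ratio of ratios 1
  ev3 <- evaluate_pool(truth2, truth2, ref_len = 100000L, edge_margin = 0L)
  expect_equal(ev3$snp_completeness, 100)
  expect_equal(ev3$snp_accuracy, 100)
  expect_equal(ev3$snp_homhet_rr, 1)
  # zero calls: accuracy is NA, not 0
  ev4 <- evaluate_pool(truth2[0, ], truth2, ref_len = 100000L,
                       edge_margin = 0L)
  expect_true(is.na(ev4$snp_accuracy))
  expect_equal(ev4$snp_completeness, 0)
})

test_that("evaluation is invariant under coordinate translation", {
  set.seed(42)
  truth <- rbind(mk_var(sort(sample(2000:9000, 40)), alt = "T"),
                 mk_var(sort(sample(12000:19000, 10)), kind = "deletion"))
  called <- truth[sample.int(nrow(truth), 35), ]
  called$ref_pos <- called$ref_pos + sample(c(0L, 1L, -1L), 35, TRUE) *
    (called$kind != "snp")
  ev1 <- evaluate_pool(called, truth, ref_len = 50000L, edge_margin = 0L)
  sh <- function(df) { df$ref_pos <- df$ref_pos + 777L; df }
  ev2 <- evaluate_pool(sh(called), sh(truth), ref_len = 50000L,
                       edge_margin = 0L)
  expect_equal(ev1, ev2)
})

test_that("metrics are bounded on random fuzzed inputs", {
  set.seed(43)
  for (i in 1:50) {
    truth <- mk_var(sort(sample(1000:5000, sample(1:30, 1))),
                    alt = sample(c("A", "G", "T"), 1),
                    genotype = sample(c("hom", "het"), 1))
    called <- mk_var(sort(sample(1000:5000, sample(1:30, 1))),
                     alt = sample(c("A", "G", "T"), 1),
                     genotype = sample(c("hom", "het"), 1))
    ev <- evaluate_pool(called, truth, ref_len = 10000L, edge_margin = 0L)
    if (!is.na(ev$snp_accuracy)) {
      expect_gte(ev$snp_accuracy, 0)
      expect_lte(ev$snp_accuracy, 100)
    }
    expect_gte(ev$snp_completeness, 0)
    expect_lte(ev$snp_completeness, 100)
  }
})

test_that("mapping statistics report rate, length and 5' uniqueness", {
  m <- data.frame(mapped = c(TRUE, TRUE, TRUE, FALSE),
                  pos = c(100L, 100L, 300L, NA),
                  strand = c("+", "+", "-", NA),
                  cigar = c("40M", "40M", "40M", NA),
                  ref_span = c(40L, 40L, 40L, NA),
                  len = c(40L, 40L, 40L, 35L))
  st <- mapping_stats(m)
  expect_equal(st$pct_reads_mapped, 75)
  expect_equal(st$mean_mapped_read_len, 40)
  # two reads share the 5' start at 100(+); the minus read is unique
  expect_equal(st$pct_unique_5prime_starts, 100 / 3)
})
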