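test_that("k-mer index stores and retrieves exact positions", {
  idx <- build_index("ACGTACGT", k = 4L)
  expect_equal(index_lookup(idx, "ACGT"), c(0L, 4L))
  expect_equal(index_lookup(idx, "CGTA"), 1L)
  expect_equal(length(index_lookup(idx, "TTTT")), 0)
  expect_error(build_index("ACGTACGT", k = 3L), "k must be")
  ref <- random_ref(2000, seed = 21)
  idx2 <- build_index(ref, k = 13L)
  for (p in sample.int(2000 - 13, 50)) {
    kmer <- substr(ref, p, p + 12L)
    expect_true((p - 1L) %in% index_lookup(idx2, kmer))
  }
})

test_that("unique reads map at their origin; repeats and junk do not map", {
  ref <- random_ref(5000, seed = 22)
  read <- substr(ref, 1001, 1040)
  m <- map_reads(build_index(ref), read)
  expect_true(m$mapped)
  expect_equal(m$pos, 1000L)
  expect_equal(m$cigar, "40M")
  expect_equal(m$nm, 0L)
  # reverse-complemented read maps to the same locus on the minus strand
  m2 <- map_reads(build_index(ref), revcomp_str(read))
  expect_true(m2$mapped)
  expect_equal(m2$pos, 1000L)
  expect_equal(m2$strand, "-")
  # exact duplication: unique-best policy leaves the read unmapped
  dup <- paste0(ref, substr(ref, 1001, 1100), random_ref(500, seed = 23))
  m3 <- map_reads(build_index(dup), read)
  expect_false(m3$mapped)
  # unrelated sequence does not map
  m4 <- map_reads(build_index(ref), random_ref(40, seed = 24))
  expect_false(m4$mapped)
})

test_that("edit-distance cap admits terminal damage within threshold", {
  ref <- random_ref(5000, seed = 25)
  start <- 2001
  read <- substr(ref, start, start + 39)
  # plant 3 C->T flips near the 5' end (cap = ceiling(0.06*40) = 3)
  b <- strsplit(read, "")[[1]]
  cpos <- which(b == "C")[1:3]
  expect_false(anyNA(cpos))
  b[cpos] <- "T"
  m <- map_reads(build_index(ref), paste(b, collapse = ""))
  expect_true(m$mapped)
  expect_equal(m$pos, start - 1L)
  expect_equal(m$nm, 3L)
  # a fourth edit pushes past the cap
  apos <- which(b == "A")[1]
  b[apos] <- "G"
  m2 <- map_reads(build_index(ref), paste(b, collapse = ""))
  expect_false(m2$mapped)
})

test_that("indels within the band are aligned and left-normalized", {
  set.seed(26)
  ref <- random_ref(4000, seed = 26)
  # construct a read with an internal 2 bp deletion
  read <- paste0(substr(ref, 501, 520), substr(ref, 523, 542))
  m <- map_reads(build_index(ref), read)
  expect_true(m$mapped)
  expect_equal(m$nm, 2L)
  expect_match(m$cigar, "2D")
  # deletion in a homopolymer is reported at its leftmost placement
  ref2 <- paste0(random_ref(300, seed = 27), "TACCCCCGT",
                 random_ref(300, seed = 28))
  # the C5 run sits at 1-based ref positions 303..307; drop one C
  read2 <- paste0(substr(ref2, 284, 305), substr(ref2, 307, 325))
  m2 <- map_reads(build_index(ref2, k = 13), read2)
  expect_true(m2$mapped)
  expect_equal(m2$nm, 1L)
  expect_equal(m2$pos, 283L)
  # leftmost placement: 19 matches (284..302), deletion of the first C
  expect_equal(m2$cigar, "19M1D22M")
})

test_that("mapper agrees with the exhaustive-alignment oracle", {
  cfg <- calibrate_branch_scale(genome_sim_config(
    length_bp = 5000L, gc_content = 0.5, divergence_level = "high",
    seed = 29))
  pair <- simulate_pair(cfg)
  set.seed(30)
  pool <- simulate_read_pool(pair, trim_distribution(50),
                             damage_config("low"), target_bases = 9e4)
  m <- map_reads(build_index(pair), pool)
  o <- exhaustive_map(pair$reference, pool$seq)
  agree <- (m$mapped == o$mapped) &
    (!m$mapped | abs(m$pos - o$pos) <= 6)
  expect_gte(mean(agree), 0.999)
})

test_that("mapping rate is non-increasing along an edit-count ladder", {
  ref <- random_ref(60000, seed = 34)
  idx <- build_index(ref)
  set.seed(35)
  starts <- sample.int(60000 - 60, 400)
  rate <- vapply(0:5, function(ne) {
    reads <- vapply(starts, function(s) {
      b <- strsplit(substr(ref, s, s + 59), "")[[1]]
      if (ne > 0) {
        pos <- sample.int(60, ne)
        b[pos] <- vapply(b[pos], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
      }
      paste(b, collapse = "")
    }, character(1))
    mean(map_reads(idx, reads)$mapped)
  }, numeric(1))
  expect_true(all(diff(rate) <= 0))
  expect_equal(rate[1], 1) # error-free unique reads all map
  # 5 substitutions exceed ceiling(0.06 * 60) = 4; the rare survivors are
  # reads whose substitutions admit a cheaper gapped re-alignment
  expect_lt(rate[6], 0.05)
})

test_that("pileup genotyping matches a binomial-likelihood oracle", {
  ref <- random_ref(300, seed = 31)
  rb <- substr(ref, 151, 151)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  mk_read <- function(base) {
    s <- substr(ref, 131, 170)
    substr(s, 21, 21) <- base
    s
  }
  mk_mapped <- function(bases) {
    data.frame(mapped = TRUE, pos = 130L, strand = "+", cigar = "40M",
               seq = vapply(bases, mk_read, character(1)), len = 40L,
               stringsAsFactors = FALSE)
  }
  # 10 alt reads: hom-alt call with quality matching the posterior oracle
  calls <- pileup_and_call(mk_mapped(rep(alt, 10)), ref)
  hit <- calls[calls$ref_pos == 150, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$genotype, "hom")
  expect_equal(hit$alt_allele, alt)
  eps <- 10^-3.5
  theta <- 1e-3
  lik <- c(RR = eps / 3, RA = 0.5 * (1 - eps) + 0.5 * eps / 3, AA = 1 - eps)
  post <- c(lik["RR"]^10 * (1 - 1.5 * theta), lik["RA"]^10 * theta,
            lik["AA"]^10 * theta / 2)
  # call quality is Phred of the hom-ref posterior, capped at 300
  expect_equal(hit$qual, min(300, -10 * log10(unname(post[1]) / sum(post))),
               tolerance = 1e-6)
  expect_gt(hit$qual, 20)
  # balanced 5/5 column: het is the ML genotype
  calls2 <- pileup_and_call(mk_mapped(rep(c(rb, alt), 5)), ref)
  hit2 <- calls2[calls2$ref_pos == 150, ]
  expect_equal(hit2$genotype, "het")
  # all-reference pileup yields no record at the site
  calls3 <- pileup_and_call(mk_mapped(rep(rb, 8)), ref)
  expect_false(150 %in% calls3$ref_pos)
  # a single alt read is called but falls below the QUAL >= 20 filter
  calls4 <- pileup_and_call(mk_mapped(alt), ref)
  hit4 <- calls4[calls4$ref_pos == 150, ]
  if (nrow(hit4)) expect_lt(hit4$qual, 20)
})

test_that("depth and quality filters apply the published cutoffs", {
  calls <- empty <- pileup_and_call(
    data.frame(mapped = logical(0), pos = integer(0), strand = character(0),
               cigar = character(0), seq = character(0)), "ACGT")
  expect_equal(nrow(filter_calls(calls)), 0)
  df <- data.frame(ref_pos = 1:4, kind = "snp", qual = c(25, 19.9, 50, 21),
                   depth = c(10, 10, 31, 1))
  kept <- filter_calls(df)
  expect_equal(kept$ref_pos, c(1L, 4L))
  expect_error(filter_calls(df, min_depth = 5, max_depth = 2), "min_depth")
})

test_that("indel calls recover planted events through the full pipeline", {
  # plant a homozygous 3 bp deletion and a het 2 bp insertion via truth-style
  # chromosomes built by hand
  ref <- random_ref(6000, seed = 32)
  chr_del <- paste0(substr(ref, 1, 3000), substr(ref, 3004, 6000))
  pair <- structure(list(reference = ref, chromosome1 = chr_del,
                         chromosome2 = chr_del), class = "ref_sample_pair")
  set.seed(33)
  pool <- simulate_read_pool(pair, trim_distribution(60),
                             damage_config("none"), target_bases = 20 * 6000,
                             error_rate = 0)
  m <- map_reads(build_index(ref), pool)
  calls <- filter_calls(pileup_and_call(m, ref))
  del <- calls[calls$kind == "deletion", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$genotype, "hom")
  # left-aligned anchor within 3 bp of the planted position
  expect_lte(abs(del$ref_pos - 2999L), 3)
  expect_equal(nchar(del$ref_allele) - nchar(del$alt_allele), 3)
})
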