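# Shared fixtures: all built in code at test time.

# A zero-divergence "pair": both chromosomes identical to the reference.
# Useful for read-level tests where the template must be known exactly.
flat_pair <- function(len = 50000L, gc = 0.5, seed = 1L) {
  cfg <- genome_sim_config(length_bp = len, gc_content = gc,
                           divergence_level = "low", branch_scale = 0,
                           seed = seed)
  simulate_pair(cfg)
}

# Random reference string.
random_ref <- function(len, gc = 0.5, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# Brute-force maximum one-to-one matching size between called and truth
# positions within a window, by exhaustive recursion (small inputs only).
# Independent oracle for the convex greedy matcher.
optimal_match_count <- function(called, truth, window) {
  best <- 0L
  n <- length(called)
  recurse <- function(i, used, count) {
    if (count + (n - i + 1L) <= best) return()
    if (i > n) {
      best <<- max(best, count)
      return()
    }
    # skip called i
    recurse(i + 1L, used, count)
    for (j in seq_along(truth)) {
      if (!used[j] && abs(called[i] - truth[j]) <= window) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(truth)), 0L)
  best
}

# Realized variant-position density per bp of a simulated pair (SNP
# positions plus indel-affected positions, insertions counted by inserted
# length, deletions by deleted length).
variant_position_density <- function(pair) {
  tr <- pair$truth
  n_pos <- length(unique(tr$ref_pos[tr$kind == "snp"])) +
    sum(nchar(tr$ref_allele[tr$kind == "deletion"]) - 1L) +
    sum(nchar(tr$alt_allele[tr$kind == "insertion"]) - 1L)
  n_pos / nchar(pair$reference)
}
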