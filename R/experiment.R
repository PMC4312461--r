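#' Factorial grid configuration
#'
#' The full study grid crosses 3 GC contents x 2 divergence levels x 3
#' replicate genome pairs x 3 read-length distributions x 3 damage levels x
#' 7 coverage depths = 378 triplicate-averaged cells (1134 read pools). Any
#' subset of levels can be requested, and the genome length can be reduced
#' for desk-scale runs.
#'
#' @param gc_levels GC fractions.
#' @param divergences Divergence levels.
#' @param read_len_means Mean trimmed read lengths (bp).
#' @param damage_levels Damage level names.
#' @param depths Coverage depths (x).
#' @param replicates Replicate genome pairs per GC x divergence.
#' @param length_bp Genome length (the published study used 10,001,000 bp;
#'   1 Mbp is the reduced-scale default).
#' @param edge_margin Reference flank excluded from variant accounting.
#' @param raw_read_len Raw read length before trimming.
#' @param base_qual Constant Phred base quality of simulated reads.
#' @param error_floor Phred cap on per-base confidence in calling.
#' @param max_mismatch_frac,band,k,seed_step Mapper parameters.
#' @param min_qual,min_depth,max_depth Call filters.
#' @param bias_filter Apply [filter_pileup_bias()] to SNP calls.
#' @param pool_headroom Accepted-pool size as a multiple of
#'   `max(depths) * length_bp` bases.
#' @param master_seed Master seed; all stage seeds derive from it.
#' @return A `grid_config` list.
#' @export
grid_config <- function(gc_levels = c(0.35, 0.5, 0.65),
                        divergences = c("low", "high"),
                        read_len_means = c(40L, 60L, 80L),
                        damage_levels = c("none", "low", "high"),
                        depths = c(0.1, 0.5, 1, 2, 4, 8, 16),
                        replicates = 3L, length_bp = 1000000L,
                        edge_margin = 500L, raw_read_len = 100L,
                        base_qual = 35, error_floor = 40,
                        max_mismatch_frac = 0.06, band = 6L, k = 13L,
                        seed_step = 2L, min_qual = 20, min_depth = 1,
                        max_depth = 30, bias_filter = TRUE,
                        pool_headroom = 1.1, master_seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "grid_config"
  cfg
}

#' Run the factorial damage/coverage experiment
#'
#' For each divergence x GC x replicate, simulates a reference/diploid pair
#' (branch scale calibrated per GC x divergence); for each read length x
#' damage level, generates one accepted read pool sized for the deepest
#' coverage and maps it once; each coverage depth then subsamples the pool,
#' calls variants on the subsample, applies the filters, and scores calls
#' against the truth. Subsampling before or after mapping is equivalent
#' because mapping is per-read and deterministic. All stages draw their
#' seeds deterministically from `master_seed`, so the full table is
#' reproducible.
#'
#' @param cfg A [grid_config()].
#' @param verbose Print per-pair progress.
#' @return List of class `pv_grid`: `pools` (one row per read pool),
#'   `cells` (replicate-averaged rows, one per grid cell, with `_sd`
#'   columns), and `config`.
#' @export
run_grid <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "grid_config"))
  rows <- list()
  damage_code <- c(none = 1L, low = 2L, high = 3L)
  for (div in cfg$divergences) {
    for (gc in cfg$gc_levels) {
      gcfg0 <- calibrate_branch_scale(genome_sim_config(
        length_bp = cfg$length_bp, gc_content = gc, divergence_level = div))
      for (rep_i in seq_len(cfg$replicates)) {
        gcfg <- gcfg0
        gcfg$seed <- derive_seed(cfg$master_seed, "pair", div, gc * 100, rep_i)
        pair <- simulate_pair(gcfg)
        if (verbose)
          message(sprintf("pair %s gc=%.2f rep=%d: %d truth variants", div,
                          gc, rep_i, nrow(pair$truth)))
        idx <- build_index(pair$reference, k = cfg$k)
        L <- nchar(pair$reference)
        for (len_mean in cfg$read_len_means) {
          for (dmg in cfg$damage_levels) {
            set.seed(derive_seed(cfg$master_seed, "pool", div, gc * 100,
                                 rep_i, len_mean, dmg))
            pool <- simulate_read_pool(
              pair, trim_distribution(len_mean), damage_config(dmg),
              target_bases = max(cfg$depths) * L * cfg$pool_headroom,
              raw_read_len = cfg$raw_read_len,
              error_rate = phred_to_error(cfg$base_qual))
            mapped <- map_reads(idx, pool,
                                max_mismatch_frac = cfg$max_mismatch_frac,
                                band = cfg$band, seed_step = cfg$seed_step)
            lens <- as.numeric(pool$len)
            for (depth in cfg$depths) {
              set.seed(derive_seed(cfg$master_seed, "depth", div, gc * 100,
                                   rep_i, len_mean, dmg, depth * 10))
              row <- tryCatch({
                ord <- sample.int(nrow(pool))
                cum <- cumsum(lens[ord])
                kk <- which(cum >= depth * L)[1]
                if (is.na(kk)) stop("pool too small for requested depth")
                sel <- ord[seq_len(kk)]
                msub <- mapped[sel, , drop = FALSE]
                stats <- mapping_stats(msub)
                calls <- pileup_and_call(msub, pair$reference,
                                         base_qual = cfg$base_qual,
                                         error_floor = cfg$error_floor)
                calls <- filter_calls(calls, min_depth = cfg$min_depth,
                                      max_depth = cfg$max_depth,
                                      min_qual = cfg$min_qual)
                if (cfg$bias_filter) calls <- filter_pileup_bias(calls)
                ev <- evaluate_pool(calls, pair$truth, L,
                                    edge_margin = cfg$edge_margin)
                cbind(data.frame(divergence = div, gc = gc,
                                 replicate = rep_i, read_len = len_mean,
                                 damage = dmg,
                                 damage_code = damage_code[[dmg]],
                                 depth = depth,
                                 realized_depth = cum[kk] / L,
                                 failed = FALSE),
                      stats, ev)
              }, error = function(e) {
                warning(sprintf("cell %s/%.2f/%d/%d/%s/%g failed: %s", div,
                                gc, rep_i, len_mean, dmg, depth,
                                conditionMessage(e)))
                data.frame(divergence = div, gc = gc, replicate = rep_i,
                           read_len = len_mean, damage = dmg,
                           damage_code = damage_code[[dmg]], depth = depth,
                           realized_depth = NA_real_, failed = TRUE)
              })
              rows[[length(rows) + 1L]] <- row
            }
          }
        }
      }
    }
  }
  pools <- rbind_fill(rows)
  cells <- average_replicates(pools)
  out <- list(pools = pools, cells = cells, config = cfg)
  class(out) <- "pv_grid"
  out
}

# rbind data.frames with possibly missing columns (failed cells)
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  }))
}

# Average metric columns over replicates within each grid cell, retaining
# standard deviations.
average_replicates <- function(pools) {
  keys <- c("divergence", "gc", "read_len", "damage", "damage_code", "depth")
  metrics <- setdiff(names(pools), c(keys, "replicate", "failed"))
  metrics <- metrics[vapply(pools[metrics], is.numeric, logical(1))]
  grp <- interaction(pools[keys], drop = TRUE)
  agg <- function(f) {
    res <- lapply(pools[metrics], function(v)
      tapply(v, grp, function(x) f(x[is.finite(x)])))
    as.data.frame(res)
  }
  mean_df <- agg(function(x) if (length(x)) mean(x) else NA_real_)
  sd_df <- agg(function(x) if (length(x) > 1) stats::sd(x) else NA_real_)
  names(sd_df) <- paste0(names(sd_df), "_sd")
  key_df <- unique(pools[keys])
  key_df <- key_df[match(levels(grp),
                         as.character(interaction(key_df[keys], drop = TRUE))), ]
  n_rep <- as.integer(tapply(!pools$failed, grp, sum))
  out <- cbind(key_df, n_replicates = n_rep, mean_df, sd_df)
  rownames(out) <- NULL
  out[order(out$divergence, out$gc, out$read_len, out$damage_code,
            out$depth), , drop = FALSE]
}

#' @export
print.pv_grid <- function(x, ...) {
  cat("pv_grid:", nrow(x$pools), "read pools,", nrow(x$cells),
      "replicate-averaged cells\n")
  invisible(x)
}

#' Multiple regression of a pipeline metric on the design factors
#'
#' Ordinary least squares of a dependent metric on GC content (%), read
#' length (bp), damage level (coded 1/2/3 for none/low/high) and coverage
#' depth (x), with an intercept; `form = "log_depth"` replaces depth with
#' log(depth). Run separately per divergence level (filter the table
#' first), as divergence is not treated as an independent variable.
#'
#' @param table Cell or pool table from [run_grid()].
#' @param dependent Name of the metric column.
#' @param independents Design columns to include.
#' @param form `"linear"` or `"log_depth"`.
#' @return A `pv_regression` list: `coefficients` data.frame (term,
#'   estimate, std_error, p_value), `r_squared`, `n`, `form`, and the
#'   underlying `lm` fit.
#' @export
regress_metrics <- function(table, dependent,
                            independents = c("gc", "read_len",
                                             "damage_code", "depth"),
                            form = c("linear", "log_depth")) {
  form <- match.arg(form)
  df <- data.frame(y = table[[dependent]])
  for (v in independents) {
    x <- table[[v]]
    if (v == "gc") x <- x * 100 # percent, as the slopes are reported per %GC
    if (v == "depth" && form == "log_depth") x <- log(x)
    df[[v]] <- x
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(independents) + 2)
    stop("too few complete rows for regression")
  fit <- lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  out <- list(coefficients = data.frame(term = rownames(cf),
                                        estimate = cf[, 1],
                                        std_error = cf[, 2],
                                        p_value = cf[, 4],
                                        row.names = NULL),
              r_squared = summary(fit)$r.squared, n = nrow(df), form = form,
              fit = fit, dependent = dependent)
  class(out) <- "pv_regression"
  out
}

#' @export
print.pv_regression <- function(x, ...) {
  cat(sprintf("OLS of %s (form %s, n = %d, R^2 = %.3f)\n", x$dependent,
              x$form, x$n, x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Compare metric-vs-depth slopes between divergence groups
#'
#' ANCOVA-style interaction test: fits `y ~ x * group` and reports the
#' slope difference (group 2 minus group 1) with its p-value.
#'
#' @param table Cell or pool table containing both groups.
#' @param dependent Metric column name.
#' @param x Covariate column (default `"depth"`).
#' @param group Grouping column (default `"divergence"`).
#' @return List: `slope_difference`, `std_error`, `p_value`, `groups`, and
#'   the `lm` fit.
#' @export
compare_slopes <- function(table, dependent, x = "depth",
                           group = "divergence") {
  g <- factor(table[[group]])
  if (nlevels(droplevels(g[!is.na(table[[dependent]])])) < 2)
    stop("both groups must be present with data")
  df <- data.frame(y = table[[dependent]], x = table[[x]], g = g)
  df <- df[complete.cases(df), , drop = FALSE]
  fit <- lm(y ~ x * g, data = df)
  cf <- summary(fit)$coefficients
  it <- grep("^x:g", rownames(cf))
  list(slope_difference = unname(cf[it, 1]),
       std_error = unname(cf[it, 2]), p_value = unname(cf[it, 4]),
       groups = levels(droplevels(df$g)), fit = fit)
}

#' Write / read a grid configuration as YAML
#'
#' @param cfg A [grid_config()].
#' @param file Path.
#' @return `write_grid_config` returns the path invisibly;
#'   `read_grid_config` returns a `grid_config`.
#' @export
write_grid_config <- function(cfg, file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required")
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname write_grid_config
#' @export
read_grid_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required")
  vals <- yaml::yaml.load_file(file)
  do.call(grid_config, vals)
}
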