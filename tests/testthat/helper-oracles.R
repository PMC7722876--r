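## Independent oracles used across the suite. These deliberately avoid the
## code paths they check.

## Binomial lower-percentile threshold by explicit pmf summation.
oracle_min_alt_depth <- function(depth, ploidy, percentile) {
  p <- 1 / ploidy
  cdf <- 0
  for (k in 0:depth) {
    cdf <- cdf + choose(depth, k) * p^k * (1 - p)^(depth - k)
    if (cdf >= percentile) return(k)
  }
  depth
}

## Clopper-Pearson bounds by direct search over binomial tail probabilities.
oracle_clopper_pearson <- function(x, n, level = 0.95, grid = 1e-5) {
  a <- 1 - level
  ps <- seq(grid, 1 - grid, by = grid)
  lower <- if (x == 0) 0 else {
    ## largest p with P(X >= x | p) <= a/2
    tail_ge <- 1 - pbinom(x - 1, n, ps)
    max(ps[tail_ge <= a / 2])
  }
  upper <- if (x == n) 1 else {
    tail_le <- pbinom(x, n, ps)
    min(ps[tail_le <= a / 2])
  }
  c(lower = lower, upper = upper)
}

## Exact two-sided permutation p-value for the rank-sum statistic.
oracle_wilcox_perm_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

## Rank-sum W by brute force over all cross pairs (ties as halves).
oracle_rank_sum_W <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

## Per-base bitmap interval algebra on small coordinates.
bitmap_from_frame <- function(df, len = 200) {
  bits <- rep(FALSE, len)
  for (i in seq_len(nrow(df))) {
    if (df$start[i] < df$end[i])
      bits[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  bits
}

random_interval_frame <- function(n, len = 200) {
  s <- sample(0:(len - 2), n, replace = TRUE)
  e <- pmin(len, s + sample(1:30, n, replace = TRUE))
  data.frame(chrom = "chr1", start = s, end = e)
}

## Tiny toy joint call set built directly (3 leaves).
toy_joint <- function() {
  samples <- c("A", "B", "C")
  sites <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = c("A", "G", "T"), alt = c("T", "C", "G"),
    pass = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  gt <- rbind(c("HET", "HET", "HOM_REF"),
              c("HOM_VAR", "HOM_REF", "HOM_REF"),
              c("HET", "HET", "HET"))
  gq <- matrix(99L, 3, 3)
  ad_alt <- rbind(c(17L, 18L, 0L), c(35L, 0L, 0L), c(17L, 17L, 18L))
  ad_ref <- 35L - ad_alt
  dp <- matrix(35L, 3, 3)
  joint_calls(samples, sites, gt, gq, ad_ref, ad_alt, dp)
}

## Small zero-noise experiment reused by several files.
small_experiment <- function(seed = 42) {
  simulate_experiment(sim_config(
    n_leaves = 5, seed = seed, n_germline = 20, branch_rate = 8,
    n_private = 4, contig_lengths = c(chr1 = 100000L, chr2 = 50000L)))
}

consolidate_all <- function(experiment) {
  leaves <- experiment$joint$samples
  out <- lapply(leaves, function(s)
    consolidate_sample_calls(
      s, experiment$pairs[startsWith(names(experiment$pairs),
                                     paste0(s, "|"))],
      length(leaves)))
  names(out) <- leaves
  out
}
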