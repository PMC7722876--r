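#' Filter configuration
#'
#' Tunable parameters of the site filters and region rules. True variants
#' passed through a single-cell bottleneck, so heterozygous carriers are
#' expected to show an alt-allele depth consistent with drawing reads from
#' one of `ploidy` local copies; carriers in the extreme lower tail of
#' `Binomial(depth, 1/ploidy)` are suspect.
#'
#' @param min_gq minimum genotype quality; any sample strictly below fails
#'   the site (default 25).
#' @param ad_percentile lower-tail binomial percentile for the allele-depth
#'   test (default 0.01, i.e. "below the 1\% percentile").
#' @param ab_denominator denominator of the "more than half of the samples"
#'   majority in the allele-balance filter: `"het_carriers"` (default; the
#'   test is undefined for non-carriers and exempt for hom-var) or
#'   `"all_samples"`.
#' @param copy_neutral_tol a sample is copy neutral over an interval when
#'   |copy ratio - 1| <= this tolerance (default 0.1).
#' @param leaf_pad bases of padding added around each leaf-variant reference
#'   span when excluding it from the high-confidence region (default 0).
#' @param reciprocal_overlap minimum reciprocal overlap for grouping CNV
#'   segments across samples into one event (default 0.5).
#' @param leaf_majority_denominator denominator for the pairwise-call
#'   consolidation majority: `"called"` (default; runs in which the site was
#'   called at all) or `"total"` (all n-1 runs).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_gq = 25L,
                          ad_percentile = 0.01,
                          ab_denominator = c("het_carriers", "all_samples"),
                          copy_neutral_tol = 0.1,
                          leaf_pad = 0L,
                          reciprocal_overlap = 0.5,
                          leaf_majority_denominator = c("called", "total")) {
  stopifnot(min_gq >= 0, ad_percentile > 0, ad_percentile < 1,
            copy_neutral_tol >= 0, leaf_pad >= 0,
            reciprocal_overlap > 0, reciprocal_overlap <= 1)
  structure(list(min_gq = as.integer(min_gq),
                 ad_percentile = ad_percentile,
                 ab_denominator = match.arg(ab_denominator),
                 copy_neutral_tol = copy_neutral_tol,
                 leaf_pad = as.integer(leaf_pad),
                 reciprocal_overlap = reciprocal_overlap,
                 leaf_majority_denominator = match.arg(leaf_majority_denominator)),
            class = "filter_config")
}

site_calls_frame <- function(joint, i) {
  data.frame(sample = joint$samples,
             gt = joint$gt[i, ], gq = joint$gq[i, ],
             ad_ref = joint$ad_ref[i, ], ad_alt = joint$ad_alt[i, ],
             dp = joint$dp[i, ], stringsAsFactors = FALSE, row.names = NULL)
}

#' Hard site filters: no-call and genotype quality
#'
#' A site fails when any sample is no-called, or when any sample's genotype
#' quality is strictly below `min_gq`. The recorded reason names the first
#' rule violated and the offending sample (no-call checked before GQ).
#'
#' @param calls data.frame with one row per tree leaf: columns sample, gt,
#'   gq, ad_ref, ad_alt, dp.
#' @param config a [filter_config()].
#' @param samples optional expected sample set; missing samples are an error.
#' @return list(pass, reason, sample); reason is NA when passing.
#' @export
hard_site_filters <- function(calls, config = filter_config(), samples = NULL) {
  if (!is.null(samples)) {
    miss <- setdiff(samples, calls$sample)
    if (length(miss)) stop("missing sample calls: ", paste(miss, collapse = ", "))
  }
  nc <- which(calls$gt == "NO_CALL")
  if (length(nc))
    return(list(pass = FALSE, reason = "no_call", sample = calls$sample[nc[1]]))
  lg <- which(calls$gq < config$min_gq)
  if (length(lg))
    return(list(pass = FALSE, reason = "low_gq", sample = calls$sample[lg[1]]))
  list(pass = TRUE, reason = NA_character_, sample = NA_character_)
}

#' Local ploidy from copy-number segments
#'
#' Ploidy at a 1-based position for one sample: `round(2 * copy ratio)` of
#' the covering segment (half rounded up), or 2 where no segment covers the
#' position. Copy ratio 1.5 gives ploidy 3, ratio 2 gives 4, ratio ~0 gives
#' 0 (homozygous deletion; such sites are handled by CNV region exclusion
#' rather than the allele-depth test).
#'
#' @param segments segment data.frame ([read_cnv_segments()] convention:
#'   0-based half-open), or NULL for diploid everywhere.
#' @param sample sample label.
#' @param chrom,pos 1-based genomic position (vectorized over pos).
#' @return integer ploidy vector.
#' @export
ploidy_at <- function(segments, sample, chrom, pos) {
  pos <- as.integer(pos)
  stopifnot(all(pos >= 1))
  out <- rep(2L, length(pos))
  if (is.null(segments) || !nrow(segments)) return(out)
  s <- segments[segments$sample == sample & segments$chrom == chrom, ,
                drop = FALSE]
  if (!nrow(s)) return(out)
  p0 <- pos - 1L  # 0-based
  for (k in seq_len(nrow(s))) {
    hit <- p0 >= s$start[k] & p0 < s$end[k]
    out[hit] <- max(0L, as.integer(floor(2 * s$copy_ratio[k] + 0.5)))
  }
  out
}

#' Minimum passing alt-allele depth
#'
#' The smallest alt depth `k` whose binomial CDF at `k` (n = depth,
#' p = 1/ploidy) reaches `percentile`. An observed alt depth d is "below the
#' percentile" (fails the balance test) exactly when d < k. This is the
#' binomial quantile, computed with [stats::qbinom()].
#'
#' @param depth total read depth (vectorized).
#' @param ploidy local copy number, >= 1.
#' @param percentile lower-tail probability (default 0.01).
#' @return integer threshold vector.
#' @export
min_passing_alt_depth <- function(depth, ploidy, percentile = 0.01) {
  if (any(ploidy < 1)) stop("ploidy must be >= 1 for the allele-depth test")
  stopifnot(all(depth >= 0), percentile > 0, percentile < 1)
  as.integer(stats::qbinom(percentile, size = depth, prob = 1 / ploidy))
}

#' Binomial allele-balance filter
#'
#' Among heterozygous carriers only, counts carriers whose alt allele depth
#' falls below [min_passing_alt_depth()] at their local ploidy; the site
#' fails when that count exceeds half the denominator (strictly). Hom-var
#' carriers are exempt, and sites with no het carriers pass. Depth is the
#' sample's DP, falling back to the AD component sum when DP is missing.
#'
#' @param calls per-sample calls data.frame as in [hard_site_filters()].
#' @param ploidy integer vector of local ploidies, parallel to `calls`
#'   rows (default diploid).
#' @param config a [filter_config()].
#' @return list(pass, n_het, n_below).
#' @export
allele_balance_filter <- function(calls, ploidy = rep(2L, nrow(calls)),
                                  config = filter_config()) {
  stopifnot(length(ploidy) == nrow(calls))
  het <- which(calls$gt == "HET")
  if (!length(het)) return(list(pass = TRUE, n_het = 0L, n_below = 0L))
  depth <- ifelse(is.na(calls$dp[het]),
                  calls$ad_ref[het] + calls$ad_alt[het], calls$dp[het])
  pl <- ploidy[het]
  usable <- pl >= 1          # hom-del ploidy handled by CNV exclusion
  below <- logical(length(het))
  if (any(usable)) {
    thr <- min_passing_alt_depth(depth[usable], pl[usable],
                                 config$ad_percentile)
    below[usable] <- calls$ad_alt[het][usable] < thr
  }
  denom <- switch(config$ab_denominator,
                  het_carriers = length(het),
                  all_samples = nrow(calls))
  list(pass = !(sum(below) > denom / 2),
       n_het = length(het), n_below = sum(below))
}
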