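#' Score caller output against a truth set
#'
#' Site-level comparison of a somatic caller's calls with a truth set.
#' Every query call lands in exactly one bin: outside the high-confidence
#' region it is \emph{ignored} (neither rewarded nor penalized — these are
#' the excluded Leaf Variant and CNV footprints); matching a positive on
#' normalized (chrom, pos, ref, alt) it is a true positive; any other
#' in-region call is a false positive, which includes calls at Germline and
#' Bad Branch sites. Positives with no matching call are false negatives.
#' Genotype and allele fraction of the query are not scored.
#'
#' @param query data.frame with chrom, pos, ref, alt (normalized internally).
#' @param truth a [build_truth_set()] result.
#' @return list with data.frame `counts` (per variant_type: tp, fp, fn,
#'   ignored) and the query partition as a character vector.
#' @export
compare_to_truth <- function(query, truth) {
  stopifnot(inherits(truth, "truth_set"))
  q <- normalize_variants(query$chrom, query$pos, query$ref, query$alt)
  region_contigs <- GenomeInfoDb::seqlevels(truth$callable)
  bad <- setdiff(unique(q$chrom), region_contigs)
  if (length(bad))
    stop("query contigs absent from the region definition: ",
         paste(bad, collapse = ", "))

  vtype <- function(d) ifelse(nchar(d$ref) != nchar(d$alt), "indel", "snv")
  qkey <- variant_key(q$chrom, q$pos, q$ref, q$alt)
  if (anyDuplicated(qkey)) {
    keep <- !duplicated(qkey)
    q <- q[keep, , drop = FALSE]; qkey <- qkey[keep]
  }
  p <- truth$positives
  pkey <- variant_key(p$chrom, p$pos, p$ref, p$alt)

  if (nrow(q)) {
    gr <- GenomicRanges::GRanges(q$chrom,
                                 IRanges::IRanges(q$pos,
                                                  q$pos + nchar(q$ref) - 1L))
    hs <- harmonize_seqlevels(gr, truth$region)
    in_region <- IRanges::overlapsAny(hs[[1]], hs[[2]])
  } else in_region <- logical(0)

  bin <- ifelse(!in_region, "ignored",
                ifelse(qkey %in% pkey, "tp", "fp"))
  fn_key <- setdiff(pkey, qkey[bin == "tp"])

  qt <- vtype(q); pt <- vtype(p)
  counts <- do.call(rbind, lapply(c("snv", "indel"), function(ty) {
    data.frame(variant_type = ty,
               tp = sum(bin == "tp" & qt == ty),
               fp = sum(bin == "fp" & qt == ty),
               fn = sum(pkey %in% fn_key & pt == ty),
               ignored = sum(bin == "ignored" & qt == ty),
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, bins = stats::setNames(bin, qkey))
}

#' Clopper-Pearson sensitivity interval
#'
#' Exact binomial confidence interval for sensitivity tp / (tp + fn),
#' computed from beta quantiles: lower bound `qbeta(a/2, tp, fn + 1)` (0
#' when tp = 0), upper bound `qbeta(1 - a/2, tp + 1, fn)` (1 when fn = 0).
#' Exactness matters because the positive count per mixture is small.
#'
#' @param tp,fn true positive and false negative counts; tp + fn >= 1.
#' @param level confidence level (default 0.95).
#' @return list(estimate, lower, upper).
#' @export
sensitivity_ci <- function(tp, fn, level = 0.95) {
  stopifnot(tp >= 0, fn >= 0, level > 0, level < 1)
  n <- tp + fn
  if (n == 0) stop("sensitivity undefined: no positives (tp + fn = 0)")
  a <- 1 - level
  list(estimate = tp / n,
       lower = if (tp == 0) 0 else stats::qbeta(a / 2, tp, fn + 1),
       upper = if (fn == 0) 1 else stats::qbeta(1 - a / 2, tp + 1, fn))
}

#' Asymptotic false-positive-rate interval
#'
#' FPR per megabase of high-confidence region, with the normal
#' approximation interval for the per-base proportion
#' `p +- z * sqrt(p (1 - p) / bases)`, clipped to [0, 1]. The large number
#' of region bases justifies the approximation.
#'
#' @param fp false positive count.
#' @param bases high-confidence region size in bases, >= 1.
#' @param level confidence level (default 0.95).
#' @return list(rate_per_mb, lower, upper) — all per megabase.
#' @export
fpr_ci <- function(fp, bases, level = 0.95) {
  stopifnot(fp >= 0, bases >= 1, level > 0, level < 1)
  p <- fp / bases
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / bases)
  list(rate_per_mb = p * 1e6,
       lower = max(0, p - half) * 1e6,
       upper = min(1, p + half) * 1e6)
}

#' Full evaluation report for one mixture
#'
#' Combines [compare_to_truth()], [sensitivity_ci()] and [fpr_ci()] into a
#' per-variant-type report.
#'
#' @param query caller calls data.frame (chrom, pos, ref, alt).
#' @param truth a [build_truth_set()] result.
#' @param purity mixture purity for the metadata columns (optional).
#' @param level confidence level.
#' @return data.frame (class `eval_report`): one row per variant type with
#'   counts, sensitivity + CI, FPR per Mb + CI, region size and mixture
#'   metadata.
#' @export
evaluate_calls <- function(query, truth, purity = NA_real_, level = 0.95) {
  cmp <- compare_to_truth(query, truth)
  bases <- interval_size(truth$region)
  out <- cmp$counts
  out$sensitivity <- out$sens_lower <- out$sens_upper <- NA_real_
  out$fpr_per_mb <- out$fpr_lower <- out$fpr_upper <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (out$tp[i] + out$fn[i] > 0) {
      s <- sensitivity_ci(out$tp[i], out$fn[i], level)
      out$sensitivity[i] <- s$estimate
      out$sens_lower[i] <- s$lower; out$sens_upper[i] <- s$upper
    }
    f <- fpr_ci(out$fp[i], bases, level)
    out$fpr_per_mb[i] <- f$rate_per_mb
    out$fpr_lower[i] <- f$lower; out$fpr_upper[i] <- f$upper
  }
  out$region_bases <- bases
  out$tumor <- truth$tumor
  out$mixed_normal <- truth$mixed_normal
  out$purity <- purity
  class(out) <- c("eval_report", "data.frame")
  out
}
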