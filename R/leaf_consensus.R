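#' Consolidate pairwise somatic runs for one sample
#'
#' Each sample is run as the "tumor" once against every other leaf as the
#' matched normal (n-1 runs), so a genuine leaf-private mutation can be
#' called up to n-1 times, some calls filtered by the somatic caller. A
#' site enters the sample's potential leaf calls when strictly more than
#' half of the calls at the site pass the caller's filters, with one
#' exception: a site called in all n-1 runs (filtered or not) is included
#' regardless, since unanimous calling is itself evidence of real
#' variation. The majority denominator is configurable
#' (`leaf_majority_denominator`): runs calling the site (default) or all
#' n-1 runs.
#'
#' @param sample the tumor-side sample label.
#' @param runs list of [pairwise_calls()] with `tumor == sample` and
#'   pairwise-distinct normals.
#' @param n_samples total number of tree leaves (so runs must number
#'   n_samples - 1).
#' @param config a [filter_config()].
#' @return data.frame with chrom, pos, ref, alt, n_called, n_passing for the
#'   included sites.
#' @export
consolidate_sample_calls <- function(sample, runs, n_samples,
                                     config = filter_config()) {
  if (length(runs) != n_samples - 1)
    stop("expected ", n_samples - 1, " runs for ", sample,
         ", got ", length(runs))
  tums <- vapply(runs, `[[`, "", "tumor")
  if (!all(tums == sample))
    stop("run with tumor ", tums[tums != sample][1], " != ", sample)
  norms <- vapply(runs, `[[`, "", "normal")
  if (anyDuplicated(norms))
    stop("duplicate normal in runs for ", sample, ": ",
         norms[duplicated(norms)][1])

  all_calls <- do.call(rbind, lapply(runs, function(r) r$calls))
  if (is.null(all_calls) || !nrow(all_calls))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      n_called = integer(), n_passing = integer()))
  key <- variant_key(all_calls$chrom, all_calls$pos,
                     all_calls$ref, all_calls$alt)
  n_called <- tapply(key, key, length)
  n_pass <- tapply(all_calls$status == "PASS", key, sum)
  uk <- names(n_called)
  first <- match(uk, key)
  denom <- switch(config$leaf_majority_denominator,
                  called = as.integer(n_called),
                  total = rep(n_samples - 1L, length(uk)))
  include <- (as.integer(n_pass) > denom / 2) |
    (as.integer(n_called) == n_samples - 1L)
  out <- data.frame(chrom = all_calls$chrom[first],
                    pos = all_calls$pos[first],
                    ref = all_calls$ref[first],
                    alt = all_calls$alt[first],
                    n_called = as.integer(n_called),
                    n_passing = as.integer(n_pass),
                    stringsAsFactors = FALSE)[include, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Leaf Variant sites across all samples
#'
#' After consolidating every sample's pairwise runs, a site is a Leaf
#' Variant of sample s when it appears in s's potential leaf calls and in
#' no other sample's. Leaf Variants have ambiguous origin (late mutation in
#' the expanded clone, subclonal variation, or artifact) and their
#' footprint is excluded from the high-confidence region of any mixture
#' involving s.
#'
#' @param consolidated named list (by sample) of data.frames from
#'   [consolidate_sample_calls()].
#' @return named list (by sample) of data.frames with chrom, pos, ref, alt.
#' @export
leaf_variant_sites <- function(consolidated) {
  keys <- lapply(consolidated, function(d)
    variant_key(d$chrom, d$pos, d$ref, d$alt))
  tab <- table(unlist(keys, use.names = FALSE))
  unique_keys <- names(tab)[tab == 1]
  out <- lapply(names(consolidated), function(s) {
    d <- consolidated[[s]]
    k <- keys[[s]]
    d[k %in% unique_keys, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  })
  names(out) <- names(consolidated)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
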