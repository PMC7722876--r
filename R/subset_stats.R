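#' Variant counts per carrier subset
#'
#' The tree-validity analysis: take the catalog \emph{before} the tree
#' filter (all quality filters applied, tree concordance not), optionally
#' remove variants in a region blacklist (e.g. a chromosome lost to a large
#' LOH event) or with population allele frequency above a threshold (common
#' germline variation), and tally the remaining variants by their exact
#' carrier subset. Every clade subset of the tree is reported even at count
#' zero; inconsistent subsets appear only when observed. Subsets of size 2
#' to n-1 are eligible for the rank test; sizes 1 and n are tracked but
#' ineligible.
#'
#' @param catalog a `variant_catalog` from [validated_truth_variants()]
#'   (FILTERED rows are dropped here).
#' @param tree the [lineage_tree()].
#' @param blacklist optional `GRanges` of regions to exclude.
#' @param pop_af optional numeric vector of population allele frequencies
#'   parallel to catalog rows (NA = unknown, kept).
#' @param af_threshold variants with pop_af strictly above this are removed
#'   (default 0.01).
#' @return data.frame (class `subset_counts`) with subset (string key),
#'   size, count, consistent, eligible.
#' @export
subset_counts <- function(catalog, tree, blacklist = NULL, pop_af = NULL,
                          af_threshold = 0.01) {
  tree <- lineage_tree(tree)
  n <- length(tree_leaves(tree))
  keep <- catalog$class != "FILTERED" & catalog$n_carriers > 0
  if (!is.null(pop_af)) {
    stopifnot(length(pop_af) == nrow(catalog))
    keep <- keep & !(!is.na(pop_af) & pop_af > af_threshold)
  }
  if (!is.null(blacklist) && length(blacklist)) {
    gr <- GenomicRanges::GRanges(catalog$chrom,
                                 IRanges::IRanges(catalog$pos, catalog$pos))
    hs <- harmonize_seqlevels(gr, blacklist)
    keep <- keep & !IRanges::overlapsAny(hs[[1]], hs[[2]])
  }
  cat2 <- catalog[keep, , drop = FALSE]
  subset_key <- vapply(cat2$carriers, function(cs)
    paste(sort(cs), collapse = ","), "")
  tab <- table(subset_key)

  clade_keys <- vapply(clade_subsets(tree), paste, "", collapse = ",")
  all_keys <- union(unname(clade_keys), names(tab))
  counts <- as.integer(tab[all_keys]); counts[is.na(counts)] <- 0L
  size <- lengths(strsplit(all_keys, ","))
  out <- data.frame(subset = all_keys, size = size, count = counts,
                    consistent = all_keys %in% clade_keys,
                    stringsAsFactors = FALSE)
  out$eligible <- out$size >= 2 & out$size <= n - 1
  out <- out[order(-out$count, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("subset_counts", "data.frame")
  out
}

#' Wilcoxon rank-sum test on subset counts
#'
#' Compares variant counts of tree-consistent subsets against inconsistent
#' subsets that hold at least one variant, using the rank-sum test with
#' continuity correction (normal approximation, tie-corrected variance),
#' plus the Hodges-Lehmann location-shift estimate and its confidence
#' interval from inverting the test. A clear location shift toward the
#' consistent subsets supports the lineage tree itself.
#'
#' @param counts a `subset_counts` data.frame, or a list with numeric
#'   elements `x` (consistent counts) and `y` (inconsistent counts).
#' @param conf_level confidence level (default 0.95).
#' @return list(W, p_value, shift, conf_int, n_consistent, n_inconsistent).
#' @export
subset_rank_test <- function(counts, conf_level = 0.95) {
  if (is.data.frame(counts)) {
    el <- counts[counts$eligible, , drop = FALSE]
    x <- el$count[el$consistent]
    y <- el$count[!el$consistent & el$count >= 1]
  } else {
    x <- counts$x; y <- counts$y
  }
  if (!length(x) || !length(y))
    stop("both consistent and inconsistent groups must be non-empty")
  if (length(unique(c(x, y))) == 1)
    return(list(W = length(x) * length(y) / 2, p_value = 1, shift = 0,
                conf_int = c(0, 0), n_consistent = length(x),
                n_inconsistent = length(y)))
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = FALSE, correct = TRUE, conf.int = TRUE,
    conf.level = conf_level, alternative = "two.sided"))
  list(W = unname(wt$statistic), p_value = wt$p.value,
       shift = unname(wt$estimate), conf_int = unname(wt$conf.int),
       n_consistent = length(x), n_inconsistent = length(y))
}
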