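#' Enumerate valid tumor-normal mixtures
#'
#' All ordered (tumor, mixed-in normal) leaf assignments crossed with the
#' requested purities, excluding (a) sister assignments — sister samples
#' share every lineage-validated variant, so nothing distinguishes them —
#' and (b) assignments whose positive set is empty. With a
#' `variant_catalog` the empty-truth test counts actual GOOD_BRANCH
#' positives; without one it falls back to topology: a direction is usable
#' when some clade contains the tumor and excludes the normal. On an
#' 11-leaf tree with five sister pairs and one unpaired leaf sibling to a
#' cherry, this yields 98 directed assignments per purity.
#'
#' @param tree a [lineage_tree()].
#' @param purities numeric vector of purities in (0, 1].
#' @param catalog optional `variant_catalog` from
#'   [validated_truth_variants()].
#' @return data.frame (class `mixture_plan`) with tumor, mixed_normal,
#'   matched_normal, purity.
#' @export
enumerate_mixtures <- function(tree, purities = c(0.1, 0.2, 0.5),
                               catalog = NULL) {
  if (any(purities <= 0 | purities > 1))
    stop("purity must lie in (0, 1]")
  tree <- lineage_tree(tree)
  leaves <- sort(tree_leaves(tree))
  sis <- sister_pairs(tree)
  sis_key <- vapply(sis, paste, "", collapse = "\r")
  clades <- clade_subsets(tree)

  has_positives <- function(t, n) {
    if (!is.null(catalog)) {
      gb <- catalog$carriers[catalog$class == "GOOD_BRANCH"]
      return(any(vapply(gb, function(cs) t %in% cs && !(n %in% cs), TRUE)))
    }
    any(vapply(clades, function(cl) t %in% cl && !(n %in% cl), TRUE))
  }

  rows <- list()
  for (t in leaves) for (n in leaves) {
    if (t == n) next
    if (paste(sort(c(t, n)), collapse = "\r") %in% sis_key) next
    if (!has_positives(t, n)) next
    rows[[length(rows) + 1L]] <- data.frame(
      tumor = t, mixed_normal = n,
      matched_normal = matched_normal(tree, n), stringsAsFactors = FALSE)
  }
  base <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(sort(purities), function(a)
    cbind(base, purity = a)))
  rownames(out) <- NULL
  class(out) <- c("mixture_plan", "data.frame")
  out
}

#' Downsampling fractions for a mixture
#'
#' A mixture at purity `purity` and target depth `target_depth` is produced
#' by downsampling the pure tumor to fraction `purity * target_depth /
#' tumor_depth` of its reads and the mixed-in normal to `(1 - purity) *
#' target_depth / normal_depth`, then merging. Fractions above 1 are
#' impossible; the error states the maximum achievable target depth.
#'
#' @param purity tumor purity in (0, 1].
#' @param tumor_depth,normal_depth mean sequencing depths of the inputs.
#' @param target_depth desired depth of the mixture.
#' @return list(tumor_fraction, normal_fraction).
#' @export
downsample_plan <- function(purity, tumor_depth, normal_depth,
                            target_depth) {
  stopifnot(purity > 0, purity <= 1, tumor_depth > 0, normal_depth > 0,
            target_depth > 0)
  f_t <- purity * target_depth / tumor_depth
  f_n <- (1 - purity) * target_depth / normal_depth
  if (f_t > 1 || f_n > 1) {
    max_d <- min(tumor_depth / purity,
                 if (purity < 1) normal_depth / (1 - purity) else Inf)
    stop("insufficient depth: maximum achievable target depth at purity ",
         purity, " is ", signif(max_d, 4))
  }
  list(tumor_fraction = f_t, normal_fraction = f_n)
}

#' Expected allele fraction in a mixture
#'
#' For a somatic variant present on `alt_copies` of the tumor's
#' `tumor_copies` local copies, diluted with a normal of `normal_copies`
#' (diploid by default) at purity `purity`:
#' `purity * alt_copies / (purity * tumor_copies + (1 - purity) *
#' normal_copies)`. A diploid het runs at half the purity; a copy-neutral
#' LOH homozygote at the purity itself.
#'
#' @param purity tumor purity in (0, 1].
#' @param alt_copies copies carrying the alt allele, 0..tumor_copies.
#' @param tumor_copies local total copy number in the tumor (default 2).
#' @param normal_copies local total copy number in the normal (default 2).
#' @return expected allele fraction.
#' @export
expected_allele_fraction <- function(purity, alt_copies, tumor_copies = 2,
                                     normal_copies = 2) {
  stopifnot(purity > 0, purity <= 1, alt_copies >= 0,
            alt_copies <= tumor_copies)
  denom <- purity * tumor_copies + (1 - purity) * normal_copies
  if (denom == 0)
    stop("zero total copies in the mixture (purity 1 over a deletion)")
  purity * alt_copies / denom
}
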