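#' Carrier set of a site
#'
#' The samples carrying the alt allele at a site: genotype class HET or
#' HOM_VAR. Zygosity is deliberately ignored when comparing alleles across
#' the tree — a branch mutation may appear heterozygous in one carrier and
#' homozygous in another after loss of heterozygosity.
#'
#' @param joint a [joint_calls()] object.
#' @param i site row index.
#' @return character vector of sample labels (possibly empty).
#' @export
carrier_set <- function(joint, i) {
  if (i < 1 || i > n_sites(joint)) stop("site index ", i, " out of range")
  sort(joint$samples[joint$gt[i, ] %in% c("HET", "HOM_VAR")])
}

#' Classify a carrier set against the lineage tree
#'
#' Variant classes by carrier set over the n leaves:
#' \describe{
#'   \item{GERMLINE}{carried by all n samples (true germline, or somatic
#'     before the lineage observation began).}
#'   \item{LEAF}{carried by exactly one sample (post-tree mutation or
#'     artifact; ambiguous).}
#'   \item{GOOD_BRANCH}{2..n-1 carriers forming exactly one clade — the
#'     lineage-validated somatic variants.}
#'   \item{BAD_BRANCH}{2..n-1 carriers not forming a clade (artifact or
#'     missed call).}
#' }
#'
#' @param carriers non-empty character vector of leaf labels.
#' @param tree a [lineage_tree()].
#' @return list(class, carriers, clade) where clade is the witnessing
#'   internal node id for GOOD_BRANCH, else NA.
#' @export
classify_variant <- function(carriers, tree) {
  tree <- lineage_tree(tree)
  leaves <- tree_leaves(tree)
  carriers <- sort(unique(as.character(carriers)))
  if (!length(carriers)) stop("empty carrier set")
  unknown <- setdiff(carriers, leaves)
  if (length(unknown))
    stop("unknown carriers: ", paste(unknown, collapse = ", "))
  n <- length(leaves)
  if (length(carriers) == n)
    return(list(class = "GERMLINE", carriers = carriers, clade = NA_character_))
  if (length(carriers) == 1)
    return(list(class = "LEAF", carriers = carriers, clade = NA_character_))
  clades <- clade_subsets(tree)
  key <- paste(carriers, collapse = "\r")
  hit <- which(vapply(clades, paste, "", collapse = "\r") == key)
  if (length(hit))
    return(list(class = "GOOD_BRANCH", carriers = carriers,
                clade = names(clades)[hit[1]]))
  list(class = "BAD_BRANCH", carriers = carriers, clade = NA_character_)
}

#' Validated variant catalog
#'
#' Runs every site of a joint call set through the filter cascade and
#' lineage classification. Filter precedence (first failure recorded):
#' upstream FILTER, no-call, genotype quality, allele balance, then tree
#' concordance. Sites with an empty carrier set after filtering
#' (monomorphic) are dropped. GOOD_BRANCH rows are the lineage-validated
#' somatic variants; GERMLINE and BAD_BRANCH rows are retained because the
#' truth-set semantics need them (in-region non-positives).
#'
#' @param joint a [joint_calls()] object.
#' @param tree a [lineage_tree()] whose leaves equal the joint samples.
#' @param segments CNV segment data.frame for local ploidy, or NULL for
#'   diploid everywhere.
#' @param config a [filter_config()].
#' @return data.frame (class `variant_catalog`) with columns chrom, pos,
#'   ref, alt, class (GERMLINE/LEAF/GOOD_BRANCH/BAD_BRANCH/FILTERED),
#'   filter_reason, clade, carriers (list column), n_carriers.
#' @export
validated_truth_variants <- function(joint, tree, segments = NULL,
                                     config = filter_config()) {
  tree <- lineage_tree(tree)
  if (!setequal(tree_leaves(tree), joint$samples))
    stop("tree leaves and joint-call samples differ")
  clades <- clade_subsets(tree)
  clade_keys <- vapply(clades, paste, "", collapse = "\r")
  n <- length(joint$samples)

  m <- n_sites(joint)
  class <- character(m); reason <- rep(NA_character_, m)
  clade <- rep(NA_character_, m); carriers <- vector("list", m)
  keep <- rep(TRUE, m)

  for (i in seq_len(m)) {
    calls <- site_calls_frame(joint, i)
    cs <- sort(calls$sample[calls$gt %in% c("HET", "HOM_VAR")])
    carriers[[i]] <- cs
    if (!joint$sites$pass[i]) {
      class[i] <- "FILTERED"; reason[i] <- "upstream_filter"; next
    }
    hf <- hard_site_filters(calls, config)
    if (!hf$pass) {
      class[i] <- "FILTERED"
      reason[i] <- paste0(hf$reason, ":", hf$sample)
      next
    }
    if (!length(cs)) { keep[i] <- FALSE; next }  # monomorphic
    pl <- vapply(seq_len(nrow(calls)), function(j)
      ploidy_at(segments, calls$sample[j], joint$sites$chrom[i],
                joint$sites$pos[i]), 1L)
    ab <- allele_balance_filter(calls, pl, config)
    if (!ab$pass) {
      class[i] <- "FILTERED"; reason[i] <- "allele_balance"; next
    }
    if (length(cs) == n) class[i] <- "GERMLINE"
    else if (length(cs) == 1) class[i] <- "LEAF"
    else {
      hit <- which(clade_keys == paste(cs, collapse = "\r"))
      if (length(hit)) {
        class[i] <- "GOOD_BRANCH"; clade[i] <- names(clades)[hit[1]]
      } else class[i] <- "BAD_BRANCH"
    }
  }

  out <- cbind(joint$sites[, c("chrom", "pos", "ref", "alt")],
               data.frame(class = class, filter_reason = reason,
                          clade = clade, stringsAsFactors = FALSE))
  out$carriers <- carriers
  out$n_carriers <- lengths(carriers)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_catalog", "data.frame")
  out
}
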