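#' Matched normal for a mixed-in normal
#'
#' The sample handed to the somatic caller as the matched normal: the
#' closest relative of the mixed-in normal (first element of
#' [nearest_relatives()], lexicographic tie-break). Two distinct samples
#' are needed because one leaf does not carry enough coverage to be both
#' the diluting normal and the matched normal.
#'
#' @param tree a [lineage_tree()].
#' @param mixed_in_normal a leaf label.
#' @return a leaf label.
#' @export
matched_normal <- function(tree, mixed_in_normal) {
  nearest_relatives(tree, mixed_in_normal)[1]
}

#' Build the truth set for one tumor / mixed-in-normal assignment
#'
#' Positives are the GOOD_BRANCH variants carried by the tumor but not by
#' the mixed-in normal: real somatic mutations that distinguish the two
#' samples. The high-confidence region is the callable genome minus the
#' Leaf Variant footprints of the tumor and the mixed-in normal (reference
#' span plus `config$leaf_pad`) and minus the tumor's CNV exclusion
#' regions. Germline variants, Bad Branch variants and Good Branch variants
#' carried by both samples stay inside the region as non-positives: calls
#' there score as false positives, which deliberately keeps recurrent
#' artifacts in the benchmark.
#'
#' @param tumor,mixed_normal distinct leaf labels.
#' @param tree a [lineage_tree()].
#' @param catalog a `variant_catalog` from [validated_truth_variants()].
#' @param leaf_sites named list from [leaf_variant_sites()] (may be NULL).
#' @param cnv_exclusions `GRanges` from [cnv_exclusion_regions()] for this
#'   tumor (may be NULL).
#' @param callable `GRanges` callable-genome interval set.
#' @param config a [filter_config()].
#' @return object of class `truth_set`: tumor, mixed_normal,
#'   matched_normal, positives (data.frame chrom,pos,ref,alt,clade), region
#'   (`GRanges`), exclusions (list: leaf, cnv), excluded_positives, callable.
#' @export
build_truth_set <- function(tumor, mixed_normal, tree, catalog,
                            leaf_sites = NULL, cnv_exclusions = NULL,
                            callable, config = filter_config()) {
  tree <- lineage_tree(tree)
  leaves <- tree_leaves(tree)
  if (!tumor %in% leaves) stop("unknown tumor: ", tumor)
  if (!mixed_normal %in% leaves) stop("unknown mixed-in normal: ", mixed_normal)
  if (tumor == mixed_normal) stop("tumor and mixed-in normal must differ")

  gb <- catalog[catalog$class == "GOOD_BRANCH", , drop = FALSE]
  in_t <- vapply(gb$carriers, function(cs) tumor %in% cs, TRUE)
  in_n <- vapply(gb$carriers, function(cs) mixed_normal %in% cs, TRUE)
  pos <- gb[in_t & !in_n, c("chrom", "pos", "ref", "alt", "clade"),
            drop = FALSE]

  leaf_excl <- interval_set()
  for (s in intersect(c(tumor, mixed_normal), names(leaf_sites))) {
    d <- leaf_sites[[s]]
    if (!is.null(d) && nrow(d))
      leaf_excl <- interval_union(leaf_excl, interval_set(
        d$chrom,
        pmax(0L, d$pos - 1L - config$leaf_pad),
        d$pos - 1L + nchar(d$ref) + config$leaf_pad))
  }
  cnv_excl <- if (is.null(cnv_exclusions)) interval_set() else cnv_exclusions
  region <- interval_subtract(
    interval_subtract(GenomicRanges::reduce(callable), leaf_excl), cnv_excl)

  ## positives must lie inside the region; those knocked out by exclusions
  ## are dropped and recorded
  if (nrow(pos)) {
    span <- interval_set(pos$chrom, pos$pos - 1L,
                         pos$pos - 1L + nchar(pos$ref))
    gr <- GenomicRanges::GRanges(pos$chrom,
                                 IRanges::IRanges(pos$pos,
                                                  pos$pos + nchar(pos$ref) - 1L))
    hs <- harmonize_seqlevels(gr, region)
    inside <- IRanges::overlapsAny(hs[[1]], hs[[2]])
  } else inside <- logical(0)
  excluded_positives <- pos[!inside, , drop = FALSE]
  pos <- pos[inside, , drop = FALSE]
  rownames(pos) <- rownames(excluded_positives) <- NULL

  ts <- structure(list(tumor = tumor, mixed_normal = mixed_normal,
                       matched_normal = matched_normal(tree, mixed_normal),
                       positives = pos, region = region,
                       exclusions = list(leaf = leaf_excl, cnv = cnv_excl),
                       excluded_positives = excluded_positives,
                       callable = GenomicRanges::reduce(callable)),
                  class = "truth_set")
  if (!nrow(pos))
    warning("truth set for tumor=", tumor, " normal=", mixed_normal,
            " has no positives; unusable for sensitivity benchmarking")
  ts
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set: tumor", x$tumor, "/ mixed-in normal", x$mixed_normal,
      "/ matched normal", x$matched_normal, "\n")
  cat("  positives:", nrow(x$positives),
      "| region:", format(interval_size(x$region), big.mark = ","),
      "bases of", format(interval_size(x$callable), big.mark = ","),
      "callable\n")
  invisible(x)
}

#' Write / read truth-set artifacts
#'
#' The positive somatic variants go out as a sorted site-only VCF (1-based)
#' and the high-confidence region as a BED (0-based half-open). Reading the
#' two files back reproduces the positives and the region.
#'
#' @param truth a [build_truth_set()] result.
#' @param vcf_path,bed_path output paths.
#' @export
write_truth_outputs <- function(truth, vcf_path, bed_path) {
  stopifnot(inherits(truth, "truth_set"))
  p <- truth$positives
  contigs <- default_contig_lengths(
    c(as.character(GenomeInfoDb::seqnames(truth$callable)), p$chrom),
    c(BiocGenerics::end(truth$callable), p$pos))
  h <- c("##fileformat=VCFv4.2",
         sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                 as.integer(contigs)),
         sprintf("##tumor_sample=%s", truth$tumor),
         sprintf("##normal_sample=%s", truth$mixed_normal),
         paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO"), collapse = "\t"))
  body <- character()
  if (nrow(p)) {
    o <- order(p$chrom, p$pos, p$ref, p$alt)
    body <- paste(p$chrom[o], p$pos[o], ".", p$ref[o], p$alt[o], ".",
                  "PASS", ".", sep = "\t")
  }
  writeLines(c(h, body), vcf_path)
  write_bed(truth$region, bed_path)
  invisible(list(vcf = vcf_path, bed = bed_path))
}

#' @rdname write_truth_outputs
#' @return `read_truth_outputs()`: list with `positives` (data.frame) and
#'   `region` (`GRanges`).
#' @export
read_truth_outputs <- function(vcf_path, bed_path) {
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "lineage")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- as.list(methods::as(VariantAnnotation::alt(vcf), "CharacterList"))
  n <- length(rr)
  pos <- if (n) data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(alts, `[`, "", 1L), stringsAsFactors = FALSE)
  else data.frame(chrom = character(), pos = integer(),
                  ref = character(), alt = character())
  rownames(pos) <- NULL
  list(positives = pos, region = read_bed(bed_path))
}
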