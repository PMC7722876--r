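## Coordinate conventions: VCF positions are 1-based; BED and SEG (after
## import) are held as 0-based half-open in plain data frames; interval sets
## are GRanges (1-based closed, the Bioconductor convention). Conversion
## between the two is confined to interval_set()/as_bed_frame().

#' Site identity keys
#'
#' Variants are matched across files by normalized (chrom, pos, ref, alt).
#'
#' @param chrom,pos,ref,alt vectors describing biallelic variants.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Normalize variants to minimal representation
#'
#' Trims the longest shared allele suffix, then the longest shared prefix
#' (keeping at least one base of each allele and advancing `pos` past the
#' trimmed prefix). Caller VCFs represent the same indel in different ways;
#' all cross-file matching in the package happens after this normalization.
#' Symbolic alleles (`<DEL>`, breakends) are rejected: the truth set covers
#' short variants only.
#'
#' @param chrom,pos,ref,alt parallel vectors of biallelic records.
#' @return data.frame with columns chrom, pos, ref, alt.
#' @export
normalize_variants <- function(chrom, pos, ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt) | !nzchar(ref) | !nzchar(alt)
  if (any(bad))
    stop("non-ACGT or symbolic allele not supported: ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  pos <- as.integer(pos)
  for (i in which(nchar(ref) > 1 | nchar(alt) > 1)) {
    r <- strsplit(ref[i], "")[[1]]; a <- strsplit(alt[i], "")[[1]]
    ## shared suffix
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    ## shared prefix
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
  }
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Joint call set

#' Multi-sample joint genotype calls
#'
#' The container for joint calls across all tree leaves: one row per
#' normalized biallelic site, one column per sample in the genotype-class,
#' GQ, allele-depth and depth matrices. `pass` carries the upstream FILTER
#' status (site-level recalibration) of each site.
#'
#' @param samples character vector of sample labels (the tree leaves).
#' @param sites data.frame with chrom, pos, ref, alt, pass (logical).
#' @param gt character matrix (sites x samples) with values HOM_REF, HET,
#'   HOM_VAR, NO_CALL.
#' @param gq,ad_ref,ad_alt,dp integer matrices (sites x samples); `dp` may
#'   contain NA, in which case the AD component sum is used as depth.
#' @return an object of class `joint_calls`.
#' @export
joint_calls <- function(samples, sites, gt, gq, ad_ref, ad_alt, dp) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "pass") %in% names(sites)))
  n <- nrow(sites)
  for (m in list(gt, gq, ad_ref, ad_alt, dp))
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == length(samples))
  ok <- gt %in% c("HOM_REF", "HET", "HOM_VAR", "NO_CALL")
  if (!all(ok)) stop("invalid genotype class: ", gt[!ok][1])
  colnames(gt) <- colnames(gq) <- colnames(ad_ref) <-
    colnames(ad_alt) <- colnames(dp) <- samples
  rownames(sites) <- NULL
  structure(list(samples = samples, sites = sites, gt = gt, gq = gq,
                 ad_ref = ad_ref, ad_alt = ad_alt, dp = dp),
            class = "joint_calls")
}

#' @export
print.joint_calls <- function(x, ...) {
  cat("joint_calls:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  invisible(x)
}

#' @rdname joint_calls
#' @param x a `joint_calls` object.
#' @export
n_sites <- function(x) nrow(x$sites)

gt_from_string <- function(gt, alt_index) {
  ## genotype class of one sample w.r.t. alt allele `alt_index` (1-based)
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (length(a) == 0 || any(a == "." | a == "")) return("NO_CALL")
    k <- sum(a == as.character(alt_index))
    c("HOM_REF", "HET", "HOM_VAR")[k + 1L]
  }, "")
}

gt_to_string <- c(HOM_REF = "0/0", HET = "0/1", HOM_VAR = "1/1", NO_CALL = "./.")

#' Read a multi-sample joint VCF
#'
#' Parses a joint-genotyped VCF (GT, GQ, AD, DP FORMAT fields) into a
#' [joint_calls()] object. Multi-allelic records are split into biallelic
#' sites, each alt against the ref with AD restricted to that alt, then
#' normalized with [normalize_variants()]. FILTER equal to `PASS` maps to
#' the site pass flag.
#'
#' @param path VCF file.
#' @param samples optional expected sample set; a mismatch is an error.
#' @return a [joint_calls()] object.
#' @export
read_joint_calls <- function(path, samples = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "lineage")
  g <- VariantAnnotation::geno(vcf)
  for (f in c("GT", "AD", "DP", "GQ"))
    if (!f %in% names(g))
      stop("FORMAT field ", f, " missing from ", path)
  smp <- colnames(g$GT)
  if (!is.null(samples) && !setequal(smp, samples))
    stop("sample set in ", path, " (", paste(sort(smp), collapse = ","),
         ") does not match expected (", paste(sort(samples), collapse = ","), ")")
  if (!is.null(samples)) {
    ord <- match(samples, smp)
    smp <- samples
  } else ord <- seq_along(smp)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- as.list(methods::as(VariantAnnotation::alt(vcf), "CharacterList"))
  pass <- as.character(rr$FILTER) == "PASS"

  rows <- list()
  for (i in seq_along(chrom)) {
    nalt <- length(alts[[i]])
    ad_i <- g$AD[i, ord]
    for (j in seq_len(nalt)) {
      gtc <- gt_from_string(unname(g$GT[i, ord]), j)
      adr <- vapply(ad_i, function(v) as.integer(v[1]), 1L)
      ada <- vapply(ad_i, function(v)
        if (length(v) >= j + 1) as.integer(v[j + 1]) else NA_integer_, 1L)
      called <- gtc != "NO_CALL"
      if (any(called & (is.na(adr) | is.na(ada))))
        stop("record ", chrom[i], ":", pos[i],
             " lacks AD for a called sample")
      rows[[length(rows) + 1L]] <- list(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[[i]][j],
        pass = pass[i], gt = gtc,
        gq = as.integer(unname(g$GQ[i, ord])),
        ad_ref = adr, ad_alt = ada,
        dp = as.integer(unname(g$DP[i, ord])))
    }
  }
  nr <- length(rows)
  sites0 <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 1L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    pass = vapply(rows, `[[`, TRUE, "pass"), stringsAsFactors = FALSE)
  norm <- normalize_variants(sites0$chrom, sites0$pos, sites0$ref, sites0$alt)
  sites <- cbind(norm, pass = sites0$pass)
  mat <- function(f) matrix(unlist(lapply(rows, `[[`, f)), nrow = nr,
                            byrow = TRUE, dimnames = list(NULL, smp))
  joint_calls(smp, sites, mat("gt"), mat("gq"), mat("ad_ref"),
              mat("ad_alt"), mat("dp"))
}

vcf_header_lines <- function(contig_lengths, formats = TRUE) {
  h <- c("##fileformat=VCFv4.2",
         sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                 as.integer(contig_lengths)),
         "##FILTER=<ID=FAIL,Description=\"Failed upstream site filtering\">")
  if (formats)
    h <- c(h,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  h
}

default_contig_lengths <- function(chrom, pos) {
  len <- tapply(pos, chrom, max) + 1000L
  stats::setNames(as.integer(len), names(len))
}

#' Write a joint call set as a multi-sample VCF
#'
#' @param x a [joint_calls()] object.
#' @param path output VCF path.
#' @param contig_lengths named integer vector for the `##contig` header
#'   lines; defaults to max position + 1 kb per chromosome seen.
#' @return the path, invisibly.
#' @export
write_joint_vcf <- function(x, path, contig_lengths = NULL) {
  stopifnot(inherits(x, "joint_calls"))
  s <- x$sites
  if (is.null(contig_lengths))
    contig_lengths <- default_contig_lengths(s$chrom, s$pos)
  o <- order(s$chrom, s$pos, s$ref, s$alt)
  fmt_sample <- function(i, j) {
    if (x$gt[i, j] == "NO_CALL") return("./.:.:.:.")
    sprintf("%s:%d,%d:%d:%d", gt_to_string[[x$gt[i, j]]],
            x$ad_ref[i, j], x$ad_alt[i, j],
            if (is.na(x$dp[i, j])) x$ad_ref[i, j] + x$ad_alt[i, j] else x$dp[i, j],
            x$gq[i, j])
  }
  body <- vapply(o, function(i) {
    paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i], ".",
            if (s$pass[i]) "PASS" else "FAIL", ".", "GT:AD:DP:GQ",
            vapply(seq_along(x$samples), function(j) fmt_sample(i, j), "")),
          collapse = "\t")
  }, "")
  writeLines(c(vcf_header_lines(contig_lengths),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples), collapse = "\t"),
               body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Pairwise somatic calls

#' Per-pair somatic calls
#'
#' Somatic calls from one ordered tumor-normal run of a pairwise caller:
#' each site keeps only its FILTER status (`PASS` / `FILTERED`).
#'
#' @param tumor,normal sample labels, distinct.
#' @param calls data.frame with chrom, pos, ref, alt, status.
#' @return object of class `pairwise_calls`.
#' @export
pairwise_calls <- function(tumor, normal, calls) {
  if (identical(tumor, normal)) stop("tumor and normal must differ")
  stopifnot(all(c("chrom", "pos", "ref", "alt", "status") %in% names(calls)))
  if (!all(calls$status %in% c("PASS", "FILTERED")))
    stop("status must be PASS or FILTERED")
  rownames(calls) <- NULL
  structure(list(tumor = tumor, normal = normal,
                 calls = calls[, c("chrom", "pos", "ref", "alt", "status")]),
            class = "pairwise_calls")
}

#' Read one tumor-normal somatic VCF
#'
#' @param path VCF of one ordered tumor-normal run.
#' @param tumor,normal sample labels for the run.
#' @return a [pairwise_calls()] object; FILTER `PASS` maps to status PASS,
#'   anything else to FILTERED. Multi-allelic records are split and
#'   normalized as in [read_joint_calls()].
#' @export
read_pairwise_somatic <- function(path, tumor, normal) {
  vcf <- VariantAnnotation::readVcf(path, genome = "lineage")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- as.list(methods::as(VariantAnnotation::alt(vcf), "CharacterList"))
  filt <- as.character(rr$FILTER)
  nalt <- lengths(alts)
  idx <- rep(seq_along(chrom), nalt)
  norm <- normalize_variants(chrom[idx], pos[idx], ref[idx], unlist(alts))
  norm$status <- ifelse(filt[idx] == "PASS", "PASS", "FILTERED")
  pairwise_calls(tumor, normal, norm)
}

#' Write per-pair somatic calls as a VCF
#'
#' @param x a [pairwise_calls()] object.
#' @param path output path.
#' @param contig_lengths as in [write_joint_vcf()].
#' @export
write_pair_vcf <- function(x, path, contig_lengths = NULL) {
  stopifnot(inherits(x, "pairwise_calls"))
  cl <- x$calls
  if (is.null(contig_lengths))
    contig_lengths <- default_contig_lengths(
      c(cl$chrom, "chrUn"), c(cl$pos, 1L))
  o <- order(cl$chrom, cl$pos, cl$ref, cl$alt)
  h <- c("##fileformat=VCFv4.2",
         sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                 as.integer(contig_lengths)),
         "##FILTER=<ID=SomaticFiltered,Description=\"Failed somatic caller filters\">",
         sprintf("##tumor_sample=%s", x$tumor),
         sprintf("##normal_sample=%s", x$normal),
         paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
               collapse = "\t"))
  body <- paste(cl$chrom[o], cl$pos[o], ".", cl$ref[o], cl$alt[o], ".",
                ifelse(cl$status[o] == "PASS", "PASS", "SomaticFiltered"),
                ".", sep = "\t")
  writeLines(c(h, body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## CNV segments (SEG)

seg_col_aliases <- list(
  sample = c("sample", "id", "sample_id", "name"),
  chrom = c("chrom", "chromosome", "contig", "chr"),
  start = c("start", "loc.start"),
  end = c("end", "loc.end", "stop"),
  copy_ratio = c("copy_ratio", "ratio", "mean_copy_ratio", "copyratio"),
  call = c("call", "status", "cnv_call"))

#' Read per-sample CNV segments (SEG)
#'
#' Tab-delimited with a header naming sample, chromosome, start, end,
#' copy-ratio and call columns (common aliases accepted). Copy ratios are
#' linear (1 = diploid). The default dialect is 1-based inclusive
#' coordinates, converted on read to the 0-based half-open convention used
#' internally; segments of one sample must not overlap within a chromosome.
#'
#' @param path SEG file.
#' @param one_based logical; input dialect (default 1-based inclusive).
#' @return data.frame with columns sample, chrom, start, end (0-based
#'   half-open), copy_ratio, call (AMP/DEL/NEUTRAL).
#' @export
read_cnv_segments <- function(path, one_based = TRUE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(raw) <- tolower(names(raw))
  pick <- function(key) {
    hit <- intersect(seg_col_aliases[[key]], names(raw))
    if (!length(hit)) stop("SEG file ", path, " lacks a ", key, " column")
    raw[[hit[1]]]
  }
  seg <- data.frame(sample = as.character(pick("sample")),
                    chrom = as.character(pick("chrom")),
                    start = as.integer(pick("start")),
                    end = as.integer(pick("end")),
                    copy_ratio = as.numeric(pick("copy_ratio")),
                    call = toupper(as.character(pick("call"))),
                    stringsAsFactors = FALSE)
  if (one_based) seg$start <- seg$start - 1L
  validate_cnv_segments(seg)
}

validate_cnv_segments <- function(seg) {
  if (any(seg$start >= seg$end))
    stop("segment with start >= end: ",
         paste(seg$chrom[seg$start >= seg$end], seg$start[seg$start >= seg$end])[1])
  if (!all(seg$call %in% c("AMP", "DEL", "NEUTRAL")))
    stop("segment call must be AMP, DEL or NEUTRAL")
  if (any(seg$copy_ratio < 0)) stop("negative copy ratio")
  seg <- seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
  for (key in unique(paste(seg$sample, seg$chrom))) {
    s <- seg[paste(seg$sample, seg$chrom) == key, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      i <- which(s$start[-1] < s$end[-nrow(s)])[1]
      stop("overlapping segments for ", key, ": [", s$start[i], ",", s$end[i],
           ") and [", s$start[i + 1], ",", s$end[i + 1], ")")
    }
  }
  rownames(seg) <- NULL
  seg
}

#' @rdname read_cnv_segments
#' @param seg segment data.frame as returned by [read_cnv_segments()].
#' @export
write_cnv_segments <- function(seg, path, one_based = TRUE) {
  out <- seg
  if (one_based) out$start <- out$start + 1L
  utils::write.table(out[, c("sample", "chrom", "start", "end",
                             "copy_ratio", "call")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Interval sets

#' Genomic interval sets
#'
#' Interval sets (callable genome, high-confidence regions, exclusion
#' regions) are `GRanges` objects, always reduced (sorted, disjoint,
#' merged). `interval_set()` builds one from 0-based half-open coordinates;
#' `as_bed_frame()` converts back.
#'
#' @param chrom character vector.
#' @param start,end 0-based half-open coordinates.
#' @return a reduced `GRanges`.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer()) {
  if (length(start) && any(start >= end)) stop("interval with start >= end")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1L, end = end))
  GenomicRanges::reduce(gr)
}

#' @rdname interval_set
#' @param x a `GRanges`.
#' @export
as_bed_frame <- function(x) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
             start = BiocGenerics::start(x) - 1L,
             end = BiocGenerics::end(x), stringsAsFactors = FALSE)
}

#' @rdname interval_set
#' @export
interval_size <- function(x) sum(as.numeric(BiocGenerics::width(x)))

harmonize_seqlevels <- function(a, b) {
  sl <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- sl
  GenomeInfoDb::seqlevels(b) <- sl
  list(a, b)
}

#' Interval algebra
#'
#' Set difference and intersection of interval sets, with
#' `size(a minus b) = size(a) - size(a intersect b)`.
#'
#' @param a,b `GRanges` interval sets.
#' @return a reduced `GRanges`.
#' @export
interval_subtract <- function(a, b) {
  ab <- harmonize_seqlevels(a, b)
  GenomicRanges::reduce(GenomicRanges::setdiff(ab[[1]], ab[[2]],
                                               ignore.strand = TRUE))
}

#' @rdname interval_subtract
#' @export
interval_intersect <- function(a, b) {
  ab <- harmonize_seqlevels(a, b)
  GenomicRanges::reduce(GenomicRanges::intersect(ab[[1]], ab[[2]],
                                                 ignore.strand = TRUE))
}

#' @rdname interval_subtract
#' @export
interval_union <- function(a, b) {
  ab <- harmonize_seqlevels(a, b)
  GenomicRanges::reduce(GenomicRanges::union(ab[[1]], ab[[2]],
                                             ignore.strand = TRUE))
}

#' Read / write BED interval sets
#'
#' BED is 0-based half-open on disk; import/export goes through
#' `rtracklayer`, returning/consuming reduced `GRanges`.
#'
#' @param path BED file.
#' @export
read_bed <- function(path) {
  GenomicRanges::reduce(rtracklayer::import(path, format = "BED"))
}

#' @rdname read_bed
#' @param x a `GRanges`.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(GenomicRanges::reduce(x), path, format = "BED")
  invisible(path)
}
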