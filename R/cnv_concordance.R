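#' Group CNV segments into cross-sample events
#'
#' Non-neutral segments are grouped across samples into events: same
#' direction (AMP or DEL) and reciprocal overlap at least
#' `config$reciprocal_overlap`, by single-linkage within a chromosome. Each
#' event is classified against the lineage tree:
#' \describe{
#'   \item{ALL_SAMPLE}{carried by every leaf (germline or pre-tree).}
#'   \item{TREE_CONSISTENT}{carriers form a clade or a single leaf.}
#'   \item{DISCORDANT}{anything else — false positives in some samples or
#'     false negatives in others; which is unknowable from the calls.}
#' }
#'
#' @param segments segment data.frame ([read_cnv_segments()] convention).
#' @param tree a [lineage_tree()].
#' @param config a [filter_config()].
#' @return data.frame (class `cnv_events`) with chrom, start, end (0-based
#'   half-open union of member segments), direction, carriers (list
#'   column), n_carriers, concordance.
#' @export
group_cnv_events <- function(segments, tree, config = filter_config()) {
  tree <- lineage_tree(tree)
  leaves <- tree_leaves(tree)
  seg <- segments[segments$call != "NEUTRAL", , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_carriers = integer(), concordance = character())
  if (!nrow(seg)) {
    empty$carriers <- list()
    class(empty) <- c("cnv_events", "data.frame")
    return(empty)
  }
  unknown <- setdiff(unique(seg$sample), leaves)
  if (length(unknown))
    stop("segment samples not in tree: ", paste(unknown, collapse = ", "))

  recip_ov <- function(s1, e1, s2, e2) {
    ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
    pmin(ov / (e1 - s1), ov / (e2 - s2))
  }
  events <- list()
  for (dir in c("AMP", "DEL")) for (chr in unique(seg$chrom)) {
    s <- seg[seg$call == dir & seg$chrom == chr, , drop = FALSE]
    if (!nrow(s)) next
    s <- s[order(s$start, s$end), , drop = FALSE]
    ## single-linkage clusters under the reciprocal-overlap predicate
    comp <- seq_len(nrow(s))
    for (i in seq_len(nrow(s))) for (j in seq_len(nrow(s))) {
      if (i < j && recip_ov(s$start[i], s$end[i], s$start[j], s$end[j]) >=
          config$reciprocal_overlap)
        comp[comp == comp[j]] <- comp[i]
    }
    for (cc in unique(comp)) {
      m <- s[comp == cc, , drop = FALSE]
      carriers <- sort(unique(m$sample))
      conc <- if (setequal(carriers, leaves)) "ALL_SAMPLE"
        else if (length(carriers) == 1 ||
                 (length(carriers) <= length(leaves) - 1 &&
                  is_lineage_concordant(tree, carriers))) "TREE_CONSISTENT"
        else "DISCORDANT"
      events[[length(events) + 1L]] <- data.frame(
        chrom = chr, start = min(m$start), end = max(m$end),
        direction = dir, n_carriers = length(carriers),
        concordance = conc, stringsAsFactors = FALSE,
        carriers = I(list(carriers)))
    }
  }
  out <- do.call(rbind, events)
  out <- out[order(out$chrom, out$start, out$end, out$direction), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_events", "data.frame")
  out
}

mean_ratio_over <- function(segments, sample, chrom, start, end) {
  ## tumor copy ratio over an interval: coverage-weighted mean, uncovered
  ## bases count as ratio 1 (neutral)
  s <- segments[segments$sample == sample & segments$chrom == chrom, ,
                drop = FALSE]
  if (!nrow(s)) return(1)
  ov <- pmax(0, pmin(s$end, end) - pmax(s$start, start))
  covered <- sum(ov)
  if (covered == 0) return(1)
  (sum(ov * s$copy_ratio) + (end - start - covered) * 1) / (end - start)
}

#' Per-tumor CNV exclusion regions
#'
#' Intervals removed from a tumor's high-confidence region on copy-number
#' grounds:
#' \itemize{
#'   \item DISCORDANT events where the tumor is \emph{not} copy neutral
#'     over the event interval (|ratio - 1| > `copy_neutral_tol`); a
#'     copy-neutral tumor keeps the interval, since its own short-variant
#'     evidence is unaffected by ambiguous events elsewhere in the cohort.
#'   \item Events carried only by the tumor itself (ambiguous quality).
#'   \item The tumor's homozygous-deletion segments (local ploidy 0: no
#'     short-variant evidence is possible there).
#' }
#'
#' @param tumor tumor sample label.
#' @param events data.frame from [group_cnv_events()].
#' @param segments the full segment data.frame.
#' @param config a [filter_config()].
#' @return a `GRanges` interval set (possibly empty).
#' @export
cnv_exclusion_regions <- function(tumor, events, segments,
                                  config = filter_config()) {
  chrom <- character(); start <- integer(); end <- integer()
  add <- function(c, s, e) {
    chrom <<- c(chrom, c); start <<- c(start, s); end <<- c(end, e)
  }
  if (!is.null(events) && nrow(events)) for (i in seq_len(nrow(events))) {
    carriers <- events$carriers[[i]]
    if (identical(carriers, tumor) ||
        (length(carriers) == 1 && carriers == tumor)) {
      add(events$chrom[i], events$start[i], events$end[i])
    } else if (events$concordance[i] == "DISCORDANT") {
      r <- mean_ratio_over(segments, tumor, events$chrom[i],
                           events$start[i], events$end[i])
      if (abs(r - 1) > config$copy_neutral_tol)
        add(events$chrom[i], events$start[i], events$end[i])
    }
  }
  if (!is.null(segments) && nrow(segments)) {
    hd <- segments[segments$sample == tumor &
                     floor(2 * segments$copy_ratio + 0.5) < 1, , drop = FALSE]
    if (nrow(hd)) add(hd$chrom, hd$start, hd$end)
  }
  interval_set(chrom, start, end)
}
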