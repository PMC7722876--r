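#' Simulation configuration
#'
#' Parameters of a simulated lineage-sequencing experiment. Defaults
#' emulate the study conditions the pipeline targets: 11 leaves sequenced
#' to 35x, mutations accumulating along every branch of a binary division
#' tree (Poisson per branch), a small fraction of branch variants turned
#' homozygous by later loss of heterozygosity, and per-leaf private
#' (subclonal) mutations at arbitrary allele fractions from the clone
#' expansion. Genome size is kept to a few hundred kilobases so a full
#' experiment simulates in seconds; all rates are per-base or per-branch,
#' so nothing else depends on the genome size.
#'
#' @param n_leaves number of leaf samples (default 11).
#' @param newick optional fixed topology; random binary tree otherwise.
#' @param contig_lengths named integer vector of contig sizes (the callable
#'   genome).
#' @param n_germline germline variants, carried by every leaf (default 300).
#' @param branch_rate Poisson mean of mutations per internal branch
#'   (default 50).
#' @param n_private private/subclonal mutations per leaf (default 10).
#' @param private_af_range allele-fraction range of private mutations
#'   (uniform; default 0.05-0.5).
#' @param loh_fraction fraction of germline/branch variants made homozygous
#'   by a later LOH (default 0.05).
#' @param indel_fraction fraction of variants simulated as short indels
#'   (default 0.1).
#' @param cnv_events optional data.frame(chrom, start, end, copy_ratio,
#'   carriers) with carriers a ";"-separated label string; 0-based
#'   half-open.
#' @param depth mean sequencing depth (default 35).
#' @param gq genotype quality assigned to clean calls (default 99).
#' @param pass_prob probability a simulated pairwise somatic call passes the
#'   caller's filters (default 1).
#' @param false_call_rate per-base probability of an artifact call per
#'   sample (default 0).
#' @param drop_call_rate per-genotype no-call probability (default 0).
#' @param gq_jitter Poisson mean subtracted from GQ as noise (default 0).
#' @param seed master seed; all stages derive substreams from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 11L, newick = NULL,
                       contig_lengths = c(chr1 = 400000L, chr2 = 200000L),
                       n_germline = 300L, branch_rate = 50,
                       n_private = 10L, private_af_range = c(0.05, 0.5),
                       loh_fraction = 0.05, indel_fraction = 0.1,
                       cnv_events = NULL, depth = 35L, gq = 99L,
                       pass_prob = 1, false_call_rate = 0,
                       drop_call_rate = 0, gq_jitter = 0, seed = 1L) {
  stopifnot(n_leaves >= 3, n_germline >= 0, branch_rate >= 0,
            n_private >= 0, depth > 0, gq >= 0,
            loh_fraction >= 0, loh_fraction <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            pass_prob >= 0, pass_prob <= 1,
            false_call_rate >= 0, false_call_rate <= 1,
            drop_call_rate >= 0, drop_call_rate <= 1,
            length(private_af_range) == 2,
            all(private_af_range > 0), all(private_af_range <= 1))
  if (is.null(names(contig_lengths)))
    stop("contig_lengths must be named")
  structure(as.list(environment()), class = "sim_config")
}

#' Random rooted binary lineage tree
#'
#' Uniform recursive splits: the leaf set is partitioned at every node into
#' two non-empty random halves, matching a division tree's structure. Leaf
#' labels default to L01..Ln.
#'
#' @param n_leaves number of leaves.
#' @param labels optional leaf labels.
#' @return a [lineage_tree()].
#' @export
random_lineage_tree <- function(n_leaves, labels = NULL) {
  if (is.null(labels))
    labels <- sprintf("L%02d", seq_len(n_leaves))
  stopifnot(length(labels) == n_leaves, n_leaves >= 2)
  split_rec <- function(lv) {
    if (length(lv) == 1) return(lv)
    if (length(lv) == 2) return(paste0("(", lv[1], ",", lv[2], ")"))
    k <- sample(seq_len(length(lv) - 1L), 1L)
    pick <- sample(seq_along(lv), k)
    paste0("(", split_rec(lv[pick]), ",", split_rec(lv[-pick]), ")")
  }
  lineage_tree(paste0(split_rec(sample(labels)), ";"))
}

offset_to_pos <- function(offsets, contig_lengths) {
  ends <- cumsum(as.numeric(contig_lengths))
  idx <- findInterval(offsets - 1, c(0, ends), rightmost.closed = TRUE)
  data.frame(chrom = names(contig_lengths)[idx],
             pos = as.integer(offsets - c(0, ends)[idx]),
             stringsAsFactors = FALSE)
}

random_alleles <- function(m, indel_fraction) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  is_indel <- stats::runif(m) < indel_fraction
  for (i in which(is_indel)) {
    k <- sample(1:3, 1L)
    ins <- stats::runif(1) < 0.5
    extra <- paste(sample(bases, k, replace = TRUE), collapse = "")
    if (ins) alt[i] <- paste0(ref[i], extra)
    else { ref[i] <- paste0(ref[i], extra); alt[i] <- substr(ref[i], 1, 1) }
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

segments_from_events <- function(cnv_events) {
  if (is.null(cnv_events) || !nrow(cnv_events)) return(NULL)
  rows <- lapply(seq_len(nrow(cnv_events)), function(i) {
    carriers <- strsplit(cnv_events$carriers[i], ";")[[1]]
    data.frame(sample = carriers, chrom = cnv_events$chrom[i],
               start = cnv_events$start[i], end = cnv_events$end[i],
               copy_ratio = cnv_events$copy_ratio[i],
               call = if (cnv_events$copy_ratio[i] > 1) "AMP" else "DEL",
               stringsAsFactors = FALSE)
  })
  validate_cnv_segments(do.call(rbind, rows))
}

#' Simulate a lineage-sequencing experiment
#'
#' Generates a full experiment with ground-truth labels: a binary lineage
#' tree, germline variants in all leaves, Poisson branch mutations carried
#' by each internal clade (heterozygous, alt depth drawn from
#' Binomial(depth, 1/ploidy) at the carrier's local ploidy; a configured
#' fraction turned homozygous by LOH), per-leaf private mutations at
#' subclonal allele fractions, CNV segments, and per-ordered-pair somatic
#' calls (a site is called in a tumor-normal run when the tumor carries it
#' and the normal does not; PASS status is Bernoulli(pass_prob)). The same
#' seed reproduces the experiment exactly.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_experiment`: tree, joint ([joint_calls()]),
#'   pairs (named list of [pairwise_calls()], names "tumor|normal"),
#'   segments, callable (`GRanges`), labels (ground-truth data.frame),
#'   config.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  set.seed(seeds[1])
  tree <- if (is.null(config$newick)) random_lineage_tree(config$n_leaves)
          else lineage_tree(config$newick)
  leaves <- sort(tree_leaves(tree))
  if (length(leaves) != config$n_leaves)
    stop("newick leaf count != n_leaves")
  n <- length(leaves)
  segments <- segments_from_events(config$cnv_events)
  if (!is.null(segments)) {
    bad <- setdiff(unique(segments$sample), leaves)
    if (length(bad)) stop("CNV carriers not in tree: ",
                          paste(bad, collapse = ", "))
  }

  set.seed(seeds[2])
  clades <- clade_subsets(tree)
  n_branch <- stats::rpois(length(clades), config$branch_rate)
  m <- config$n_germline + sum(n_branch) + n * config$n_private
  genome <- sum(as.numeric(config$contig_lengths))
  if (m * 10 > genome)
    stop("genome too small for ", m, " variants")
  offs <- sample(seq(5, genome - 5), m)
  loci <- cbind(offset_to_pos(offs, config$contig_lengths),
                random_alleles(m, config$indel_fraction))

  carrier_sets <- c(
    rep(list(leaves), config$n_germline),
    rep(unname(clades), n_branch),
    rep(as.list(leaves), each = config$n_private))
  class_lab <- c(rep("GERMLINE", config$n_germline),
                 rep("GOOD_BRANCH", sum(n_branch)),
                 rep("LEAF", n * config$n_private))
  clade_lab <- c(rep(NA_character_, config$n_germline),
                 rep(names(clades), n_branch),
                 rep(NA_character_, n * config$n_private))

  gt <- matrix("HOM_REF", m, n, dimnames = list(NULL, leaves))
  ad_alt <- matrix(0L, m, n); ad_ref <- matrix(0L, m, n)
  dp <- matrix(as.integer(config$depth), m, n)
  gq <- matrix(as.integer(config$gq), m, n)
  af <- rep(NA_real_, m)

  for (i in seq_len(m)) {
    cs <- carrier_sets[[i]]
    is_leafvar <- class_lab[i] == "LEAF"
    hom <- !is_leafvar && stats::runif(1) < config$loh_fraction
    site_af <- if (is_leafvar)
      stats::runif(1, config$private_af_range[1], config$private_af_range[2])
    else NA_real_
    af[i] <- site_af
    for (s in cs) {
      j <- match(s, leaves)
      d <- as.integer(config$depth)
      if (hom) {
        gt[i, j] <- "HOM_VAR"; ad_alt[i, j] <- d; ad_ref[i, j] <- 0L
      } else {
        gt[i, j] <- "HET"
        p <- if (is_leafvar) site_af else {
          pl <- ploidy_at(segments, s, loci$chrom[i], loci$pos[i])
          if (pl >= 1) 1 / pl else 0.5
        }
        a <- stats::rbinom(1L, d, p)
        ad_alt[i, j] <- a; ad_ref[i, j] <- d - a
      }
    }
    nc <- setdiff(leaves, cs)
    ad_ref[i, match(nc, leaves)] <- as.integer(config$depth)
  }

  sites <- data.frame(chrom = loci$chrom, pos = loci$pos, ref = loci$ref,
                      alt = loci$alt, pass = TRUE, stringsAsFactors = FALSE)
  ## positions are sampled distinct as offsets, but indel refs could collide
  ## after normalization only if positions coincide -- they cannot
  joint <- joint_calls(leaves, sites, gt, gq, ad_ref, ad_alt, dp)
  labels <- data.frame(sites[, c("chrom", "pos", "ref", "alt")],
                       class = class_lab, clade = clade_lab,
                       carriers = vapply(carrier_sets, paste, "",
                                         collapse = ","),
                       af = af, origin = "planted", stringsAsFactors = FALSE)

  set.seed(seeds[3])
  pairs <- simulate_pairwise(joint, config$pass_prob)

  callable <- interval_set(names(config$contig_lengths),
                           rep(0L, length(config$contig_lengths)),
                           as.integer(config$contig_lengths))
  structure(list(tree = tree, joint = joint, pairs = pairs,
                 segments = segments, callable = callable, labels = labels,
                 config = config),
            class = "sim_experiment")
}

#' Simulate pairwise somatic caller output from joint genotypes
#'
#' A site is called in an ordered (tumor, normal) run when the tumor
#' carries the alt allele and the normal does not (no-calls in the normal
#' count as not carrying, mimicking a caller's loss of the germline
#' evidence). Each called site passes the caller's filters with probability
#' `pass_prob`.
#'
#' @param joint a [joint_calls()] object.
#' @param pass_prob Bernoulli PASS probability.
#' @return named list of [pairwise_calls()], names "tumor|normal".
#' @export
simulate_pairwise <- function(joint, pass_prob = 1) {
  leaves <- joint$samples
  carrier <- joint$gt == "HET" | joint$gt == "HOM_VAR"
  pairs <- list()
  for (t in leaves) for (nn in leaves) {
    if (t == nn) next
    idx <- which(carrier[, t] & !carrier[, nn])
    status <- ifelse(stats::runif(length(idx)) < pass_prob,
                     "PASS", "FILTERED")
    pairs[[paste(t, nn, sep = "|")]] <- pairwise_calls(
      t, nn, cbind(joint$sites[idx, c("chrom", "pos", "ref", "alt"),
                               drop = FALSE],
                   data.frame(status = status, stringsAsFactors = FALSE)))
  }
  pairs
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", length(x$joint$samples), "leaves,",
      n_sites(x$joint), "sites,", length(x$pairs), "pairwise runs\n")
  invisible(x)
}

#' Corrupt a simulated experiment with call noise
#'
#' Adds per-sample artifact calls at new random sites (these become Leaf
#' Variant artifacts), adds spurious extra carriers at existing sites
#' (turning clade variants into Bad Branch artifacts), drops genotypes to
#' NO_CALL, and degrades GQ. Ground-truth labels gain artifact rows with
#' `origin = "artifact"` for new sites; planted labels are left untouched
#' so recovery can be measured against them. Pairwise calls are regenerated
#' from the corrupted genotypes. With all rates zero the experiment is
#' returned unchanged.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param false_call_rate per-base artifact probability per sample.
#' @param extra_carrier_rate per-(site, non-carrier sample) probability of
#'   a spurious carrier call at an existing site.
#' @param drop_call_rate per-genotype no-call probability.
#' @param gq_jitter Poisson mean subtracted from GQ.
#' @param seed seed for the noise stream.
#' @return a new `sim_experiment`.
#' @export
corrupt_calls <- function(experiment, false_call_rate = 0,
                          extra_carrier_rate = 0, drop_call_rate = 0,
                          gq_jitter = 0, seed = 1L) {
  stopifnot(inherits(experiment, "sim_experiment"))
  if (false_call_rate == 0 && extra_carrier_rate == 0 &&
      drop_call_rate == 0 && gq_jitter == 0)
    return(experiment)
  set.seed(seed)
  cfg <- experiment$config
  joint <- experiment$joint
  labels <- experiment$labels
  leaves <- joint$samples
  n <- length(leaves)
  genome <- sum(as.numeric(cfg$contig_lengths))

  ## artifact sites
  if (false_call_rate > 0) {
    used <- paste(joint$sites$chrom, joint$sites$pos)
    for (s in leaves) {
      k <- stats::rpois(1, false_call_rate * genome)
      if (!k) next
      offs <- sample(seq(5, genome - 5), k)
      loci <- cbind(offset_to_pos(offs, cfg$contig_lengths),
                    random_alleles(k, cfg$indel_fraction))
      new <- !(paste(loci$chrom, loci$pos) %in% used)
      loci <- loci[new, , drop = FALSE]
      k <- nrow(loci)
      if (!k) next
      used <- c(used, paste(loci$chrom, loci$pos))
      j <- match(s, leaves)
      gt <- matrix("HOM_REF", k, n, dimnames = list(NULL, leaves))
      gt[, j] <- "HET"
      d <- as.integer(cfg$depth)
      a <- stats::rbinom(k, d, stats::runif(k, 0.1, 0.5))
      ad_alt <- matrix(0L, k, n); ad_alt[, j] <- a
      ad_ref <- matrix(d, k, n); ad_ref[, j] <- d - a
      sites <- data.frame(loci[, c("chrom", "pos")],
                          ref = loci$ref, alt = loci$alt, pass = TRUE,
                          stringsAsFactors = FALSE)
      joint <- joint_calls(
        leaves, rbind(joint$sites, sites),
        rbind(joint$gt, gt), rbind(joint$gq, matrix(as.integer(cfg$gq), k, n)),
        rbind(joint$ad_ref, ad_ref), rbind(joint$ad_alt, ad_alt),
        rbind(joint$dp, matrix(d, k, n)))
      labels <- rbind(labels, data.frame(
        sites[, c("chrom", "pos", "ref", "alt")],
        class = "LEAF", clade = NA_character_, carriers = s,
        af = NA_real_, origin = "artifact", stringsAsFactors = FALSE))
    }
  }

  if (extra_carrier_rate > 0) {
    flip <- which(joint$gt == "HOM_REF" &
                    matrix(stats::runif(length(joint$gt)) <
                             extra_carrier_rate, nrow(joint$gt)))
    if (length(flip)) {
      d <- ifelse(is.na(joint$dp[flip]),
                  joint$ad_ref[flip] + joint$ad_alt[flip], joint$dp[flip])
      a <- stats::rbinom(length(flip), d,
                         stats::runif(length(flip), 0.1, 0.5))
      joint$gt[flip] <- "HET"
      joint$ad_alt[flip] <- a
      joint$ad_ref[flip] <- d - a
    }
  }

  if (drop_call_rate > 0) {
    drop <- matrix(stats::runif(length(joint$gt)) < drop_call_rate,
                   nrow(joint$gt))
    joint$gt[drop] <- "NO_CALL"
  }
  if (gq_jitter > 0) {
    joint$gq <- matrix(pmax(0L, as.integer(joint$gq) -
                              stats::rpois(length(joint$gq), gq_jitter)),
                       nrow(joint$gq), dimnames = dimnames(joint$gq))
  }

  pairs <- simulate_pairwise(joint, cfg$pass_prob)
  structure(list(tree = experiment$tree, joint = joint, pairs = pairs,
                 segments = experiment$segments,
                 callable = experiment$callable, labels = labels,
                 config = cfg),
            class = "sim_experiment")
}

#' Write a simulated experiment to standard formats
#'
#' Emits tree.nwk (Newick), joint.vcf (multi-sample VCF), pairs/TUMOR__NORMAL.vcf,
#' segments.seg, callable.bed and truth_labels.tsv under `dir`, all readable
#' by the package's own readers.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @param pairs which pairwise runs to write: "all" or a character vector of
#'   "tumor|normal" names (default "all").
#' @return named list of paths.
#' @export
write_experiment <- function(experiment, dir, pairs = "all") {
  stopifnot(inherits(experiment, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "pairs"), showWarnings = FALSE)
  cl <- experiment$config$contig_lengths
  paths <- list(tree = file.path(dir, "tree.nwk"),
                joint = file.path(dir, "joint.vcf"),
                callable = file.path(dir, "callable.bed"),
                labels = file.path(dir, "truth_labels.tsv"))
  write_lineage_tree(experiment$tree, paths$tree)
  write_joint_vcf(experiment$joint, paths$joint, contig_lengths = cl)
  write_bed(experiment$callable, paths$callable)
  utils::write.table(experiment$labels, paths$labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(experiment$segments)) {
    paths$segments <- file.path(dir, "segments.seg")
    write_cnv_segments(experiment$segments, paths$segments)
  }
  sel <- if (identical(pairs, "all")) names(experiment$pairs) else pairs
  paths$pairs <- vapply(sel, function(nm) {
    p <- file.path(dir, "pairs", paste0(gsub("\\|", "__", nm), ".vcf"))
    write_pair_vcf(experiment$pairs[[nm]], p, contig_lengths = cl)
    p
  }, "")
  paths
}
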