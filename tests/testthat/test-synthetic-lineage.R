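test_that("the same seed reproduces an experiment exactly", {
  cfg <- sim_config(n_leaves = 6, seed = 31, n_germline = 10,
                    branch_rate = 5, n_private = 2,
                    contig_lengths = c(chr1 = 100000L))
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$joint, b$joint)
  expect_identical(a$labels, b$labels)
  expect_identical(format(a$tree), format(b$tree))
  expect_identical(lapply(a$pairs, `[[`, "calls"),
                   lapply(b$pairs, `[[`, "calls"))
  ## written artifacts are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(a, d1, pairs = names(a$pairs)[1])
  write_experiment(b, d2, pairs = names(b$pairs)[1])
  for (f in c("tree.nwk", "joint.vcf", "callable.bed", "truth_labels.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  ## a different seed changes the data
  c2 <- simulate_experiment(sim_config(n_leaves = 6, seed = 32,
                                       n_germline = 10, branch_rate = 5,
                                       n_private = 2,
                                       contig_lengths = c(chr1 = 100000L)))
  expect_false(identical(a$joint$sites, c2$joint$sites))
})

test_that("rate-zero configurations plant only what they say", {
  ex <- simulate_experiment(sim_config(
    n_leaves = 5, seed = 2, n_germline = 12, branch_rate = 0, n_private = 0,
    contig_lengths = c(chr1 = 50000L)))
  expect_equal(unique(ex$labels$class), "GERMLINE")
  expect_equal(n_sites(ex$joint), 12)
  ## germline variants are carried by every leaf -> no pairwise calls
  expect_true(all(vapply(ex$pairs, function(p) nrow(p$calls), 1L) == 0))

  ## corrupt with zero rates is the identity
  expect_identical(corrupt_calls(ex), ex)
})

test_that("random lineage trees are valid and carry n-2 clades", {
  set.seed(17)
  for (n in c(3, 5, 9, 11)) {
    tr <- random_lineage_tree(n)
    expect_length(tree_leaves(tr), n)
    expect_length(clade_subsets(tr), n - 2)
  }
})

test_that("planted carrier sets equal observed carriers at zero noise", {
  ex <- small_experiment()
  key <- variant_key(ex$joint$sites$chrom, ex$joint$sites$pos,
                     ex$joint$sites$ref, ex$joint$sites$alt)
  lkey <- variant_key(ex$labels$chrom, ex$labels$pos, ex$labels$ref,
                      ex$labels$alt)
  expect_setequal(key, lkey)
  for (i in seq_len(n_sites(ex$joint))) {
    want <- sort(strsplit(ex$labels$carriers[match(key[i], lkey)], ",")[[1]])
    expect_equal(carrier_set(ex$joint, i), want)
  }
})

test_that("het alt fractions average 1/ploidy within 3 standard errors", {
  cnv <- data.frame(chrom = "chr1", start = 0L, end = 200000L,
                    copy_ratio = 1.5, carriers = "L01;L02",
                    stringsAsFactors = FALSE)
  ex <- simulate_experiment(sim_config(
    n_leaves = 5, seed = 13, n_germline = 400, branch_rate = 0,
    n_private = 0, loh_fraction = 0, cnv_events = cnv, depth = 35L,
    contig_lengths = c(chr1 = 200000L, chr2 = 200000L)))
  for (grp in list(list(sample = "L01", chrom = "chr1", p = 1 / 3),
                   list(sample = "L01", chrom = "chr2", p = 1 / 2),
                   list(sample = "L04", chrom = "chr1", p = 1 / 2))) {
    sel <- ex$joint$sites$chrom == grp$chrom
    af <- ex$joint$ad_alt[sel, grp$sample] / ex$joint$dp[sel, grp$sample]
    se <- sqrt(grp$p * (1 - grp$p) / 35 / sum(sel))
    expect_lt(abs(mean(af) - grp$p), 3 * se)
  }
})

test_that("noise corruption produces the artifact classes the pipeline sees", {
  ex <- small_experiment()
  noisy <- corrupt_calls(ex, false_call_rate = 3e-4, seed = 5)
  art <- noisy$labels[noisy$labels$origin == "artifact", ]
  expect_gt(nrow(art), 0)
  catalog <- validated_truth_variants(noisy$joint, noisy$tree)
  ckey <- variant_key(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  akey <- variant_key(art$chrom, art$pos, art$ref, art$alt)
  got <- catalog$class[match(akey, ckey)]
  ## single-sample artifacts surface as LEAF unless allele balance trips
  expect_true(all(got %in% c("LEAF", "FILTERED")))
  expect_gt(sum(got == "LEAF"), 0)

  ## dropped genotypes knock sites out via the no-call rule
  dropped <- corrupt_calls(ex, drop_call_rate = 0.05, seed = 6)
  cat2 <- validated_truth_variants(dropped$joint, dropped$tree)
  nc_keys <- with(dropped$joint$sites,
                  variant_key(chrom, pos, ref, alt))[
                    rowSums(dropped$joint$gt == "NO_CALL") > 0]
  hit <- variant_key(cat2$chrom, cat2$pos, cat2$ref, cat2$alt) %in% nc_keys
  expect_gt(sum(hit), 0)
  expect_true(all(cat2$class[hit] == "FILTERED"))
  expect_true(all(grepl("^no_call", cat2$filter_reason[hit])))

  ## spurious extra carriers create Bad Branch artifacts
  bad <- corrupt_calls(ex, extra_carrier_rate = 0.1, seed = 8)
  cat3 <- validated_truth_variants(bad$joint, bad$tree)
  expect_gt(sum(cat3$class == "BAD_BRANCH"), 0)
})

test_that("infeasible configurations error out", {
  expect_error(simulate_experiment(sim_config(
    n_leaves = 5, seed = 1, cnv_events = data.frame(
      chrom = "chr1", start = 0L, end = 1000L, copy_ratio = 1.5,
      carriers = "NOPE"))), "not in tree")
  expect_error(sim_config(n_leaves = 5, false_call_rate = 2), "false_call_rate")
  expect_error(simulate_experiment(sim_config(
    n_leaves = 5, n_germline = 100000L,
    contig_lengths = c(chr1 = 1000L))), "genome too small")
})

test_that("a written experiment is consumable by the package readers", {
  ex <- small_experiment()
  d <- withr::local_tempdir()
  paths <- write_experiment(ex, d, pairs = names(ex$pairs)[1:2])
  tr <- read_lineage_tree(paths$tree)
  expect_equal(sort(tree_leaves(tr)), sort(tree_leaves(ex$tree)))
  jc <- read_joint_calls(paths$joint, samples = ex$joint$samples)
  expect_equal(n_sites(jc), n_sites(ex$joint))
  expect_equal(as_bed_frame(read_bed(paths$callable)),
               as_bed_frame(ex$callable))
  nm <- names(ex$pairs)[1]
  tn <- strsplit(nm, "|", fixed = TRUE)[[1]]
  pc <- read_pairwise_somatic(paths$pairs[[nm]], tn[1], tn[2])
  expect_equal(nrow(pc$calls), nrow(ex$pairs[[nm]]$calls))
})
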