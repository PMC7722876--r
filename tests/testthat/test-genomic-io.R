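test_that("variant normalization trims to minimal representation", {
  n <- normalize_variants(c("chr1", "chr1", "chr1", "chr1"),
                          c(100, 100, 100, 100),
                          c("A", "ATT", "CAG", "GCGC"),
                          c("T", "A", "CG", "GCTC"))
  expect_equal(n$ref, c("A", "ATT", "CA", "G"))
  expect_equal(n$alt, c("T", "A", "C", "T"))
  expect_equal(n$pos, c(100L, 100L, 100L, 102L))

  expect_error(normalize_variants("chr1", 5, "A", "<DEL>"), "symbolic|ACGT")
})

test_that("joint VCF write -> read is identity", {
  ex <- small_experiment()
  p <- withr::local_tempfile(fileext = ".vcf")
  write_joint_vcf(ex$joint, p, contig_lengths = ex$config$contig_lengths)
  back <- read_joint_calls(p, samples = ex$joint$samples)

  o1 <- order(ex$joint$sites$chrom, ex$joint$sites$pos)
  expect_equal(back$sites, ex$joint$sites[o1, ], ignore_attr = TRUE)
  expect_equal(back$gt, ex$joint$gt[o1, ])
  expect_equal(back$gq, ex$joint$gq[o1, ])
  expect_equal(back$ad_alt, ex$joint$ad_alt[o1, ])
  expect_equal(back$dp, ex$joint$dp[o1, ])
})

test_that("multi-allelic records split into per-alt biallelic sites", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tX\tY\tZ",
    "chr1\t50\t.\tG\tA,T\t.\tPASS\t.\tGT:AD:DP:GQ\t1/2:5,15,15:35:80\t0/1:20,15,0:35:99\t0/0:35,0,0:35:99"
  ), p)
  jc <- read_joint_calls(p)
  expect_equal(n_sites(jc), 2)
  expect_equal(jc$sites$alt, c("A", "T"))
  expect_equal(jc$sites$pos, c(50L, 50L))
  ## sample X is 1/2: het for each alt; Y het for alt A only
  expect_equal(unname(jc$gt[, "X"]), c("HET", "HET"))
  expect_equal(unname(jc$gt[, "Y"]), c("HET", "HOM_REF"))
  expect_equal(unname(jc$ad_alt[, "X"]), c(15L, 15L))
})

test_that("missing FORMAT fields and sample mismatches are errors", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tX",
    "chr1\t50\t.\tG\tA\t.\tPASS\t.\tGT\t0/1"), p)
  expect_error(read_joint_calls(p), "AD")

  ex <- small_experiment()
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_joint_vcf(ex$joint, p2)
  expect_error(read_joint_calls(p2, samples = c("L01", "L02")),
               "sample set")
})

test_that("pairwise somatic VCF round trip keeps FILTER status", {
  ex <- small_experiment()
  pc <- ex$pairs[[1]]
  pc$calls$status[1] <- "FILTERED"
  p <- withr::local_tempfile(fileext = ".vcf")
  write_pair_vcf(pc, p)
  back <- read_pairwise_somatic(p, pc$tumor, pc$normal)
  o <- order(pc$calls$chrom, pc$calls$pos, pc$calls$ref, pc$calls$alt)
  expect_equal(back$calls, pc$calls[o, ], ignore_attr = TRUE)
  expect_equal(back$tumor, pc$tumor)
})

test_that("SEG reading converts coordinates and rejects overlaps", {
  p <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tcopy_ratio\tcall",
               "S1\tchr1\t1\t1000\t1.0\tNEUTRAL",
               "S1\tchr1\t2001\t3000\t1.5\tAMP",
               "S2\tchr2\t501\t800\t0.1\tDEL"), p)
  seg <- read_cnv_segments(p)
  expect_equal(seg$start, c(0L, 2000L, 500L))
  expect_equal(seg$end, c(1000L, 3000L, 800L))
  seg0 <- read_cnv_segments(p, one_based = FALSE)
  expect_equal(seg0$start[1], 1L)

  p2 <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tcopy_ratio\tcall",
               "S1\tchr1\t1\t1000\t1.5\tAMP",
               "S1\tchr1\t500\t1500\t1.5\tAMP"), p2)
  expect_error(read_cnv_segments(p2), "overlap")
})

test_that("interval algebra matches worked examples", {
  a <- interval_set("chr1", 0, 100)
  b <- interval_set("chr1", 10, 20)
  d <- interval_subtract(a, b)
  expect_equal(as_bed_frame(d),
               data.frame(chrom = "chr1", start = c(0L, 20L),
                          end = c(10L, 100L)))
  expect_equal(interval_size(d), 90)
  expect_equal(as_bed_frame(interval_subtract(a, interval_set())),
               as_bed_frame(a))
})

test_that("interval algebra agrees with a per-base bitmap oracle", {
  set.seed(99)
  for (rep in 1:20) {
    fa <- random_interval_frame(6); fb <- random_interval_frame(6)
    a <- interval_set(fa$chrom, fa$start, fa$end)
    b <- interval_set(fb$chrom, fb$start, fb$end)
    ba <- bitmap_from_frame(fa); bb <- bitmap_from_frame(fb)

    expect_equal(interval_size(interval_subtract(a, b)), sum(ba & !bb))
    expect_equal(interval_size(interval_intersect(a, b)), sum(ba & bb))
    expect_equal(interval_size(interval_union(a, b)), sum(ba | bb))
    ## conservation: size(a \ b) = size(a) - size(a n b)
    expect_equal(interval_size(interval_subtract(a, b)),
                 interval_size(a) - interval_size(interval_intersect(a, b)))
    ## membership oracle per base
    dsub <- as_bed_frame(interval_subtract(a, b))
    expect_equal(bitmap_from_frame(dsub), ba & !bb)
  }
})

test_that("BED round trip preserves 0-based half-open coordinates", {
  x <- interval_set(c("chr1", "chr2"), c(0, 500), c(150, 700))
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, p)
  raw <- read.delim(p, header = FALSE)
  expect_equal(raw$V2, c(0L, 500L))
  expect_equal(as_bed_frame(read_bed(p)), as_bed_frame(x))
})
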