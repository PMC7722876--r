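eval_fixture <- function() {
  ex <- small_experiment()
  catalog <- validated_truth_variants(ex$joint, ex$tree)
  lv <- leaf_variant_sites(consolidate_all(ex))
  t <- ex$joint$samples[1]
  others <- setdiff(ex$joint$samples, t)
  ## pick a non-sister normal with positives
  for (n in others) {
    ts <- tryCatch(suppressWarnings(
      build_truth_set(t, n, ex$tree, catalog, lv, callable = ex$callable)),
      error = function(e) NULL)
    if (!is.null(ts) && nrow(ts$positives) > 0) break
  }
  list(ex = ex, catalog = catalog, lv = lv, truth = ts)
}

test_that("query calls partition into TP/FP/ignored exactly once", {
  fx <- eval_fixture()
  ts <- fx$truth
  catalog <- fx$catalog

  ## query = exactly the positives
  cmp <- compare_to_truth(ts$positives, ts)
  expect_equal(sum(cmp$counts$tp), nrow(ts$positives))
  expect_equal(sum(cmp$counts$fp), 0)
  expect_equal(sum(cmp$counts$fn), 0)
  expect_equal(sum(cmp$counts$ignored), 0)

  ## a germline site in-region is a false positive
  germ <- catalog[catalog$class == "GERMLINE", ][1, ]
  cmp2 <- compare_to_truth(
    rbind(ts$positives[, c("chrom", "pos", "ref", "alt")],
          germ[, c("chrom", "pos", "ref", "alt")]), ts)
  expect_equal(sum(cmp2$counts$fp), 1)

  ## a call at an excluded leaf site is ignored
  lv_t <- fx$lv[[ts$tumor]]
  if (nrow(lv_t)) {
    cmp3 <- compare_to_truth(lv_t[1, ], ts)
    expect_equal(sum(cmp3$counts$ignored), 1)
    expect_equal(sum(cmp3$counts$fp), 0)
  }

  ## every query call lands in exactly one bin
  q <- rbind(ts$positives[, c("chrom", "pos", "ref", "alt")],
             germ[, c("chrom", "pos", "ref", "alt")])
  cmp4 <- compare_to_truth(q, ts)
  expect_equal(sum(cmp4$counts$tp + cmp4$counts$fp + cmp4$counts$ignored),
               nrow(q))

  expect_error(compare_to_truth(
    data.frame(chrom = "chrZ", pos = 1, ref = "A", alt = "T"), ts),
    "absent from the region")
})

test_that("missed positives count as false negatives per variant type", {
  fx <- eval_fixture()
  ts <- fx$truth
  p <- ts$positives
  miss <- p[1, ]
  cmp <- compare_to_truth(p[-1, ], ts)
  ty <- if (nchar(miss$ref) != nchar(miss$alt)) "indel" else "snv"
  expect_equal(cmp$counts$fn[cmp$counts$variant_type == ty], 1)
  expect_equal(sum(cmp$counts$tp) + sum(cmp$counts$fn), nrow(p))
})

test_that("Clopper-Pearson bounds match tail-search and binom.test oracles", {
  cases <- list(c(10, 0), c(0, 10), c(5, 5), c(17, 3), c(1, 29))
  for (cs in cases) {
    tp <- cs[1]; fn <- cs[2]
    ci <- sensitivity_ci(tp, fn)
    expect_equal(ci$estimate, tp / (tp + fn))
    bt <- binom.test(tp, tp + fn)$conf.int
    expect_equal(ci$lower, bt[1], tolerance = 1e-8)
    expect_equal(ci$upper, bt[2], tolerance = 1e-8)
    oc <- oracle_clopper_pearson(tp, tp + fn)
    expect_lt(abs(ci$lower - oc["lower"]), 2e-5)  # search grid resolution
    expect_lt(abs(ci$upper - oc["upper"]), 2e-5)
    expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  }
  expect_equal(sensitivity_ci(10, 0)$upper, 1)
  expect_equal(sensitivity_ci(0, 10)$lower, 0)
  expect_error(sensitivity_ci(0, 0), "undefined")
})

test_that("FPR interval is the clipped normal approximation per megabase", {
  f0 <- fpr_ci(0, 1e6)
  expect_equal(f0$rate_per_mb, 0)
  expect_equal(f0$lower, 0)

  f <- fpr_ci(100, 1e9)
  p <- 100 / 1e9; z <- qnorm(0.975)
  expect_equal(f$rate_per_mb, p * 1e6)
  expect_equal(f$upper, (p + z * sqrt(p * (1 - p) / 1e9)) * 1e6)
  ## close to the exact (Clopper-Pearson) interval at these counts
  exact <- c(qbeta(0.025, 100, 1e9 - 99), qbeta(0.975, 101, 1e9 - 100)) * 1e6
  expect_lt(abs((f$upper - f$lower) - (exact[2] - exact[1])) /
              (exact[2] - exact[1]), 0.10)

  ## width scales as 1/sqrt(bases) at fixed rate
  w1 <- with(fpr_ci(100, 1e8), upper - lower)
  w2 <- with(fpr_ci(400, 4e8), upper - lower)
  expect_equal(w2 / w1, 0.5, tolerance = 1e-6)
})

test_that("shrinking the region never increases the FP count", {
  fx <- eval_fixture()
  ts <- fx$truth
  germ <- fx$catalog[fx$catalog$class == "GERMLINE",
                     c("chrom", "pos", "ref", "alt")]
  q <- rbind(ts$positives[, c("chrom", "pos", "ref", "alt")], germ)
  fp_full <- sum(compare_to_truth(q, ts)$counts$fp)
  ts_small <- ts
  bed <- as_bed_frame(ts$region)
  bed$end <- bed$start + floor((bed$end - bed$start) / 2)
  bed <- bed[bed$end > bed$start, ]
  ts_small$region <- interval_set(bed$chrom, bed$start, bed$end)
  fp_small <- sum(compare_to_truth(q, ts_small)$counts$fp)
  expect_lte(fp_small, fp_full)
})

test_that("synthetic caller sensitivity lands inside its own CI (coverage)", {
  fx <- eval_fixture()
  ts <- fx$truth
  p <- ts$positives
  expect_gte(nrow(p), 5)
  q_miss <- 0.2
  set.seed(123)
  cover <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    keep <- runif(nrow(p)) > q_miss
    cmp <- compare_to_truth(p[keep, , drop = FALSE], ts)
    ci <- sensitivity_ci(sum(cmp$counts$tp), sum(cmp$counts$fn))
    if (ci$lower <= 1 - q_miss && 1 - q_miss <= ci$upper) cover <- cover + 1L
  }
  expect_gte(cover / reps, 0.9)
})

test_that("evaluate_calls assembles the report with metadata", {
  fx <- eval_fixture()
  ts <- fx$truth
  rep <- evaluate_calls(ts$positives, ts, purity = 0.2)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$variant_type, c("snv", "indel"))
  expect_equal(rep$purity, c(0.2, 0.2))
  expect_equal(rep$region_bases, rep(interval_size(ts$region), 2))
  got_sens <- rep$sensitivity[rep$tp + rep$fn > 0]
  expect_true(all(got_sens == 1))
})
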