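# lineagetruth

Lineage-validated somatic truth sets for benchmarking variant callers.

## The problem

Benchmarking somatic SNV/indel callers needs truth data: a list of sites
that are genuinely somatic in a tumor-normal pair, and a region of the
genome inside which every other call can be judged a false positive.
Simulated truth sets miss the biology of real mutagenesis; germline-based
proxies force callers to disable their germline filtering; per-site
validation does not scale.

A recorded cell lineage solves this. When a single founder cell is observed
dividing under a microscope for several generations and clones grown from
the terminal cells ("leaves") are whole-genome sequenced, the division tree
is *known*. A real somatic mutation that arose on a branch of that tree must
be present in exactly the leaves below that branch — a clade — and in no
others. Concordance with the tree therefore validates mutations without any
orthogonal assay, at whole-genome scale.

This package implements that validation pipeline for any such experiment
(the shipped 11-leaf fixture tree mirrors a lineage-sequenced colon-cancer
cell line), plus a seeded simulator so the whole pipeline is testable with
no external data.

## What it computes

Variants from a joint-genotyped multi-sample VCF are filtered and
classified by carrier set over the `n` leaves:

* **site filters** — upstream FILTER column, any-sample no-call, any-sample
  GQ < 25, and a ploidy-aware allele-balance test: a heterozygous carrier
  with alt depth below the 1% quantile of `Binomial(depth, 1/ploidy)`
  (ploidy = `round(2 × copy ratio)` from per-sample CNV segments) is
  suspect; the site fails when more than half of the het carriers are.
* **classification** — `GERMLINE` (all leaves), `LEAF` (one leaf),
  `GOOD_BRANCH` (carriers form a clade: the validated somatic variants),
  `BAD_BRANCH` (carriers form no clade: artifacts kept in-region as decoys).
* **leaf consolidation** — each sample's n−1 pairwise somatic runs are
  consolidated (strict majority of passing calls, with an all-runs-called
  exception) and sites unique to one sample become its Leaf Variants.
* **truth set per ordered (tumor, mixed-in normal)** — positives are
  GOOD_BRANCH variants carried by the tumor but not the normal; the
  high-confidence region is the callable genome minus both samples' Leaf
  Variant footprints and the tumor's discordant/tumor-only CNV regions.
* **mixture planning** — all usable ordered assignments (sisters and
  empty-truth directions excluded; 98 on the 11-leaf fixture) crossed with
  purities, with downsampling fractions `f_t = αD/d_t`,
  `f_n = (1−α)D/d_n` and expected allele fractions
  `αm / (αCN_t + (1−α)CN_n)`.
* **evaluation** — TP/FP/FN/ignored per variant type, sensitivity with
  exact Clopper–Pearson 95% CIs, FPR per megabase with asymptotic normal
  CIs, plus a Wilcoxon rank-sum check (with continuity correction and
  Hodges–Lehmann shift) that variant counts concentrate on tree-consistent
  carrier subsets.

## Worked example

```r
library(lineagetruth)

tr <- ht115_tree()                       # 11 leaves, 10 internal nodes
length(clade_subsets(tr))                # 9 tree-consistent subsets
nrow(enumerate_mixtures(tr, c(0.1, 0.2, 0.5)))   # 294 mixtures

## simulate a full experiment on that topology
ex <- simulate_experiment(sim_config(seed = 11, newick = format(tr),
                                     n_germline = 100, branch_rate = 50,
                                     n_private = 5))
catalog <- validated_truth_variants(ex$joint, ex$tree, ex$segments)
table(catalog$class)
#>    FILTERED    GERMLINE GOOD_BRANCH        LEAF
#>          28         100         450          27

## consolidate pairwise runs and build one truth set
leaves <- ex$joint$samples
cons <- lapply(leaves, function(s)
  consolidate_sample_calls(s, ex$pairs[startsWith(names(ex$pairs),
                                                  paste0(s, "|"))],
                           length(leaves)))
names(cons) <- leaves
lv <- leaf_variant_sites(cons)
ts <- build_truth_set("S57", "S44", ex$tree, catalog, lv,
                      callable = ex$callable)
ts
#> truth_set: tumor S57 / mixed-in normal S44 / matched normal S34
#>   positives: 103 | region: 599,988 bases of 6e+05 callable

## score a synthetic caller that misses 10% of the positives
set.seed(1)
query <- ts$positives[runif(nrow(ts$positives)) > 0.1, ]
evaluate_calls(query, ts, purity = 0.2)
#>   variant_type tp fp fn ignored sensitivity sens_lower sens_upper fpr_per_mb
#> 1          snv 85  0  6       0       0.934      0.862      0.975          0
#> 2        indel 11  0  1       0       0.917      0.615      0.998          0
```

The 103 positives are exactly the planted clade mutations carried by S57
but not S44; the region is the 600 kb simulated callable genome minus the
two samples' Leaf Variant footprints. The sensitivity point estimates sit
inside their exact 95% intervals, and with no spurious calls the FPR is 0
per megabase.

A thin CLI over the same functions lives at `inst/cli/lineage-truth.R`
(subcommands `simulate`, `plan`, `build-truth`, `evaluate`).

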