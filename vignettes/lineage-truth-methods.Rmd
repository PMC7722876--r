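---
title: "Methods: building somatic truth sets from a known cell lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building somatic truth sets from a known cell lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagetruth)
```

## The model

A lineage-sequencing experiment observes one founder cell dividing for
several generations; each terminal cell is expanded into a clone and
whole-genome sequenced. The division history is therefore a *known* rooted
strictly binary tree whose leaves are the sequenced samples. Every somatic
mutation that arose on a branch of this tree passed through a single-cell
bottleneck, which has two consequences the whole pipeline rests on:

1. **Carrier sets are clades.** A branch mutation is present in exactly the
   leaves below the branch. A candidate variant whose carriers match a
   clade is validated (`GOOD_BRANCH`); one whose carriers match no clade
   cannot be a single branch mutation (`BAD_BRANCH`). Variants in all
   leaves are germline or pre-tree (`GERMLINE`); variants in a single leaf
   are post-tree mutations or artifacts and are inherently ambiguous
   (`LEAF`).
2. **Allele balance is constrained.** A true variant is a clean het or hom
   genotype in every carrier, so in a region of local copy number `ploidy`
   the alt-allele depth of a het carrier is a
   `Binomial(depth, 1/ploidy)` draw. Subclonal artifacts are not so
   constrained.

A truth set for an ordered (tumor, mixed-in normal) assignment is then:
positives = `GOOD_BRANCH` variants carried by the tumor and not by the
normal; high-confidence region = callable genome minus the two samples'
Leaf Variant footprints minus copy-number exclusions. `GERMLINE` and
`BAD_BRANCH` sites deliberately *stay in-region as non-positives*: a
benchmarked caller that reports them is charged a false positive, which
keeps recurrent artifacts and germline leakage inside the benchmark instead
of sweeping them out of scope.

Because sister leaves share every validated variant, the five sister
assignments (in each direction) carry no positives, and any leaf whose
minimal clade is not a cherry (S38 in the shipped fixture) has no positives
against the members of that clade. On the 11-leaf fixture this leaves
`110 − 10 − 2 = 98` usable directed assignments, i.e. 50 usable unordered
pairings, and 294 mixtures at three purities.

## Filter cascade and its parameters

Filters are applied in a fixed order and the first failure is recorded;
since all filters are pure predicates of the site record, the order affects
only the recorded reason, not the verdict.

| parameter | default | meaning |
|---|---|---|
| upstream FILTER | `PASS` required | site-level recalibration verdict from the joint caller, consumed as-is |
| `min_gq` | 25 | any sample with GQ strictly below fails the site |
| no-call rule | always on | any sample without a genotype fails the site |
| `ad_percentile` | 0.01 | lower-tail binomial quantile for the het allele-balance test |
| `ab_denominator` | `"het_carriers"` | what "more than half of the samples" counts over |
| `copy_neutral_tol` | 0.1 | \|copy ratio − 1\| at or below this is copy neutral |
| `reciprocal_overlap` | 0.5 | cross-sample CNV segment grouping threshold |
| `leaf_pad` | 0 bp | padding around excluded Leaf Variant footprints |
| `leaf_majority_denominator` | `"called"` | denominator of the pairwise-consolidation majority |

The allele-balance threshold is the smallest `k` with
`P(Binomial(depth, 1/ploidy) ≤ k) ≥ ad_percentile` — exactly
`qbinom(ad_percentile, depth, 1/ploidy)` — and an observed alt depth fails
when strictly below `k`. Hom-var carriers are exempt (deletion and LOH
regions legitimately produce hom genotypes), and sites with no het carriers
pass. The GQ test is strict (`GQ = 25` passes), matching a "< 25" rule.

Two denominators in the source procedure are ambiguous, and both are
config switches here:

* *"more than half of the samples"* in the allele-balance test: the
  default counts het carriers only, because the binomial test is undefined
  for non-carriers and explicitly waived for hom-var carriers; the
  alternative (`"all_samples"`) counts the full cohort.
* *the consolidation majority* for potential leaf calls: the default
  denominator is the number of runs in which the site was called at all;
  the all-`n−1`-runs-called exception then rescues unanimously called but
  unanimously filtered sites. The alternative (`"total"`) divides by all
  n−1 runs.

## Copy-number handling

Local ploidy is `round(2 × copy ratio)` of the covering per-sample segment
(half rounds up: ratio 1.5 → 3, ratio 2 → 4), default 2 where uncovered.
Non-neutral segments are grouped across samples into events by direction
and reciprocal overlap ≥ 0.5 (single linkage); events are `ALL_SAMPLE`,
`TREE_CONSISTENT` (clade or single leaf) or `DISCORDANT`. A tumor's
high-confidence region loses: discordant event intervals where the tumor is
not copy neutral, events carried only by the tumor, and the tumor's
homozygous-deletion segments (ploidy 0 — no short-variant evidence is
possible, and the binomial test is inapplicable there, which is why such
sites are handled by exclusion rather than by the allele-balance filter).
A copy-neutral tumor keeps discordant intervals: its own short-variant
evidence is unaffected by ambiguous events elsewhere in the cohort.

## Matching and coordinates

Cross-file site identity is normalized `(chrom, pos, ref, alt)`: alleles
are trimmed to minimal representation (shared suffix, then shared prefix,
advancing `pos`). Full left-alignment would need the reference FASTA,
which this package deliberately does not consume; trimming alone resolves
the padding-base differences between joint and somatic caller outputs,
which is the representation drift the pipeline actually encounters.
Symbolic alleles are rejected — the truth set covers short variants only.
VCF positions are 1-based, BED and SEG are held 0-based half-open, and
interval sets are reduced `GRanges`; the SEG reader defaults to the 1-based
inclusive dialect with a flag for 0-based input.

## Statistics

* **Sensitivity** uses the exact Clopper–Pearson interval (beta quantiles:
  lower `qbeta(α/2, tp, fn+1)`, upper `qbeta(1−α/2, tp+1, fn)`, with the
  0 and 1 boundary cases pinned), because per-mixture positive counts are
  small. The test suite cross-checks the bounds against a direct search
  over binomial tail probabilities and against `binom.test`.
* **FPR** per megabase uses the normal approximation
  `p̂ ± z·sqrt(p̂(1−p̂)/bases)` clipped to [0, 1]; with gigabase regions and
  hundreds of false positives the approximation error is far below the
  interval width (asserted against the exact interval in tests).
* **Tree validity** is checked without using the tree as a filter: variants
  passing all quality filters are tallied by exact carrier subset, every
  clade subset is reported (even at count zero), inconsistent subsets enter
  only with ≥ 1 variant, and a Wilcoxon rank-sum test with continuity
  correction (tie-corrected normal approximation; `stats::wilcox.test`)
  compares the two groups, with the Hodges–Lehmann shift and its CI from
  inverting the test. Degenerate all-tied input short-circuits to p = 1,
  shift 0. Region blacklists (e.g. a chromosome lost to a large LOH event)
  and per-site population allele-frequency annotations (> 1% removed by
  default) are generic inputs, not hard-coded.

## The simulator: what it does and does not emulate

`simulate_experiment()` draws a random binary tree (uniform recursive
splits — no result depends on the shape distribution) or accepts a fixed
topology, then plants: germline variants in all leaves; `Poisson(λ)`
mutations per internal branch, het with alt depth `Binomial(depth,
1/ploidy)` at the carrier's local ploidy and a configurable fraction made
hom by later LOH; and per-leaf private mutations at uniform subclonal
allele fractions. Pairwise somatic output is derived by the defining rule —
called where the tumor carries and the normal does not, PASS with
probability `pass_prob`. `corrupt_calls()` adds single-sample artifact
sites, spurious extra carriers at existing sites (the Bad Branch mechanism),
no-calls and GQ degradation. All randomness flows from one master seed
through per-stage substreams, so runs are bit-reproducible.

Defaults mirror the targeted study conditions: 11 leaves, 35× depth,
GQ 99 for clean calls, purities {10%, 20%, 50%} in the planner. Genome
size (600 kb over two contigs) and per-branch rates (λ = 50) are chosen so
a full experiment simulates in seconds while every clade still receives
mutations with overwhelming probability; the suite's end-to-end checks run
at these sizes, with smaller 5–8-leaf experiments for module tests.

What the simulator does *not* model — and hence what passing tests do not
show about real data: read-level errors and mapping artifacts (noise enters
at the call level, not the read level), mutational signatures and context,
correlated artifacts between samples, caller-specific filter behaviour, and
subclonal structure beyond a single allele fraction per private mutation.
Real-data headline quantities (genome-scale region sizes, per-branch
variant counts, the published rank-test statistics) depend on the actual
sequencing experiment and are out of reach of desk-scale simulation; the
package reproduces the *combinatorial* quantities exactly (9 consistent
subsets, 50/98/294 mixtures) and the *behavioural* guarantees by property
tests.

## Design choices made where the design was open

* **Fixture topology.** The published constraints pin only the five sister
  pairs and S38's sibling clade; everything above is arbitrary. The shipped
  Newick fixes one such topology and every packaged combinatorial result
  depends only on the constrained facts.
* **Matched normal.** The closest relative of the mixed-in normal, with a
  lexicographic tie-break when the sibling subtree has several leaves —
  deterministic and documented, since no rule is stated for the unpaired
  leaf. The matched normal's own Leaf Variants are *not* excluded from the
  region (only the tumor's and the mixed-in normal's are).
* **Empty-truth bookkeeping.** Enumeration works per direction; on the
  fixture, the sister exclusions plus the two empty S38-as-tumor directions
  give the same 98 total as booking one unordered pairing, but directions
  are what the planner emits.
* **Depth for the allele-balance test** is the sample's DP, falling back to
  the AD component sum when DP is missing.
* **Monomorphic sites** (no carriers after filters) are dropped silently;
  multi-allelic records are split and each alt classified independently.

## Limitations

The pipeline consumes calls, not reads: it cannot rescue a variant the
joint caller missed, and its notion of "callable" is an input BED (default:
the contigs named in the VCF header), not a coverage computation. Manual
review steps of the original procedure are not reproducible and are not
encoded. The Wilcoxon inversion CI is approximate under heavy ties, which
is inherent to count data; the suite bounds its behaviour against exact
permutation enumeration only at small sizes.
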