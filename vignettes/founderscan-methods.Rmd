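---
title: "founderscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{founderscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderscan)
```

## The problem

Tumors accumulate somatic mutations at very different rates, and in
colorectal cancer a mutation that disables a DNA-repair gene early in a
tumor's life can act as a *founder* event: present in every descendant
cell, and followed by a burst of new mutations that the crippled repair
machinery can no longer prevent. `founderscan` reconstructs this history
from a single bulk-sequencing snapshot per tumor, using only mutation
frequencies.

The chain of reasoning is deliberately simple:

1. A mutation's variant allele frequency (VAF, the fraction of reads
   carrying the mutant allele) is a proxy for its *age*: an early mutation
   is carried by more tumor cells and therefore more reads; later
   subclonal mutations sit at lower frequencies.
2. A founder candidate is a DNA-repair gene mutation with high VAF
   relative to its own sample.
3. If the repair defect really boosted the mutation rate, the bulk of the
   sample's mutations should have arisen shortly *after* the founder — at
   frequencies just below it. The qualifying rule: at least half of the
   subsequent (lower-VAF) mutations must lie in the open window
   `(V_f − 30, V_f)` percentage points.
4. The shape of the sub-founder VAF spectrum records how the expansion
   proceeded: one subclone (single peak), two or more subclones
   (double/multiple peaks), many small subclones (exponential pile-up near
   zero), or no discernible expansion (neutral).

## Data model and filters

The atom is a mutation record: sample, gene, position, alleles, variant
class, total depth, mutant-read depth. VAF is always recomputed as
`100 · alt_depth / total_depth`; records with zero coverage are rejected at
parse time (their frequency is undefined) rather than assigned VAF 0.
Coordinates are 1-based; strand is ignored, since every downstream
statistic needs only mutation identity and read support.

Quality filtering retains records with total depth ≥ 50 and mutant reads
≥ 5. Tumor mutation burden (TMB) is the count of retained records per
sample. Upstream caller-specific filters (e.g. the judgement system of the
variant caller that produced the input) are assumed already applied; this
package never re-calls variants.

Mutation *status* of a sample for a gene or pathway counts **any** variant
class, including silent mutations, because the procedure being reproduced
applies no class filter; `nonsilent_only = TRUE` is available for users who
prefer the modern convention. Both choices are defensible — silent
variants in a repair gene are usually irrelevant to function but equally
usable as clonal markers; the default favors procedural fidelity.

## Statistics

**Burden association.** Samples are split by mutation status and burdens
compared with a two-sided Mann–Whitney U test. For group sizes up to 8 the
null distribution of U is enumerated exhaustively over all assignments of
the pooled ranks — exact even under ties, with two-sided p-value
`min(1, 2·min(P(U ≤ u), P(U ≥ u)))`. Above that, the tie- and
continuity-corrected normal approximation is used, matching the standard
`wilcox.test()` behavior (which the tests use as an independent
cross-check). The reported effect size is the fold increase in median
burden; it is undefined (NA) when the wild-type median is 0, rather than
infinite. No multiple-testing correction is applied to the primary
ranking — raw p-values are what the procedure reports — but a
Benjamini–Hochberg `q_value` column is attached for modern use.

**Co-mutation.** For each unordered pathway pair a 2×2 status table is
built over samples. The odds ratio is the plain cross-product `ad/bc`,
with the Haldane–Anscombe 0.5 correction applied *only when a zero cell
exists* (so clean tables are uncorrected); the p-value is Fisher's exact
test. The test type behind the original pairwise enrichment figures is not
stated in the source material; Fisher is the conventional choice for 2×2
tables of this size.

## Founder calling

`candidate_founders()` requires `VAF ≥ min_founder_vaf` (default 50%) and
`VAF > median(sample VAFs)`. The 50% floor is a configurable interpretation:
the procedure's description says only "high proportion of mutant reads".
Fifty percent is the diploid heterozygous ceiling — anything at or above it
is clonal under this model — and sits safely below the observed founder
VAFs the method is meant to capture. The median condition encodes
"earlier than the bulk" without a second tunable number.

`call_founder()` uses the open window `(V_f − 30, V_f)`. Both endpoints
are open by choice: the source description ("within a 30% frequency range
following the founder") fixes the width but not the endpoint convention,
and excluding `V_f` itself avoids counting mutations tied with the
founder's own clone boundary. `min_subsequent = 10` guards against samples
with too few mutations for the half-in-window fraction to mean anything;
the original analysis notes such patients are unreliable without giving a
number, so the floor is explicit and configurable.

Per sample, qualifying calls are ranked by founder VAF (descending, ties
alphabetical — a deterministic convention) and the top 3 retained.

## Pattern classification

Classification works on the 1%-wide VAF histogram restricted to bins
strictly below the founder VAF and at or above a 5% floor (bins below 5%
are dominated by sequencing-error artifacts at typical depths). Counts are
smoothed with a centered moving average of 5 bins.

The **exponential** check runs first, because an exponential decay also
contains a formal local maximum at its low end: the spectrum is called
exponential when smoothed counts are non-increasing with increasing VAF
across ≥ 60% of adjacent bin pairs *and* the maximum lies in the lowest
quartile of the restricted range. Otherwise local maxima with smoothed
height ≥ `peak_min_fraction · n_mutations` are collected; maxima closer
than 10 bins are merged (visually distinct peaks need a numeric minimum
separation; 10 points is config-exposed). Zero peaks → neutral, one →
single, two or more → double/multiple.

**Why `peak_min_fraction = 0.02`.** Binomial read sampling at ~100× depth
spreads a subclone's VAFs with a standard deviation near 5 points, so even
a perfectly clonal peak puts at most ~8% of its mutations into its tallest
1%-bin. Two equal subclones therefore top out near 3.5% of the sample's
mutations per peak — a 5% threshold could never call a double pattern at
this depth, while 2% still sits well above the per-bin share of a diffuse
(neutral) spectrum spread over ~70 bins (~1.4%). The threshold scales with
the sample's mutation count, so it is depth- and burden-aware but assumes
roughly 100× coverage; at much higher depth a larger value would be
appropriate, which is why it is a parameter.

## The synthetic cohort generator

Each sample receives `Poisson(background)` truncal passenger mutations at
the clonal expectation (VAF `50·purity`), and, with probability
`founder_probability`, one founder record in a repair gene plus
`Poisson(background · boost)` post-founder mutations arranged by pattern.
Depth is negative binomial (mean 100, size 25 — a coefficient of variation
near 22%, typical of exome coverage); mutant reads are binomial at the
expected VAF. Defaults are anchored to the colorectal cohorts this package
is designed around: background 330 (wild-type median burden), boost 8
(within the reported 6–12× range), founder prevalence 0.21, pattern mix
0.352 / 0.216 / 0.144 single/double/exponential with the remainder
diffuse, and a founder gene pool weighted like the five most recurrent
founder genes (PRKDC, ATM, POLE, SRCAP, BRCA2 at 31 : 26 : 18 : 18 : 15).

**Founder VAFs are drawn directly** from `founder_vaf_range = (60, 95)`
rather than derived from a diploid CCF, which would cap them at 50:
observed founders sit well above the heterozygous ceiling because early
truncal events are frequently inflated by copy-number gain or loss of
heterozygosity. The generator does not model copy number explicitly — the
detection method applies no copy-number correction either, so simulating
it would test code the method does not have. For the same reason,
expansion-peak VAFs for single and double patterns are anchored at small
offsets beneath the founder VAF (U(5,25); for double, U(4,8) and U(21,28),
guaranteeing ≥ 10-point peak separation): expansion subclones descend from
the founder clone, so their frequencies trail it closely. Implied subclone
CCFs (peak VAF / founder VAF) are recorded in the truth table. The
exponential pattern piles mass against the low-VAF end
(`5 + Exp(mean 12)`); neutral spreads mutations uniformly below the
founder.

What the generator does **not** emulate: mutational signatures and
sequence context, copy-number segments and purity/ploidy interplay,
sample-specific depth profiles, caller artifacts, or clustered/kataegis
mutations. Passing tests show the detection machinery recovers planted
structure under honest read-sampling noise; they do not show robustness to
the full messiness of real tumor sequencing.

Passenger labels come from a dummy gene pool disjoint from the repair
sets; `repair_contamination` optionally relabels a fraction of passengers
with repair-gene symbols (a realistic value is ~0.009, the fraction of
genes that are repair genes) as a stress test for false founder calls and
for non-trivial gene rankings.

## Survival stage

Everything statistical here is deliberately off-the-shelf: Cox regression
and Kaplan–Meier curves come from the `survival` package; the package
contributes only the median split (samples exactly at the median go to the
*low* group — a deterministic convention), mean-expression signature
scores, tumor/normal fold changes (ratio of means, Mann–Whitney p), and
file orchestration. The split point (median versus an optimized cutoff) is
an assumption; it is the conservative default and configurable by
supplying a recoded expression row. The expression generator draws
log-normal intensities (`sdlog = 0.5` on a chip-normalized scale of mean
1000) and exponential relapse times whose hazard is multiplied by
`hr_true` in the high-expression group, with independent exponential
censoring — exactly the model the median-split Cox fit assumes, which is
what makes it a calibration target rather than a realism claim.

## Determinism and numerical conventions

All simulator randomness flows from a single seed (`params$seed`); the
analysis stages are deterministic. Pipeline outputs are plain TSVs with a
provenance header (package version, MD5 hash of the configuration, seed);
two runs with the same configuration are byte-identical, and different
configurations never share a hash. Ties are always broken alphabetically;
floating-point comparisons in the window and enumeration code use a 1e-9
epsilon so that boundary VAFs behave predictably.

Problem sizes used by the test suite and the acceptance script — 200-sample
cohorts, 20 cohorts for ranking stability, 100 replicate survival cohorts
of 1000 patients — are the package's chosen verification scale: large
enough that the binomial/Poisson tolerances derived above are meaningful,
small enough to run comfortably on a laptop.

## Known limitations

* VAF ordering is a proxy for time; without multi-region or longitudinal
  data the "subsequent mutations" definition is an assumption, and
  copy-number events can reorder apparent ages.
* No subclonal deconvolution is attempted (no mixture models or CCF
  clustering); the pattern classes are histogram heuristics, faithful to
  the method they implement.
* The packaged repair gene sets are curated from the cited KEGG maps and
  close double-strand-break signaling partners; they are versioned but not
  identical to any particular published appendix list.
* The exponential/neutral patterns rarely produce *qualifying* founder
  calls by construction — their subsequent-mutation mass lies far below
  the 30-point window. This mirrors the method itself, where the window
  rule prunes the initial candidate set; recovery of planted founders is
  therefore assessed on the candidate ranking, qualification on the
  single/double expansions.
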