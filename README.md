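# founderscan

Founder-mutation detection and mutation-burden analysis for tumor cohorts.

Colorectal tumors vary enormously in their somatic mutation load, and a
large part of that variation traces back to early ("founder") mutations in
DNA-repair genes: once a repair pathway is crippled, mutations accumulate
at a boosted rate in every descendant cell. `founderscan` is for
bioinformaticians who have a table of somatic mutation calls (MAF, VCF, or
a simple TSV) and want to

* compute per-sample **tumor mutation burden** (TMB) under the standard
  read-support filters (≥50× coverage, ≥5 mutant reads),
* test which repair genes and pathways (BER, NER, MMR, HR, NHEJ) are
  **associated with high burden** (two-sided Mann–Whitney U on the
  mutant/wild-type split) and how often pathways are **co-mutated**
  (Fisher exact test, odds ratios with Haldane–Anscombe correction),
* read each sample's **VAF histogram** as a clonal-expansion record:
  classify it as *neutral*, *single*, *double/multiple*, or *exponential*
  expansion, and
* call **founder mutations**: repair-gene mutations whose variant allele
  frequency (VAF) is high (present in all descendant cells) and such that
  at least half of the subsequent, lower-VAF mutations fall within a
  30-percentage-point frequency window below the founder — the signature of
  a mutation burst that followed the repair defect. Per sample, the top 3
  qualifying genes by VAF are retained.

A synthetic-cohort generator with full per-sample ground truth (planted
founder gene and VAF, expansion pattern, subclone structure, binomial read
sampling at negative-binomial depth) makes every stage verifiable without
access to protected patient data, and a thin survival stage relates
repair-gene expression to relapse-free survival (median-split Cox
regression and Kaplan–Meier curves via the `survival` package).

## The model in brief

For a mutation with `a` mutant reads out of `d` total reads, the mutation
frequency is `VAF = 100·a/d`. Under a diploid heterozygous model a clone at
cancer-cell fraction CCF has expected `VAF = 100·purity·CCF/2`; early
truncal events often exceed the 50% ceiling through copy-number gain or
loss of heterozygosity, which is what makes founders stand out. A founder
candidate in sample *s* is a repair-gene mutation with `VAF ≥ 50` and
`VAF > median(VAF_s)`; it **qualifies** when

```
#{ subsequent mutations with VAF in (V_f − 30, V_f) } ≥ ⌈ n_subsequent / 2 ⌉
```

with `V_f` the founder VAF and "subsequent" meaning all lower-VAF
mutations (lower frequency ⇒ later origin). Burden associations use the
Mann–Whitney U test (exact enumeration for groups ≤ 8, tie- and
continuity-corrected normal approximation above), reported with the fold
increase in median burden `median(TMB_mutant) / median(TMB_wild)`.

## Worked example

```r
library(founderscan)

params  <- simulation_params(n_samples = 60, seed = 42)  # synthetic cohort
sim     <- simulate_cohort(params)
records <- apply_quality_filters(sim$records)            # 50x / 5x policy
profiles <- build_profiles(records, sample_ids = sim$truth$sample_id)
gs      <- load_gene_sets()                              # packaged KEGG-derived sets

head(rank_genes(profiles, gs), 3)
#>   gene_or_pathway p_value median_burden_mutant median_burden_wild fold_increase
#> 1            POLE 0.00668                 2928                330          8.88
#> 2             ATM 0.01458                 2940                330          8.91
#> 3           BRCA2 0.01786                 3053                332          9.20

head(cohort_founder_summary(profiles, gs)$summary, 3)
#>    gene n_samples median_vaf min_vaf max_vaf
#> 1  POLE         3      74.74   74.07   94.06
#> 2   ATM         2      78.23   64.86   91.59
#> 3 PRKDC         2      85.87   83.50   88.24
```

Mutant samples carry ~9× the wild-type median burden (the planted boost is
8×, plus the founder sample's own truncal background), and the founder
summary counts, per gene, the samples whose top-3 qualifying founder calls
include that gene, with the median and range of the founder VAFs.

The survival stage on a simulated expression/relapse cohort (true hazard
ratio 0.72, true tumor/normal fold change 6.44):

```r
s <- simulate_expression_survival(n_patients = 1000, hr_true = 0.72,
                                  fc_tumor_normal = 6.44, seed = 42)
median_split_survival(s$expression, "PRKDC", s$survival)
#> PRKDC: HR (high vs low) 0.71 [0.61-0.84], p = 3.8e-05 (n = 500 high / 500 low)
tumor_normal_fold_change(s$expression, s$normal_expression, "PRKDC")$fold_change
#> 6.78
```

A thin command-line front end ships in `inst/cli/founderscan.R`
(subcommands `simulate`, `burden`, `founder`, `survival`, `all`); every
output table carries a provenance header with the package version, a
configuration hash, and the seed, and reruns are byte-identical.

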