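test_that("VAF histogram bins are half-open with a closed last bin", {
  p <- make_profile(c(50.0, 50.4, 99.9, 100.0))
  h <- vaf_histogram(p, bin_width = 1)
  expect_equal(length(h$counts), 100)
  expect_equal(h$counts[51], 2)  # [50, 51)
  expect_equal(h$counts[100], 2) # [99, 100]
  expect_equal(sum(h$counts), 4)
})

test_that("histogram counts are conserved for any divisor bin width", {
  set.seed(9)
  p <- make_profile(round(runif(400, 0, 100), 1))
  for (bw in c(1, 2, 5, 10)) {
    h <- vaf_histogram(p, bin_width = bw)
    expect_equal(sum(h$counts), 400)
    expect_equal(length(h$counts), 100 / bw)
  }
  expect_error(vaf_histogram(p, bin_width = 3), "divide")
  empty <- build_profiles(make_records("E", "G", 100, 50),
                          sample_ids = c("E", "Z"))$Z
  expect_error(vaf_histogram(empty), "no mutations")
})

test_that("founder candidates are high-VAF repair genes above the sample median", {
  gs <- small_gene_sets()
  # PRKDC at 70 towers over a low-VAF bulk (median 30)
  p <- make_profile(c(70, rep(30, 10), rep(28, 4)),
                    genes = c("PRKDC", sprintf("G%d", 1:14)))
  cand <- candidate_founders(p, gs)
  expect_equal(cand$gene, "PRKDC")
  expect_equal(cand$founder_vaf, 70)
  # below the VAF floor: not a candidate
  p2 <- make_profile(c(45, rep(30, 10)), genes = c("BRCA2", sprintf("G%d", 1:10)))
  expect_equal(nrow(candidate_founders(p2, gs)), 0)
  # non-repair gene at 95: not a candidate
  p3 <- make_profile(c(95, rep(30, 10)), genes = c("MYC", sprintf("G%d", 1:10)))
  expect_equal(nrow(candidate_founders(p3, gs)), 0)
  # at or below the sample median: not a candidate
  p4 <- make_profile(c(60, rep(80, 10)), genes = c("ATM", sprintf("G%d", 1:10)))
  expect_equal(nrow(candidate_founders(p4, gs)), 0)
})

test_that("the 30%-window founder rule matches hand counts", {
  gs <- small_gene_sets()
  p_yes <- make_profile(c(70, 65, 62, 60, 55, 50, 45, 25, 20, 15, 10),
                        genes = c("PRKDC", sprintf("G%d", 1:10)))
  call <- call_founder(p_yes, "PRKDC", 70, classify = FALSE)
  expect_equal(call$n_subsequent, 10)
  expect_equal(call$n_subsequent_in_window, 6)
  expect_true(call$qualifies)
  expect_equal(c(call$window_lo, call$window_hi), c(40, 70))

  p_no <- make_profile(c(70, 65, 62, 60, 35, 30, 25, 20, 15, 10),
                       genes = c("PRKDC", sprintf("G%d", 1:9)))
  call2 <- call_founder(p_no, "PRKDC", 70, classify = FALSE)
  expect_equal(call2$n_subsequent, 9)
  expect_equal(call2$n_subsequent_in_window, 3)
  expect_false(call2$qualifies)

  # no subsequent mutations: degenerate, never qualifies
  p_solo <- make_profile(70, genes = "PRKDC")
  expect_false(call_founder(p_solo, "PRKDC", 70, classify = FALSE)$qualifies)
})

test_that("founder calls are invariant to record order", {
  gs <- small_gene_sets()
  vafs <- c(70, 65, 62, 60, 55, 50, 45, 25, 20, 15, 10)
  genes <- c("PRKDC", sprintf("G%d", 1:10))
  p <- make_profile(vafs, genes)
  set.seed(3)
  ord <- sample(seq_along(vafs))
  p_shuf <- make_profile(vafs[ord], genes[ord])
  c1 <- call_founder(p, "PRKDC", 70, classify = FALSE)
  c2 <- call_founder(p_shuf, "PRKDC", 70, classify = FALSE)
  expect_equal(c1[, -1], c2[, -1])
})

test_that("raising the founder VAF floor never adds qualifying calls", {
  gs <- small_gene_sets()
  sim <- simulate_cohort(simulation_params(n_samples = 15, founder_probability = 1,
                                           background_mutations = 80, seed = 13))
  profiles <- build_profiles(apply_quality_filters(sim$records),
                             sample_ids = sim$truth$sample_id)
  n_qualifying <- function(vaf_floor) {
    fp <- founder_params(min_founder_vaf = vaf_floor)
    sum(vapply(profiles, function(p) {
      if (p$burden == 0) return(0L)
      sum(analyze_sample_founders(p, load_gene_sets(), fp, classify = FALSE)$qualifies)
    }, integer(1)))
  }
  counts <- vapply(c(50, 60, 70, 80, 90), n_qualifying, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("expansion patterns are classified from spectrum shape", {
  set.seed(101)
  fp <- founder_params()
  # one subclone peak
  single <- make_profile(pmin(pmax(rnorm(600, 30, 4), 1), 99))
  expect_equal(classify_pattern(vaf_histogram(single), 70, fp), "single")
  # two well-separated subclone peaks
  double <- make_profile(pmin(pmax(c(rnorm(300, 55, 4), rnorm(300, 25, 4)), 1), 99))
  expect_equal(classify_pattern(vaf_histogram(double), 70, fp),
               "double_or_multiple")
  # mass piled against the low-VAF end
  expo <- make_profile(pmin(5 + rexp(600, 1 / 10), 69))
  expect_equal(classify_pattern(vaf_histogram(expo), 80, fp), "exponential")
  # diffuse spectrum at a boosted burden: no peak above threshold
  neutral <- make_profile(runif(3000, 5, 69))
  expect_equal(classify_pattern(vaf_histogram(neutral), 70, fp), "neutral")
  # peaks closer than the separation floor merge into one
  close_pair <- make_profile(pmin(pmax(c(rnorm(300, 50, 3), rnorm(300, 56, 3)), 1), 99))
  expect_equal(classify_pattern(vaf_histogram(close_pair), 70,
                                founder_params(peak_separation = 15)),
               "single")
  expect_error(classify_pattern(vaf_histogram(single), 0), "founder_vaf")
})

test_that("single-expansion histogram mode sits near the planted subclone", {
  sim <- simulate_cohort(simulation_params(
    n_samples = 6, founder_probability = 1,
    pattern_mix = c(single = 1, double = 0, exponential = 0, neutral = 0),
    seed = 17
  ))
  profiles <- build_profiles(apply_quality_filters(sim$records),
                             sample_ids = sim$truth$sample_id)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    planted_peak <- as.numeric(tr$subclone_ccfs) * tr$founder_true_vaf
    h <- vaf_histogram(profiles[[tr$sample_id]])
    mode_bin <- which.max(h$counts) - 0.5
    expect_lte(abs(mode_bin - planted_peak), 3)
  }
})

test_that("top founder selection keeps top_k by VAF with alphabetical ties", {
  calls <- data.frame(
    sample_id = "S1", gene = c("ZZZ", "BBB", "MMM", "AAA"),
    founder_vaf = c(90, 80, 75, 80),
    n_subsequent = 100, n_subsequent_in_window = 90,
    window_lo = 50, window_hi = 80, qualifies = TRUE, pattern = "single",
    stringsAsFactors = FALSE
  )
  top <- select_top_founders(calls, founder_params(top_k = 3))
  expect_equal(top$gene, c("ZZZ", "AAA", "BBB"))
  two <- select_top_founders(calls[1:2, ], founder_params())
  expect_equal(nrow(two), 2)
  none <- select_top_founders(transform(calls, qualifies = FALSE), founder_params())
  expect_equal(nrow(none), 0)
})

test_that("cohort summary recovers the planted founder gene ranking", {
  gs <- load_gene_sets()
  sim <- simulate_cohort(simulation_params(
    n_samples = 80, background_mutations = 100, founder_probability = 1,
    founder_gene_pool = c(PRKDC = 8, ATM = 2), seed = 29
  ))
  profiles <- build_profiles(apply_quality_filters(sim$records),
                             sample_ids = sim$truth$sample_id)
  res <- cohort_founder_summary(profiles, gs)
  expect_equal(res$summary$gene[1], "PRKDC")
  n <- setNames(res$summary$n_samples, res$summary$gene)
  expect_gt(n["PRKDC"], n["ATM"])
  # observed founder VAFs track the planted values closely
  merged <- merge(res$calls, sim$truth, by = "sample_id")
  matching <- merged[merged$gene == merged$founder_gene, ]
  expect_gt(nrow(matching), 10)
  # per-sample read-sampling noise at ~100x has sd near 4 VAF points; the
  # cohort-level medians must agree much more tightly
  expect_lte(abs(median(matching$founder_vaf) -
                   median(matching$founder_true_vaf)), 2.5)
  expect_lte(median(abs(matching$founder_vaf - matching$founder_true_vaf)), 5)
  # a cohort without repair mutations yields an empty summary
  clean <- build_profiles(rbind(
    make_records("A", sprintf("Z%d", 1:30), 100, 50),
    make_records("B", sprintf("Y%d", 1:30), 100, 50)
  ))
  expect_equal(nrow(cohort_founder_summary(clean, gs)$summary), 0)
})
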