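test_that("profiles count burden per sample, including zero-burden samples", {
  recs <- make_records("S1", sprintf("G%d", 1:5), 100, 50)
  profiles <- build_profiles(recs, sample_ids = c("S1", "S2"))
  expect_equal(profiles$S1$burden, 5)
  expect_equal(profiles$S2$burden, 0)
  single <- build_profiles(make_records("S9", "TP53", 100, 50))
  expect_equal(single$S9$burden, 1)
})

test_that("simulated burdens match the truth table counts", {
  sim <- simulate_cohort(simulation_params(n_samples = 12,
                                           background_mutations = 60,
                                           seed = 21))
  profiles <- build_profiles(sim$records, sample_ids = sim$truth$sample_id)
  burdens <- vapply(profiles, `[[`, numeric(1), "burden")[sim$truth$sample_id]
  planted <- sim$truth$n_pre_founder + sim$truth$n_post_founder +
    as.integer(!is.na(sim$truth$founder_gene))
  expect_equal(unname(burdens), planted)
})

test_that("mutation status resolves genes and pathways, honoring the silent switch", {
  gs <- small_gene_sets()
  p1 <- build_profiles(make_records("S1", "PRKDC", 100, 50))[["S1"]]
  expect_true(mutation_status(p1, "NHEJ", gs))
  expect_true(mutation_status(p1, "PRKDC", gs))
  p2 <- build_profiles(make_records("S2", "TP53", 100, 50))[["S2"]]
  expect_false(mutation_status(p2, "BER", gs))
  # silent variants count by default, are excluded under nonsilent_only
  p3 <- build_profiles(make_records("S3", "APEX1", 100, 50,
                                    variant_class = "silent"))[["S3"]]
  expect_true(mutation_status(p3, "BER", gs))
  expect_false(mutation_status(p3, "BER", gs, nonsilent_only = TRUE))
  # a pathway target without gene sets cannot be resolved
  expect_error(mutation_status(p1, "MMR", NULL), "no gene sets")
})

test_that("burden association reports medians, fold increase and percent mutant", {
  gs <- small_gene_sets()
  # 7 mutant samples with median 4002, 7 wild with median 336
  recs <- list()
  mut_burdens <- c(3800, 3900, 4000, 4002, 4100, 4200, 4300)
  wild_burdens <- c(300, 320, 330, 336, 340, 350, 4000)
  for (i in seq_along(mut_burdens)) {
    id <- sprintf("M%d", i)
    recs[[id]] <- make_records(id, c("PRKDC", sprintf("P%d_%d", i, seq_len(mut_burdens[i] - 1))), 100, 50)
  }
  for (i in seq_along(wild_burdens)) {
    id <- sprintf("W%d", i)
    recs[[id]] <- make_records(id, sprintf("Q%d_%d", i, seq_len(wild_burdens[i])), 100, 50)
  }
  profiles <- build_profiles(do.call(rbind, recs))
  assoc <- associate_burden(profiles, "PRKDC", gs)
  expect_equal(assoc$median_burden_mutant, 4002)
  expect_equal(assoc$median_burden_wild, 336)
  expect_equal(round(assoc$fold_increase, 1), 11.9)
  expect_equal(assoc$pct_samples_mutant, 50)
  expect_lt(assoc$p_value, 0.01)
  # identical groups give fold increase 1
  expect_equal(fold_increase(336, 336), 1)
  # empty mutant group: p flagged undefined
  none <- associate_burden(profiles, "LIG4", gs)
  expect_true(is.na(none$p_value))
})

test_that("exact Mann-Whitney p-values match exhaustive enumeration", {
  r <- mann_whitney_u(c(10, 12, 14), c(1, 2, 3))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1) # 2 * 1/choose(6,3)
  expect_equal(r$p_value, mw_oracle(c(10, 12, 14), c(1, 2, 3)))
  # with ties
  x <- c(5, 5, 7); y <- c(5, 6, 6, 8)
  expect_equal(mann_whitney_u(x, y)$p_value, mw_oracle(x, y))
})

test_that("large-sample Mann-Whitney matches the standard rank-sum test", {
  set.seed(42)
  x <- rpois(30, 20); y <- rpois(25, 28)
  ours <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(ours$method, "normal_approx")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("association is invariant to sample order and relabeling", {
  gs <- small_gene_sets()
  set.seed(7)
  recs <- do.call(rbind, lapply(1:12, function(i) {
    genes <- c(if (i <= 5) "ATM", sprintf("R%d_%d", i, seq_len(rpois(1, 30) + i)))
    make_records(sprintf("S%02d", i), genes, 100, 50)
  }))
  profiles <- build_profiles(recs)
  a1 <- associate_burden(profiles, "ATM", gs)
  a2 <- associate_burden(rev(profiles), "ATM", gs)
  recs2 <- recs; recs2$sample_id <- paste0("X_", recs2$sample_id)
  a3 <- associate_burden(build_profiles(recs2), "ATM", gs)
  expect_equal(a1$p_value, a2$p_value)
  expect_equal(a1$p_value, a3$p_value)
  expect_equal(a1$fold_increase, a3$fold_increase)
})

test_that("gene ranking puts a planted mutator first and breaks ties alphabetically", {
  gs <- small_gene_sets()
  sim <- simulate_cohort(simulation_params(
    n_samples = 60, background_mutations = 60,
    founder_gene_pool = c(PRKDC = 1), founder_probability = 0.4, seed = 31
  ))
  profiles <- build_profiles(apply_quality_filters(sim$records),
                             sample_ids = sim$truth$sample_id)
  rk <- rank_genes(profiles, gs)
  expect_equal(rk$gene_or_pathway[1], "PRKDC")
  expect_true(all(diff(rk$p_value) >= 0))

  # no repair gene mutated -> empty ranking
  clean <- build_profiles(rbind(make_records("A", c("Z1", "Z2"), 100, 50),
                                make_records("B", "Z3", 100, 50)))
  expect_equal(nrow(rank_genes(clean, gs)), 0)

  # identical mutant sample sets -> identical p, alphabetical order
  recs <- rbind(
    make_records("S1", c("PRKDC", "ATM", "F1", "F2", "F3"), 100, 50),
    make_records("S2", c("PRKDC", "ATM", "F1", "F2", "F3", "F4", "F5"), 100, 50),
    make_records("S3", c("F6"), 100, 50),
    make_records("S4", c("F7", "F8"), 100, 50)
  )
  rk2 <- rank_genes(build_profiles(recs), gs)
  expect_equal(rk2$gene_or_pathway, c("ATM", "PRKDC"))
  expect_equal(rk2$p_value[1], rk2$p_value[2])
})

test_that("co-mutation odds ratios match hand arithmetic", {
  gs <- small_gene_sets()
  pick <- function(m, a, b) m[m$pathway_a == a & m$pathway_b == b, ]

  m1 <- comutation_matrix(comutation_cohort(10, 10, 10, 10), gs)
  expect_equal(pick(m1, "BER", "MMR")$odds_ratio, 1.0)

  m2 <- comutation_matrix(comutation_cohort(30, 10, 10, 30), gs)
  cell <- pick(m2, "BER", "MMR")
  expect_equal(cell$odds_ratio, 9.0)
  expect_equal(cell$pct_comutated, 100 * 30 / 80)
  expect_equal(cell$p_value,
               stats::fisher.test(matrix(c(30, 10, 10, 30), 2))$p.value)

  # Haldane-Anscombe correction only when a zero cell exists
  m3 <- comutation_matrix(comutation_cohort(5, 0, 2, 10), gs)
  expect_equal(pick(m3, "BER", "MMR")$odds_ratio,
               (5.5 * 10.5) / (0.5 * 2.5))
  expect_equal(round(pick(m3, "BER", "MMR")$odds_ratio, 1), 46.2)
})

test_that("co-mutation is symmetric in the pathway pair", {
  # swapping which pathway holds which status leaves OR, p and pct unchanged
  gs <- small_gene_sets()
  m_ab <- comutation_matrix(comutation_cohort(12, 3, 7, 20), gs)
  m_ba <- comutation_matrix(comutation_cohort(12, 7, 3, 20), gs)
  a <- m_ab[m_ab$pathway_a == "BER" & m_ab$pathway_b == "MMR", ]
  b <- m_ba[m_ba$pathway_a == "BER" & m_ba$pathway_b == "MMR", ]
  expect_equal(a$odds_ratio, b$odds_ratio)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$pct_comutated, b$pct_comutated)
})
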