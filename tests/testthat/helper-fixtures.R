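# Shared fixtures and independent oracles.

# Build a mutation-record data frame from per-record depths and alt counts.
make_records <- function(sample_id, gene, total_depth, alt_depth,
                         variant_class = "missense", chrom = "1",
                         pos = NULL) {
  n <- max(length(gene), length(total_depth), length(alt_depth),
           length(sample_id))
  if (is.null(pos)) pos <- seq_len(n)
  data.frame(
    sample_id = rep_len(sample_id, n), gene = rep_len(gene, n),
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    ref = "A", alt = "T",
    variant_class = rep_len(variant_class, n),
    total_depth = rep_len(total_depth, n),
    alt_depth = rep_len(alt_depth, n),
    vaf_percent = 100 * rep_len(alt_depth, n) / rep_len(total_depth, n),
    stringsAsFactors = FALSE
  )
}

# Profile with exact VAFs (depth 1000 so alt counts are integral for
# VAFs given to 0.1%).
make_profile <- function(vafs, genes = NULL, sample_id = "S1") {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_along(vafs))
  rec <- make_records(sample_id, genes, total_depth = 1000,
                      alt_depth = round(vafs * 10))
  build_profiles(rec)[[sample_id]]
}

# Minimal five-pathway gene-set fixture written to a temp YAML.
small_gene_sets <- function(ber = c("APEX1", "OGG1"),
                            ner = c("XPA", "ERCC1"),
                            mmr = c("MLH1", "MSH2"),
                            hr = c("BRCA2", "ATM"),
                            nhej = c("PRKDC", "LIG4")) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    version = "test-fixture",
    pathways = list(BER = as.list(ber), NER = as.list(ner), MMR = as.list(mmr),
                    HR = as.list(hr), NHEJ = as.list(nhej))
  ), path)
  load_gene_sets(path)
}

# Independent Mann-Whitney oracle: enumerate every assignment of the pooled
# VALUES to the two groups and compute U by direct pairwise comparison
# (#{x > y} + 0.5 #{x == y}), a different computation route than the
# package's rank-sum formula.
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_pairwise <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_pairwise(x, y)
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, function(ix) u_pairwise(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Cohort of profiles whose pathway mutation statuses realize the 2x2 table
# (a = both, b = only first, c = only second, d = neither) for the BER/MMR
# pair of small_gene_sets().
comutation_cohort <- function(a, b, c, d) {
  statuses <- rbind(
    matrix(rep(c(TRUE, TRUE), a), ncol = 2, byrow = TRUE),
    matrix(rep(c(TRUE, FALSE), b), ncol = 2, byrow = TRUE),
    matrix(rep(c(FALSE, TRUE), c), ncol = 2, byrow = TRUE),
    matrix(rep(c(FALSE, FALSE), d), ncol = 2, byrow = TRUE)
  )
  recs <- lapply(seq_len(nrow(statuses)), function(i) {
    genes <- "NEUTRAL1"
    if (statuses[i, 1]) genes <- c(genes, "APEX1")
    if (statuses[i, 2]) genes <- c(genes, "MLH1")
    make_records(sprintf("S%03d", i), genes, 100, 50)
  })
  build_profiles(do.call(rbind, recs))
}
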