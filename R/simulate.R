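#' Parameters of the synthetic tumor-cohort generator
#'
#' The generator plants, with probability `founder_probability`, a single
#' high-VAF founder mutation in a DNA-repair gene, preceded by a truncal
#' background of clonal mutations and followed by a boosted burst of
#' lower-VAF mutations arranged in one of four clonal-expansion patterns.
#' Read support is sampled per record: depth from a negative binomial,
#' mutant reads from a binomial at the mutation's expected VAF.
#'
#' Defaults mirror the conditions of the colorectal-cancer cohorts the
#' package is designed around: background burden of ~330 mutations
#' (wild-type median), an 8-fold post-founder boost (top repair genes show
#' a 6-12x median burden increase), founder VAFs of 60-95 percent
#' (observed founders cluster near 70 percent, ranging up to 99), a founder
#' prevalence of 0.21 (125 of 591 patients), pattern proportions of
#' 35.2/21.6/14.4 percent for single/double/exponential with the remainder
#' diffuse ("neutral"), a founder gene pool weighted like the top five
#' recurrent founder genes, and ~100x exome coverage.
#'
#' @param n_samples Number of samples. Default 200.
#' @param background_mutations Mean truncal (pre-founder) mutation count per
#'   sample; also the burden of samples without a founder. Default 330.
#' @param founder_probability Probability that a sample carries a planted
#'   founder. Default 0.21.
#' @param founder_gene_pool Named numeric vector of repair-gene weights from
#'   which the founder gene is drawn.
#' @param boost_factor Multiplier on the post-founder mutation count
#'   (Poisson mean `background_mutations * boost_factor`). Default 8.
#' @param pattern_mix Named probabilities over
#'   `single`, `double`, `exponential`, `neutral`; must sum to 1.
#' @param purity Tumor purity in \[0, 1\]; scales every expected VAF.
#'   Default 1.
#' @param depth_mean Mean sequencing depth. Default 100.
#' @param depth_dispersion Negative-binomial size parameter for depth;
#'   25 gives a coefficient of variation near 22 percent, typical of exome
#'   coverage. Larger is less dispersed.
#' @param founder_vaf_range Range (percent) of the founder's expected VAF,
#'   drawn uniformly. Founders are early truncal events whose mutant-read
#'   fraction is typically inflated above the 50 percent diploid
#'   heterozygous ceiling by copy-number gain or loss of heterozygosity;
#'   the generator draws the founder VAF directly instead of deriving it
#'   from a diploid CCF. Default (60, 95).
#' @param subclone_ccf_range Range of subclone cancer-cell fractions
#'   relative to the founder clone; a subclone's expected VAF is its CCF
#'   times the founder VAF. Used for reporting in the truth table.
#'   Default (0.2, 0.9).
#' @param n_passenger_genes Size of the dummy gene pool (disjoint from
#'   repair genes) used for passenger labels. Default 500.
#' @param repair_contamination Probability that a passenger mutation is
#'   labeled with a repair gene instead of a dummy gene - a stress test for
#'   false founder calls. Default 0 (off). A realistic value is ~0.009
#'   (about 180 repair genes out of ~20,000).
#' @param contamination_gene_pool Character vector of repair genes used when
#'   `repair_contamination > 0` (e.g. `load_gene_sets()$all_repair_genes`).
#' @param seed Integer seed; mandatory for reproducible cohorts via
#'   [simulate_cohort()].
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_samples = 200,
                              background_mutations = 330,
                              founder_probability = 0.21,
                              founder_gene_pool = c(PRKDC = 31, ATM = 26,
                                                    POLE = 18, SRCAP = 18,
                                                    BRCA2 = 15),
                              boost_factor = 8,
                              pattern_mix = c(single = 0.352, double = 0.216,
                                              exponential = 0.144,
                                              neutral = 0.288),
                              purity = 1.0,
                              depth_mean = 100,
                              depth_dispersion = 25,
                              founder_vaf_range = c(60, 95),
                              subclone_ccf_range = c(0.2, 0.9),
                              n_passenger_genes = 500,
                              repair_contamination = 0,
                              contamination_gene_pool = NULL,
                              seed = NULL) {
  stopifnot(
    n_samples >= 1, background_mutations > 0,
    founder_probability >= 0, founder_probability <= 1,
    length(founder_gene_pool) >= 1, !is.null(names(founder_gene_pool)),
    all(founder_gene_pool > 0),
    boost_factor >= 1,
    purity > 0, purity <= 1,
    depth_mean > 0, depth_dispersion > 0,
    length(founder_vaf_range) == 2, founder_vaf_range[1] < founder_vaf_range[2],
    length(subclone_ccf_range) == 2,
    repair_contamination >= 0, repair_contamination <= 1
  )
  if (!setequal(names(pattern_mix), c("single", "double", "exponential", "neutral"))) {
    stop("pattern_mix must name single, double, exponential, neutral", call. = FALSE)
  }
  if (any(pattern_mix < 0) || abs(sum(pattern_mix) - 1) > 1e-8) {
    stop("pattern_mix probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  if (repair_contamination > 0 && is.null(contamination_gene_pool)) {
    stop("repair_contamination > 0 requires contamination_gene_pool", call. = FALSE)
  }
  structure(
    list(
      n_samples = n_samples, background_mutations = background_mutations,
      founder_probability = founder_probability,
      founder_gene_pool = founder_gene_pool, boost_factor = boost_factor,
      pattern_mix = pattern_mix[c("single", "double", "exponential", "neutral")],
      purity = purity, depth_mean = depth_mean,
      depth_dispersion = depth_dispersion,
      founder_vaf_range = founder_vaf_range,
      subclone_ccf_range = subclone_ccf_range,
      n_passenger_genes = n_passenger_genes,
      repair_contamination = repair_contamination,
      contamination_gene_pool = contamination_gene_pool,
      seed = seed
    ),
    class = "simulation_params"
  )
}

BASES <- c("A", "C", "G", "T")
PASSENGER_CLASSES <- c("missense", "silent", "nonsense", "frameshift_ins",
                       "frameshift_del", "splice", "other")
PASSENGER_CLASS_PROBS <- c(0.55, 0.25, 0.08, 0.04, 0.04, 0.02, 0.02)
FOUNDER_CLASSES <- c("missense", "frameshift_ins", "frameshift_del", "nonsense")
FOUNDER_CLASS_PROBS <- c(0.6, 0.15, 0.15, 0.1)

sample_gene_labels <- function(n, params) {
  pool <- sprintf("GENE%04d", seq_len(params$n_passenger_genes))
  genes <- sample(pool, n, replace = TRUE)
  if (params$repair_contamination > 0 && n > 0) {
    hit <- stats::runif(n) < params$repair_contamination
    if (any(hit)) {
      genes[hit] <- sample(params$contamination_gene_pool, sum(hit), replace = TRUE)
    }
  }
  genes
}

draw_records <- function(sample_id, genes, expected_vaf, classes, params) {
  n <- length(genes)
  depth <- pmax(stats::rnbinom(n, size = params$depth_dispersion,
                               mu = params$depth_mean), 1)
  p <- pmin(pmax(expected_vaf, 0), 100) / 100
  alt <- stats::rbinom(n, depth, p)
  ref <- sample(BASES, n, replace = TRUE)
  alt_allele <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
  data.frame(
    sample_id = sample_id, gene = genes,
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n, replace = TRUE),
    ref = ref, alt = alt_allele, variant_class = classes,
    total_depth = depth, alt_depth = alt,
    vaf_percent = ifelse(depth > 0, 100 * alt / depth, NA_real_),
    stringsAsFactors = FALSE
  )
}

# Expected VAFs of post-founder mutations for one pattern. Expansion
# subclones descend from the founder clone, so their peaks are anchored a
# short frequency offset beneath the founder VAF (single and double); the
# exponential pattern piles many small subclones against the low-VAF end;
# neutral spreads mutations diffusely with no dominant subclone.
pattern_vafs <- function(pattern, n_post, fv) {
  if (n_post == 0) return(list(vafs = numeric(), peaks = numeric()))
  switch(pattern,
    single = {
      peak <- fv - stats::runif(1, 5, 25)
      list(vafs = rep(peak, n_post), peaks = peak)
    },
    double = {
      p1 <- fv - stats::runif(1, 4, 8)
      p2 <- fv - stats::runif(1, 21, 28)
      pick <- stats::runif(n_post) < 0.5
      list(vafs = ifelse(pick, p1, p2), peaks = c(p1, p2))
    },
    exponential = {
      v <- 5 + stats::rexp(n_post, rate = 1 / 12)
      list(vafs = pmin(v, fv - 10), peaks = numeric())
    },
    neutral = {
      list(vafs = stats::runif(n_post, 5, fv), peaks = numeric())
    },
    stop(sprintf("unknown pattern: %s", pattern), call. = FALSE)
  )
}

#' Simulate one tumor sample
#'
#' Draws one sample's mutation records and the matching ground truth. Uses
#' the current R random-number state; seed via [set.seed()] or use
#' [simulate_cohort()], which seeds once from `params$seed`.
#'
#' Model: `n_pre ~ Poisson(background_mutations)` truncal passenger
#' mutations at the clonal expectation (`VAF = 50 * purity`, diploid
#' heterozygous, CCF 1). With probability `founder_probability`, one founder
#' record in a repair gene at an expected VAF drawn from
#' `founder_vaf_range`, followed by `n_post ~ Poisson(background *
#' boost_factor)` passenger mutations placed according to the sample's
#' expansion pattern. Depth is negative binomial, mutant reads binomial, so
#' records failing the default quality policy may be emitted - filtering is
#' the reader's job.
#'
#' @param params A [simulation_params()] object.
#' @param sample_id Sample identifier for the emitted records.
#' @return A list with `records` (mutation-record data frame) and `truth`
#'   (one-row data frame: `sample_id`, `founder_gene`, `founder_true_vaf`,
#'   `pattern`, `subclone_ccfs`, `n_pre_founder`, `n_post_founder`).
#' @export
simulate_sample <- function(params, sample_id = "S001") {
  stopifnot(inherits(params, "simulation_params"))
  n_pre <- stats::rpois(1, params$background_mutations)
  truncal_vaf <- 50 * params$purity

  has_founder <- stats::runif(1) < params$founder_probability
  founder_gene <- NA_character_
  founder_vaf <- NA_real_
  pattern <- NA_character_
  ccf_str <- NA_character_
  n_post <- 0L

  pre <- draw_records(
    sample_id,
    genes = sample_gene_labels(n_pre, params),
    expected_vaf = rep(truncal_vaf, n_pre),
    classes = sample(PASSENGER_CLASSES, n_pre, TRUE, PASSENGER_CLASS_PROBS),
    params = params
  )
  parts <- list(pre)

  if (has_founder) {
    w <- params$founder_gene_pool
    founder_gene <- sample(names(w), 1, prob = w / sum(w))
    founder_vaf <- stats::runif(1, params$founder_vaf_range[1],
                                params$founder_vaf_range[2]) * params$purity
    pattern <- sample(names(params$pattern_mix), 1, prob = params$pattern_mix)
    n_post <- stats::rpois(1, params$background_mutations * params$boost_factor)
    pv <- pattern_vafs(pattern, n_post, founder_vaf)
    if (length(pv$peaks)) {
      ccf_str <- paste(round(pv$peaks / founder_vaf, 4), collapse = ",")
    }
    parts <- c(parts, list(
      draw_records(sample_id, founder_gene, founder_vaf,
                   sample(FOUNDER_CLASSES, 1, prob = FOUNDER_CLASS_PROBS),
                   params),
      draw_records(
        sample_id,
        genes = sample_gene_labels(n_post, params),
        expected_vaf = pv$vafs,
        classes = sample(PASSENGER_CLASSES, n_post, TRUE, PASSENGER_CLASS_PROBS),
        params = params
      )
    ))
  }

  records <- do.call(rbind, parts)
  rownames(records) <- NULL
  truth <- data.frame(
    sample_id = sample_id,
    founder_gene = founder_gene,
    founder_true_vaf = founder_vaf,
    pattern = pattern,
    subclone_ccfs = ccf_str,
    n_pre_founder = n_pre,
    n_post_founder = n_post,
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Simulate a tumor cohort with ground truth
#'
#' Seeds the random-number generator once from `params$seed` and draws
#' `n_samples` samples via [simulate_sample()]. Optionally writes the
#' mutation table (canonical simple_tsv dialect, readable by
#' [read_mutation_table()]) and the truth table, aligned by `sample_id`.
#'
#' @param params A [simulation_params()] object; `params$seed` must be set.
#' @param out_dir Optional output directory; if given, writes
#'   `mutations.tsv` and `truth.tsv` there.
#' @return A list with `records`, `truth`, and (if written) `files`.
#' @export
simulate_cohort <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (is.null(params$seed)) stop("params$seed must be set for cohort simulation",
                                 call. = FALSE)
  set.seed(params$seed)
  ids <- sprintf("S%04d", seq_len(params$n_samples))
  sims <- lapply(ids, function(id) simulate_sample(params, id))
  records <- do.call(rbind, lapply(sims, `[[`, "records"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  rownames(records) <- rownames(truth) <- NULL
  out <- list(records = records, truth = truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    mut_path <- file.path(out_dir, "mutations.tsv")
    truth_path <- file.path(out_dir, "truth.tsv")
    write_mutation_table(records, mut_path)
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- c(mutations = mut_path, truth = truth_path)
  }
  out
}

#' Simulate an expression matrix with relapse-free survival
#'
#' Generates log-normal gene expression for tumor and normal samples and an
#' exponential relapse-time table whose hazard depends on the target gene's
#' median-split expression group: patients above the cohort median have
#' hazard multiplied by `hr_true`. Censoring is independent and
#' exponential. The target gene's tumor mean is `fc_tumor_normal` times its
#' normal mean; all other genes share the same mean in both tissues.
#'
#' @param n_patients Number of tumor samples with survival data.
#' @param hr_true True hazard ratio of the high-expression group versus the
#'   low group. Must be positive.
#' @param fc_tumor_normal True tumor-versus-normal fold change of the
#'   target gene's mean expression.
#' @param target_gene Gene whose expression drives survival. Default
#'   `"PRKDC"`.
#' @param other_genes Additional genes carried in the matrix (no survival
#'   effect, fold change 1).
#' @param n_normal Number of normal-tissue samples. Default 100.
#' @param base_mean Mean expression of a neutral gene on the normalized
#'   scale (chips scaled to mean 1000). Default 1000.
#' @param sdlog Log-scale standard deviation of expression. Default 0.5.
#' @param base_hazard Baseline relapse hazard per time unit. Default 0.1.
#' @param censor_hazard Hazard of independent censoring. Default 0.05.
#' @param seed Optional integer seed.
#' @return A list with `expression` (genes x tumor samples matrix),
#'   `normal_expression` (genes x normal samples), `survival` (data frame
#'   `sample_id`, `time`, `event`), and `annotations` (`sample_id`,
#'   `tissue`).
#' @export
simulate_expression_survival <- function(n_patients = 1000,
                                         hr_true = 1.0,
                                         fc_tumor_normal = 1.0,
                                         target_gene = "PRKDC",
                                         other_genes = c("BRCA2", "ATM",
                                                         "RAD50", "LIG1",
                                                         "MLH3", "POLD1",
                                                         "POLE"),
                                         n_normal = 100,
                                         base_mean = 1000,
                                         sdlog = 0.5,
                                         base_hazard = 0.1,
                                         censor_hazard = 0.05,
                                         seed = NULL) {
  stopifnot(hr_true > 0, fc_tumor_normal > 0, n_patients >= 4, n_normal >= 2)
  if (!is.null(seed)) set.seed(seed)
  genes <- c(target_gene, setdiff(other_genes, target_gene))
  tumor_ids <- sprintf("T%04d", seq_len(n_patients))
  normal_ids <- sprintf("N%04d", seq_len(n_normal))
  # lognormal mean = exp(mu + sdlog^2/2); shift mu so E[X] hits the target
  mu_neutral <- log(base_mean) - sdlog^2 / 2
  draw <- function(n, mu) stats::rlnorm(n, meanlog = mu, sdlog = sdlog)
  expr <- matrix(NA_real_, nrow = length(genes), ncol = n_patients,
                 dimnames = list(genes, tumor_ids))
  norm <- matrix(NA_real_, nrow = length(genes), ncol = n_normal,
                 dimnames = list(genes, normal_ids))
  for (g in genes) {
    mu_t <- if (g == target_gene) mu_neutral + log(fc_tumor_normal) else mu_neutral
    expr[g, ] <- draw(n_patients, mu_t)
    norm[g, ] <- draw(n_normal, mu_neutral)
  }
  high <- expr[target_gene, ] > stats::median(expr[target_gene, ])
  hazard <- base_hazard * hr_true^as.numeric(high)
  t_event <- stats::rexp(n_patients, rate = hazard)
  t_cens <- stats::rexp(n_patients, rate = censor_hazard)
  surv <- data.frame(
    sample_id = tumor_ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )
  list(
    expression = expr,
    normal_expression = norm,
    survival = surv,
    annotations = data.frame(
      sample_id = c(tumor_ids, normal_ids),
      tissue = rep(c("tumor", "normal"), c(n_patients, n_normal)),
      stringsAsFactors = FALSE
    )
  )
}
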