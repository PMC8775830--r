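#' Run configuration for the analysis pipeline
#'
#' Bundles input paths, filter and founder parameters, and the output
#' directory for the orchestrated stages ([run_burden()], [run_founder()],
#' [run_survival()]). Referenced input paths are checked at construction
#' time. Every output table carries a provenance header with the package
#' version, a hash of the configuration, and the seed.
#'
#' @param mutations Path to the mutation table (for burden/founder stages).
#' @param dialect Mutation-table dialect; see [read_mutation_table()].
#' @param gene_sets Path to a gene-set YAML, or `NULL` for the packaged
#'   default.
#' @param expression,normal_expression Paths to genes-by-samples expression
#'   TSVs (tumor / normal) for the survival stage.
#' @param survival_table Path to a survival TSV (`sample_id`, `time`,
#'   `event`).
#' @param out_dir Output directory (created if absent).
#' @param policy A [quality_filter_policy()].
#' @param params A [founder_params()].
#' @param seed Integer seed recorded in output headers (the analysis stages
#'   are deterministic; the seed matters when the inputs were simulated).
#' @param nonsilent_only Restrict mutation status to non-silent variants.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mutations = NULL,
                       dialect = "simple_tsv",
                       gene_sets = NULL,
                       expression = NULL,
                       normal_expression = NULL,
                       survival_table = NULL,
                       out_dir = ".",
                       policy = quality_filter_policy(),
                       params = founder_params(),
                       seed = 0L,
                       nonsilent_only = FALSE) {
  paths <- c(mutations = mutations, gene_sets = gene_sets,
             expression = expression, normal_expression = normal_expression,
             survival_table = survival_table)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      stop(sprintf("config: %s file not found: %s", nm, paths[[nm]]),
           call. = FALSE)
    }
  }
  cfg <- structure(
    list(
      mutations = mutations, dialect = dialect, gene_sets = gene_sets,
      expression = expression, normal_expression = normal_expression,
      survival_table = survival_table, out_dir = out_dir,
      policy = policy, params = params, seed = as.integer(seed),
      nonsilent_only = nonsilent_only
    ),
    class = "run_config"
  )
  cfg
}

#' Hash of a run configuration
#'
#' MD5 over the deparsed configuration (excluding the output directory, so
#' the same analysis written elsewhere shares a hash).
#'
#' @param config A `run_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(config) {
  c(
    sprintf("# founderscan %s",
            as.character(utils::packageVersion("founderscan"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %d", config$seed)
  )
}

write_result_table <- function(df, path, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(format(df, digits = 6, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_cohort <- function(config) {
  if (is.null(config$mutations)) stop("config has no mutations path", call. = FALSE)
  records <- read_mutation_table(config$mutations, config$dialect)
  filtered <- apply_quality_filters(records, config$policy)
  list(
    profiles = build_profiles(filtered, sample_ids = unique(records$sample_id)),
    gene_sets = load_gene_sets(config$gene_sets),
    n_input = nrow(records), n_retained = attr(filtered, "n_retained")
  )
}

#' Run the burden-association stage
#'
#' Reads and quality-filters the mutation table, ranks repair genes by
#' burden association, and computes the pathway co-mutation matrix. Writes
#' `gene_burden_associations.tsv` and `pathway_comutation.tsv` to the
#' configured output directory; outputs are deterministic given the inputs.
#'
#' @param config A [run_config()] with a `mutations` path.
#' @return Invisibly, a list with `ranking`, `comutation`, and `files`.
#' @export
run_burden <- function(config) {
  stopifnot(inherits(config, "run_config"))
  co <- load_cohort(config)
  message(sprintf("burden: %d records read, %d retained, %d samples",
                  co$n_input, co$n_retained, length(co$profiles)))
  ranking <- rank_genes(co$profiles, co$gene_sets,
                        nonsilent_only = config$nonsilent_only)
  comut <- comutation_matrix(co$profiles, co$gene_sets,
                             nonsilent_only = config$nonsilent_only)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  files <- c(
    ranking = write_result_table(
      ranking, file.path(config$out_dir, "gene_burden_associations.tsv"), config),
    comutation = write_result_table(
      comut, file.path(config$out_dir, "pathway_comutation.tsv"), config)
  )
  invisible(list(ranking = ranking, comutation = comut, files = files))
}

#' Run the founder-detection stage
#'
#' Reads and quality-filters the mutation table, calls founder mutations per
#' sample, and aggregates the cohort summary. Writes `founder_calls.tsv`
#' (top qualifying calls per sample) and `founder_summary.tsv` (per-gene
#' sample counts with founder-VAF medians and ranges).
#'
#' @param config A [run_config()] with a `mutations` path.
#' @return Invisibly, a list with `calls`, `summary`, and `files`.
#' @export
run_founder <- function(config) {
  stopifnot(inherits(config, "run_config"))
  co <- load_cohort(config)
  res <- cohort_founder_summary(co$profiles, co$gene_sets, config$params)
  message(sprintf("founder: %d qualifying calls across %d samples",
                  nrow(res$calls), length(co$profiles)))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  files <- c(
    calls = write_result_table(
      res$calls, file.path(config$out_dir, "founder_calls.tsv"), config),
    summary = write_result_table(
      res$summary, file.path(config$out_dir, "founder_summary.tsv"), config)
  )
  invisible(list(calls = res$calls, summary = res$summary, files = files))
}

read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                          comment.char = "#")
  as.matrix(df)
}

#' Run the expression/survival stage
#'
#' For each requested gene, computes the tumor-versus-normal expression fold
#' change and the median-split Cox hazard ratio for relapse-free survival.
#' Writes `survival_results.tsv` with columns `gene`, `hazard_ratio`,
#' `ci_low`, `ci_high`, `p_value`, `fold_change_tumor_vs_normal`.
#'
#' @param config A [run_config()] with `expression`, `normal_expression`,
#'   and `survival_table` paths.
#' @param genes Genes to analyze; default: all rows shared by both matrices.
#' @return Invisibly, a list with `results` and `files`.
#' @export
run_survival <- function(config, genes = NULL) {
  stopifnot(inherits(config, "run_config"))
  for (nm in c("expression", "normal_expression", "survival_table")) {
    if (is.null(config[[nm]])) {
      stop(sprintf("config has no %s path", nm), call. = FALSE)
    }
  }
  expr <- read_expression_matrix(config$expression)
  norm <- read_expression_matrix(config$normal_expression)
  surv <- utils::read.delim(config$survival_table, comment.char = "#")
  if (is.null(genes)) genes <- intersect(rownames(expr), rownames(norm))
  rows <- lapply(genes, function(g) {
    fc <- tumor_normal_fold_change(expr, norm, g)
    ms <- median_split_survival(expr, g, surv)
    cbind(
      data.frame(gene = g, stringsAsFactors = FALSE),
      ms$result[, c("hazard_ratio", "ci_low", "ci_high", "p_value")],
      data.frame(fold_change_tumor_vs_normal = fc$fold_change,
                 fc_p_value = fc$p_value)
    )
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  files <- c(results = write_result_table(
    results, file.path(config$out_dir, "survival_results.tsv"), config))
  invisible(list(results = results, files = files))
}
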