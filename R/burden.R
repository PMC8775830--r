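#' Build per-sample mutation profiles
#'
#' Groups quality-filtered mutation records by sample and computes each
#' sample's tumor mutation burden (TMB): the number of mutations accepted by
#' the applied filters. Samples known to the cohort but absent from the
#' record table (zero burden) can be declared via `sample_ids`.
#'
#' @param records Filtered mutation-record data frame.
#' @param sample_ids Optional character vector of all cohort sample IDs;
#'   defaults to the IDs present in `records`.
#' @return A named list of `sample_profile` objects (class
#'   `sample_profiles`), each with elements `sample_id`, `records`, and
#'   `burden`.
#' @export
build_profiles <- function(records, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- unique(records$sample_id)
  } else {
    sample_ids <- unique(as.character(sample_ids))
    extra <- setdiff(unique(records$sample_id), sample_ids)
    if (length(extra)) {
      stop(sprintf("records contain sample IDs not in sample_ids: %s",
                   paste(utils::head(extra, 3), collapse = ", ")), call. = FALSE)
    }
  }
  idx <- split(seq_len(nrow(records)), factor(records$sample_id, levels = sample_ids))
  profiles <- lapply(sample_ids, function(sid) {
    rec <- records[idx[[sid]], , drop = FALSE]
    rownames(rec) <- NULL
    structure(
      list(sample_id = sid, records = rec, burden = nrow(rec)),
      class = "sample_profile"
    )
  })
  names(profiles) <- sample_ids
  structure(profiles, class = c("sample_profiles", "list"))
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("Sample %s: burden %d\n", x$sample_id, x$burden))
  invisible(x)
}

#' @export
print.sample_profiles <- function(x, ...) {
  b <- vapply(x, `[[`, numeric(1), "burden")
  cat(sprintf("%d sample profiles; burden median %g (range %g-%g)\n",
              length(x), stats::median(b), min(b), max(b)))
  invisible(x)
}

resolve_target_genes <- function(target, gene_sets) {
  if (!is.null(gene_sets) && target %in% names(gene_sets$pathways)) {
    return(gene_sets$pathways[[target]])
  }
  if (target %in% PATHWAY_NAMES) {
    stop(sprintf("pathway %s requested but no gene sets supplied", target),
         call. = FALSE)
  }
  target
}

profile_genes <- function(profile, nonsilent_only = FALSE) {
  rec <- profile$records
  if (nonsilent_only) rec <- rec[rec$variant_class != "silent", , drop = FALSE]
  unique(rec$gene)
}

#' Mutation status of a sample for a gene or pathway
#'
#' `TRUE` if the sample carries at least one mutation in the target gene, or
#' in any gene of the target repair pathway. By default every variant class
#' counts, including silent variants; set `nonsilent_only = TRUE` to restrict
#' status to protein-altering classes.
#'
#' @param profile A `sample_profile`.
#' @param target A gene symbol or one of the pathway names
#'   (`BER`, `NER`, `MMR`, `HR`, `NHEJ`).
#' @param gene_sets A `pathway_gene_sets` object (required to resolve
#'   pathway targets).
#' @param nonsilent_only Exclude silent variants from status calls.
#' @return Logical scalar.
#' @export
mutation_status <- function(profile, target, gene_sets = NULL,
                            nonsilent_only = FALSE) {
  genes <- resolve_target_genes(target, gene_sets)
  any(profile_genes(profile, nonsilent_only) %in% genes)
}

#' Association between repair mutation status and mutation burden
#'
#' Splits the cohort by the mutation status of a DNA-repair gene or pathway
#' and compares tumor mutation burden between the two groups with a
#' two-sided Mann-Whitney U test. Reports group medians, the fold increase
#' in median burden (mutant over wild-type), and the percentage of mutant
#' samples. If one group is empty the association is returned with the
#' p-value flagged undefined (`NA`).
#'
#' @param profiles A `sample_profiles` list from [build_profiles()].
#' @param target Gene symbol or pathway name.
#' @param gene_sets A `pathway_gene_sets` object.
#' @param nonsilent_only Exclude silent variants from status calls.
#' @return One-row data frame with columns `gene_or_pathway`, `p_value`,
#'   `median_burden_mutant`, `median_burden_wild`, `fold_increase`,
#'   `pct_samples_mutant`, `n_mutant`, `n_total`.
#' @export
associate_burden <- function(profiles, target, gene_sets = NULL,
                             nonsilent_only = FALSE) {
  burdens <- vapply(profiles, `[[`, numeric(1), "burden")
  mutant <- vapply(profiles, mutation_status, logical(1),
                   target = target, gene_sets = gene_sets,
                   nonsilent_only = nonsilent_only)
  burden_association(target, burdens, mutant)
}

# Shared worker: association from a burden vector and a mutant mask.
burden_association <- function(target, burdens, mutant) {
  n <- length(burdens)
  bm <- burdens[mutant]
  bw <- burdens[!mutant]
  med_m <- if (length(bm)) stats::median(bm) else NA_real_
  med_w <- if (length(bw)) stats::median(bw) else NA_real_
  p <- if (length(bm) && length(bw)) mann_whitney_u(bm, bw)$p_value else NA_real_
  data.frame(
    gene_or_pathway = target,
    p_value = p,
    median_burden_mutant = med_m,
    median_burden_wild = med_w,
    fold_increase = if (is.na(med_m) || is.na(med_w)) NA_real_ else fold_increase(med_m, med_w),
    pct_samples_mutant = 100 * sum(mutant) / n,
    n_mutant = sum(mutant),
    n_total = n,
    stringsAsFactors = FALSE
  )
}

#' Rank DNA-repair genes by association with mutation burden
#'
#' Computes one burden association per repair gene that is mutated in at
#' least one sample, ordered by ascending Mann-Whitney p-value (ties broken
#' alphabetically by gene, undefined p-values last). A Benjamini-Hochberg
#' adjusted `q_value` column is added as supplementary output; the primary
#' ordering uses the raw p-values.
#'
#' @param profiles A `sample_profiles` list.
#' @param gene_sets A `pathway_gene_sets` object.
#' @param nonsilent_only Exclude silent variants from status calls.
#' @return Data frame of associations (possibly empty), one row per mutated
#'   repair gene.
#' @export
rank_genes <- function(profiles, gene_sets, nonsilent_only = FALSE) {
  stopifnot(inherits(gene_sets, "pathway_gene_sets"))
  if (length(profiles) < 2) stop("ranking needs at least 2 samples", call. = FALSE)
  burdens <- vapply(profiles, `[[`, numeric(1), "burden")
  genes_by_sample <- lapply(profiles, profile_genes, nonsilent_only = nonsilent_only)
  repair_by_sample <- lapply(genes_by_sample, intersect, x = gene_sets$all_repair_genes)
  mutated <- sort(unique(unlist(repair_by_sample, use.names = FALSE)))
  if (!length(mutated)) {
    out <- burden_association("x", numeric(1), TRUE)[0, ]
    out$q_value <- numeric(0)
    return(out)
  }
  rows <- lapply(mutated, function(g) {
    mask <- vapply(repair_by_sample, function(gs) g %in% gs, logical(1))
    burden_association(g, burdens, mask)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$gene_or_pathway, na.last = TRUE), , drop = FALSE]
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Pairwise co-mutation enrichment between repair pathways
#'
#' For each unordered pair of repair pathways, cross-tabulates sample
#' mutation status (mutated in A by mutated in B) and reports the odds
#' ratio (with the Haldane-Anscombe 0.5 correction applied only when a zero
#' cell exists), the Fisher exact p-value, and the percentage of samples
#' mutated in both pathways.
#'
#' @param profiles A `sample_profiles` list.
#' @param gene_sets A `pathway_gene_sets` object.
#' @param nonsilent_only Exclude silent variants from status calls.
#' @return Data frame with columns `pathway_a`, `pathway_b`, `odds_ratio`,
#'   `p_value`, `pct_comutated`, `n_both`, `n_total`; one row per unordered
#'   pathway pair (diagonal excluded).
#' @export
comutation_matrix <- function(profiles, gene_sets, nonsilent_only = FALSE) {
  stopifnot(inherits(gene_sets, "pathway_gene_sets"))
  pw <- names(gene_sets$pathways)
  genes_by_sample <- lapply(profiles, profile_genes, nonsilent_only = nonsilent_only)
  status <- vapply(pw, function(p) {
    vapply(genes_by_sample, function(gs) any(gs %in% gene_sets$pathways[[p]]),
           logical(1))
  }, logical(length(profiles)))
  if (length(profiles) == 1) status <- matrix(status, nrow = 1, dimnames = list(NULL, pw))
  n <- nrow(status)
  pairs <- utils::combn(pw, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    pa <- pairs[1, k]; pb <- pairs[2, k]
    a <- sum(status[, pa] & status[, pb])
    b <- sum(status[, pa] & !status[, pb])
    c <- sum(!status[, pa] & status[, pb])
    d <- sum(!status[, pa] & !status[, pb])
    p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
    data.frame(
      pathway_a = pa, pathway_b = pb,
      odds_ratio = odds_ratio_2x2(a, b, c, d),
      p_value = p,
      pct_comutated = 100 * a / n,
      n_both = a, n_total = n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
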