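#' Tumor-versus-normal expression fold change
#'
#' Fold change of a gene's mean expression in tumor versus normal tissue,
#' with a two-sided Mann-Whitney p-value for the group comparison.
#'
#' @param expression Genes-by-samples numeric matrix of tumor expression.
#' @param normal_expression Genes-by-samples matrix of normal expression.
#' @param gene Gene symbol (must be a row of both matrices).
#' @return A list with `fold_change` (mean tumor / mean normal), `p_value`,
#'   `n_tumor`, `n_normal`.
#' @export
tumor_normal_fold_change <- function(expression, normal_expression, gene) {
  if (!gene %in% rownames(expression) || !gene %in% rownames(normal_expression)) {
    stop(sprintf("gene %s absent from the expression matrices", gene),
         call. = FALSE)
  }
  tum <- as.numeric(expression[gene, ])
  nor <- as.numeric(normal_expression[gene, ])
  if (!length(tum) || !length(nor)) stop("both tissue groups must be present",
                                         call. = FALSE)
  list(
    fold_change = mean(tum) / mean(nor),
    p_value = mann_whitney_u(tum, nor)$p_value,
    n_tumor = length(tum),
    n_normal = length(nor)
  )
}

#' Mean-expression signature score over a gene set
#'
#' Per-sample arithmetic mean of the expression of the available genes in
#' the set. Genes missing from the matrix are reported via the
#' `missing_genes` attribute; if no gene overlaps, an error is raised.
#'
#' @param expression Genes-by-samples numeric matrix.
#' @param gene_set Character vector of gene symbols.
#' @return Named numeric vector of per-sample scores with attribute
#'   `missing_genes`.
#' @export
signature_score <- function(expression, gene_set) {
  present <- intersect(gene_set, rownames(expression))
  if (!length(present)) {
    stop("no gene of the set is present in the expression matrix", call. = FALSE)
  }
  score <- colMeans(expression[present, , drop = FALSE])
  attr(score, "missing_genes") <- setdiff(gene_set, present)
  score
}

#' Median-split survival analysis for a gene or signature
#'
#' Splits patients into high and low expression at the cohort median
#' (samples exactly at the median go to the low group - a deterministic
#' convention), fits a Cox proportional-hazards model for high versus low,
#' and computes Kaplan-Meier product-limit curves per group. Cox fitting and
#' the product-limit estimator come from the survival package; this stage
#' only contributes the split, the signature scoring, and the orchestration.
#'
#' @param expression Genes-by-samples numeric matrix.
#' @param gene_or_signature A single gene symbol, or a character vector of
#'   genes scored with [signature_score()].
#' @param survival_table Data frame with columns `sample_id`, `time`,
#'   `event` (1 = relapse, 0 = censored); sample IDs must be columns of
#'   `expression`.
#' @return An object of class `survival_result`: list with `result` (one-row
#'   data frame: `gene_or_signature`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `n_high`, `n_low`), `fit` (the `coxph` fit), and `km` (a
#'   `survfit` object with one stratum per group).
#' @export
median_split_survival <- function(expression, gene_or_signature, survival_table) {
  required <- c("sample_id", "time", "event")
  if (!all(required %in% names(survival_table))) {
    stop("survival_table needs columns sample_id, time, event", call. = FALSE)
  }
  missing_ids <- setdiff(survival_table$sample_id, colnames(expression))
  if (length(missing_ids)) {
    stop(sprintf("survival sample IDs absent from expression matrix: %s",
                 paste(utils::head(missing_ids, 3), collapse = ", ")),
         call. = FALSE)
  }
  score <- if (length(gene_or_signature) == 1 &&
               gene_or_signature %in% rownames(expression)) {
    stats::setNames(as.numeric(expression[gene_or_signature, ]),
                    colnames(expression))
  } else {
    signature_score(expression, gene_or_signature)
  }
  score <- score[survival_table$sample_id]
  med <- stats::median(score)
  group <- factor(ifelse(score > med, "high", "low"), levels = c("low", "high"))
  if (length(unique(group)) < 2) {
    stop("degenerate split: expression is constant across the cohort",
         call. = FALSE)
  }
  if (min(tapply(survival_table$event, group, sum)) < 2) {
    stop("each expression group needs at least 2 events", call. = FALSE)
  }
  sv <- survival::Surv(survival_table$time, survival_table$event)
  fit <- survival::coxph(sv ~ group)
  sm <- summary(fit)
  km <- survival::survfit(sv ~ group)
  structure(
    list(
      result = data.frame(
        gene_or_signature = paste(gene_or_signature, collapse = "+"),
        hazard_ratio = unname(sm$conf.int[1, "exp(coef)"]),
        ci_low = unname(sm$conf.int[1, "lower .95"]),
        ci_high = unname(sm$conf.int[1, "upper .95"]),
        p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
        n_high = sum(group == "high"),
        n_low = sum(group == "low"),
        stringsAsFactors = FALSE
      ),
      fit = fit,
      km = km
    ),
    class = "survival_result"
  )
}

#' @export
print.survival_result <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "%s: HR (high vs low) %.2f [%.2f-%.2f], p = %.3g (n = %d high / %d low)\n",
    r$gene_or_signature, r$hazard_ratio, r$ci_low, r$ci_high, r$p_value,
    r$n_high, r$n_low
  ))
  invisible(x)
}
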