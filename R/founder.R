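#' Parameters for founder-mutation calling and pattern classification
#'
#' @param window_percent Width (in VAF percentage points) of the frequency
#'   window below a candidate founder within which at least half of the
#'   subsequent mutations must fall for the candidate to qualify. Default 30.
#' @param min_founder_vaf Minimum VAF (percent) for a repair-gene mutation to
#'   be considered a founder candidate. Default 50: early truncal events sit
#'   at or above the heterozygous-diploid ceiling once copy-number gains or
#'   loss of heterozygosity inflate the mutant-read fraction.
#' @param min_subsequent Minimum number of subsequent (lower-VAF) mutations
#'   required before the window rule is meaningful; samples with very few
#'   mutations give unreliable spectra. Default 10.
#' @param top_k Number of qualifying founder genes retained per sample.
#'   Default 3.
#' @param smoothing_window Width, in histogram bins, of the centered moving
#'   average applied before peak finding. Default 5.
#' @param peak_min_fraction Minimum smoothed bin height, as a fraction of the
#'   sample's mutation count, for a local maximum to count as an expansion
#'   peak. Default 0.02: binomial read-sampling noise at ~100x depth spreads
#'   a clone over roughly a dozen 1-percent bins, capping the peak bin at
#'   about 8 percent of the clone's mutations, so 2 percent of the total
#'   separates genuine subclone peaks (even one of two equal subclones) from
#'   diffuse background.
#' @param vaf_floor Lowest VAF (percent) considered during pattern
#'   classification; bins below it are dominated by sequencing-error
#'   artifacts near the detection limit. Default 5.
#' @param peak_separation Minimum distance in bins between two local maxima
#'   for a spectrum to count as double/multiple rather than one broad peak.
#'   Default 10.
#' @return An object of class `founder_params`.
#' @export
founder_params <- function(window_percent = 30,
                           min_founder_vaf = 50,
                           min_subsequent = 10,
                           top_k = 3,
                           smoothing_window = 5,
                           peak_min_fraction = 0.02,
                           vaf_floor = 5,
                           peak_separation = 10) {
  stopifnot(
    window_percent > 0, window_percent <= 100,
    min_founder_vaf > 0, min_subsequent > 0, top_k > 0,
    smoothing_window > 0, peak_min_fraction > 0, vaf_floor >= 0,
    peak_separation > 0
  )
  structure(
    list(
      window_percent = window_percent, min_founder_vaf = min_founder_vaf,
      min_subsequent = min_subsequent, top_k = top_k,
      smoothing_window = smoothing_window, peak_min_fraction = peak_min_fraction,
      vaf_floor = vaf_floor, peak_separation = peak_separation
    ),
    class = "founder_params"
  )
}

#' Variant-allele-frequency histogram of a sample
#'
#' Bins a sample's mutation VAFs (percent) over \[0, 100\]. Bins are
#' half-open `[lo, hi)` except the last, which is closed so that VAF 100
#' is counted. Counts always sum to the number of mutations.
#'
#' @param profile A `sample_profile`.
#' @param bin_width Bin width in VAF percentage points; must divide 100.
#'   Default 1.
#' @return An object of class `vaf_histogram`: list with `bin_width`,
#'   `breaks`, `counts`, and `n_mutations`.
#' @export
vaf_histogram <- function(profile, bin_width = 1) {
  stopifnot(inherits(profile, "sample_profile"))
  if (profile$burden == 0) {
    stop(sprintf("sample %s has no mutations; histogram undefined",
                 profile$sample_id), call. = FALSE)
  }
  if (100 %% bin_width != 0) stop("bin_width must divide 100", call. = FALSE)
  n_bins <- ceiling(100 / bin_width)
  v <- profile$records$vaf_percent
  idx <- pmin(floor(v / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(
      bin_width = bin_width,
      breaks = seq(0, 100, by = bin_width),
      counts = counts,
      n_mutations = length(v)
    ),
    class = "vaf_histogram"
  )
}

#' @export
print.vaf_histogram <- function(x, ...) {
  cat(sprintf("VAF histogram: %d mutations in %d bins of %g%%\n",
              x$n_mutations, length(x$counts), x$bin_width))
  invisible(x)
}

#' Plot a VAF histogram with optional founder annotation
#'
#' @param x A `vaf_histogram`.
#' @param founder_vaf Optional VAF (percent) at which to draw a founder
#'   arrow.
#' @param main Plot title.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.vaf_histogram <- function(x, founder_vaf = NULL, main = "VAF spectrum", ...) {
  mids <- x$breaks[-length(x$breaks)] + x$bin_width / 2
  graphics::barplot(x$counts, names.arg = ifelse(mids %% 10 < x$bin_width,
                                                 round(mids), NA),
                    space = 0, border = NA, col = "grey40",
                    xlab = "mutation frequency (%)", ylab = "mutations",
                    main = main, ...)
  if (!is.null(founder_vaf)) {
    xpos <- founder_vaf / x$bin_width
    graphics::arrows(xpos, max(x$counts) * 0.9, xpos, max(x$counts) * 0.6,
                     col = "red", length = 0.1, lwd = 2)
  }
  invisible(x)
}

# centered moving average; edges use the partial window
smooth_counts <- function(counts, window) {
  if (window <= 1) return(as.numeric(counts))
  half <- floor(window / 2)
  n <- length(counts)
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Candidate founder mutations of a sample
#'
#' A founder candidate is a DNA-repair gene mutation whose VAF is at least
#' `min_founder_vaf` percent and strictly greater than the sample's median
#' VAF: an early event present in all descendant cells shows a higher
#' mutant-read proportion than the bulk of later mutations. When a gene has
#' several qualifying records its highest-VAF record is used. Candidates are
#' ordered by VAF, descending.
#'
#' @param profile A `sample_profile` (quality-filtered records).
#' @param gene_sets A `pathway_gene_sets` object.
#' @param params A [founder_params()] object.
#' @return Data frame with columns `gene`, `founder_vaf` (possibly empty).
#' @export
candidate_founders <- function(profile, gene_sets,
                               params = founder_params()) {
  stopifnot(inherits(profile, "sample_profile"),
            inherits(gene_sets, "pathway_gene_sets"))
  rec <- profile$records
  if (!nrow(rec)) return(data.frame(gene = character(), founder_vaf = numeric()))
  med <- stats::median(rec$vaf_percent)
  cand <- rec[rec$gene %in% gene_sets$all_repair_genes &
                rec$vaf_percent >= params$min_founder_vaf &
                rec$vaf_percent > med, , drop = FALSE]
  if (!nrow(cand)) return(data.frame(gene = character(), founder_vaf = numeric()))
  best <- tapply(cand$vaf_percent, cand$gene, max)
  out <- data.frame(gene = names(best), founder_vaf = as.numeric(best),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$founder_vaf, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the founder frequency-window rule to one candidate
#'
#' Subsequent mutations are all records with VAF strictly below the
#' candidate's VAF (the candidate's own record excluded); lower VAF is the
#' proxy for later occurrence. The candidate qualifies as a founder when at
#' least half of the subsequent mutations fall inside the open window
#' `(founder_vaf - window_percent, founder_vaf)` and there are at least
#' `min_subsequent` subsequent mutations.
#'
#' @param profile A `sample_profile`.
#' @param gene Candidate gene symbol.
#' @param founder_vaf Candidate VAF in percent.
#' @param params A [founder_params()] object.
#' @param classify Also classify the sample's clonal-expansion pattern
#'   (adds a `pattern` column). Default `TRUE`.
#' @return One-row data frame with columns `sample_id`, `gene`,
#'   `founder_vaf`, `n_subsequent`, `n_subsequent_in_window`, `window_lo`,
#'   `window_hi`, `qualifies`, `pattern`.
#' @export
call_founder <- function(profile, gene, founder_vaf,
                         params = founder_params(), classify = TRUE) {
  stopifnot(inherits(profile, "sample_profile"))
  v <- profile$records$vaf_percent
  own <- which(profile$records$gene == gene & v == founder_vaf)
  if (length(own)) v <- v[-own[1]]
  subsequent <- v[v < founder_vaf]
  lo <- founder_vaf - params$window_percent
  n_in <- sum(subsequent > lo & subsequent < founder_vaf)
  n_sub <- length(subsequent)
  qualifies <- n_sub >= params$min_subsequent && n_in >= ceiling(n_sub / 2)
  pattern <- NA_character_
  if (classify && profile$burden > 0) {
    pattern <- classify_pattern(vaf_histogram(profile), founder_vaf, params)
  }
  data.frame(
    sample_id = profile$sample_id, gene = gene, founder_vaf = founder_vaf,
    n_subsequent = n_sub, n_subsequent_in_window = n_in,
    window_lo = lo, window_hi = founder_vaf,
    qualifies = qualifies, pattern = pattern,
    stringsAsFactors = FALSE
  )
}

#' Classify the clonal-expansion pattern of a VAF spectrum
#'
#' Works on the part of the histogram strictly below the founder VAF and at
#' or above the VAF floor. Counts are smoothed with a centered moving
#' average, then:
#'
#' 1. **exponential** - smoothed counts are non-increasing with increasing
#'    VAF across at least 60 percent of adjacent bin pairs, and the maximum
#'    lies in the lowest quartile of the restricted range (and reaches the
#'    peak height threshold). Checked first, because an exponential decay
#'    also contains a formal local maximum at its low end.
#' 2. Otherwise, local maxima with smoothed height of at least
#'    `peak_min_fraction * n_mutations` are collected; maxima closer than
#'    `peak_separation` bins are merged (highest kept). Zero peaks is
#'    **neutral**, one is **single**, two or more is **double_or_multiple**.
#'
#' @param hist A [vaf_histogram()] built from the same profile.
#' @param founder_vaf Founder VAF in percent; must lie in (0, 100].
#' @param params A [founder_params()] object.
#' @return One of `"neutral"`, `"single"`, `"double_or_multiple"`,
#'   `"exponential"`.
#' @export
classify_pattern <- function(hist, founder_vaf, params = founder_params()) {
  stopifnot(inherits(hist, "vaf_histogram"))
  if (!is.finite(founder_vaf) || founder_vaf <= 0 || founder_vaf > 100) {
    stop("founder_vaf must lie in (0, 100]", call. = FALSE)
  }
  bw <- hist$bin_width
  lo_edges <- hist$breaks[-length(hist$breaks)]
  hi_edges <- hist$breaks[-1]
  keep <- lo_edges >= params$vaf_floor & hi_edges <= founder_vaf
  if (!any(keep)) return("neutral")
  s <- smooth_counts(hist$counts, params$smoothing_window)[keep]
  n <- length(s)
  threshold <- params$peak_min_fraction * hist$n_mutations
  if (max(s) < threshold) return("neutral")

  # exponential: mass piled against the low-VAF end, decaying upward
  if (n >= 4) {
    nonincreasing <- mean(s[-n] >= s[-1] - 1e-9)
    max_pos <- which.max(s)
    if (nonincreasing >= 0.6 && max_pos <= ceiling(n / 4)) {
      return("exponential")
    }
  }

  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  is_peak <- s > left & s >= right & s >= threshold
  peaks <- which(is_peak)
  if (!length(peaks)) return("neutral")
  # merge maxima closer than peak_separation bins, keeping the highest
  peaks <- peaks[order(-s[peaks])]
  kept <- integer()
  for (p in peaks) {
    if (!length(kept) || all(abs(kept - p) >= params$peak_separation)) {
      kept <- c(kept, p)
    }
  }
  if (length(kept) == 1) "single" else "double_or_multiple"
}

#' Founder calls for every candidate of a sample
#'
#' Runs [candidate_founders()] and [call_founder()] for each candidate.
#'
#' @inheritParams candidate_founders
#' @param classify Classify the expansion pattern per call.
#' @return Data frame of founder calls (possibly zero rows).
#' @export
analyze_sample_founders <- function(profile, gene_sets,
                                    params = founder_params(),
                                    classify = TRUE) {
  cand <- candidate_founders(profile, gene_sets, params)
  if (!nrow(cand)) return(empty_founder_calls())
  hist <- if (classify) vaf_histogram(profile) else NULL
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    call <- call_founder(profile, cand$gene[i], cand$founder_vaf[i],
                         params, classify = FALSE)
    call$pattern <- if (classify) {
      classify_pattern(hist, cand$founder_vaf[i], params)
    } else NA_character_
    call
  })
  do.call(rbind, rows)
}

empty_founder_calls <- function() {
  data.frame(
    sample_id = character(), gene = character(), founder_vaf = numeric(),
    n_subsequent = integer(), n_subsequent_in_window = integer(),
    window_lo = numeric(), window_hi = numeric(),
    qualifies = logical(), pattern = character(),
    stringsAsFactors = FALSE
  )
}

#' Select a sample's top founder calls
#'
#' Keeps the qualifying calls with the highest founder VAF, at most `top_k`
#' per sample; ties are broken alphabetically by gene symbol.
#'
#' @param calls Data frame of founder calls for one sample.
#' @param params A [founder_params()] object.
#' @return At most `top_k` rows of `calls`.
#' @export
select_top_founders <- function(calls, params = founder_params()) {
  calls <- calls[calls$qualifies, , drop = FALSE]
  if (!nrow(calls)) return(calls)
  calls <- calls[order(-calls$founder_vaf, calls$gene), , drop = FALSE]
  out <- utils::head(calls, params$top_k)
  rownames(out) <- NULL
  out
}

#' Cohort-level founder summary
#'
#' Runs founder detection on every sample and counts, per gene, the number
#' of samples in whose top-k qualifying calls the gene appears, together
#' with the median and range of its founder VAFs.
#'
#' @param profiles A `sample_profiles` list.
#' @param gene_sets A `pathway_gene_sets` object.
#' @param params A [founder_params()] object.
#' @return A list with `summary` (data frame: `gene`, `n_samples`,
#'   `median_vaf`, `min_vaf`, `max_vaf`, sorted by `n_samples` descending)
#'   and `calls` (data frame of all selected top calls).
#' @export
cohort_founder_summary <- function(profiles, gene_sets,
                                   params = founder_params()) {
  top <- lapply(profiles, function(p) {
    if (p$burden == 0) return(empty_founder_calls())
    select_top_founders(analyze_sample_founders(p, gene_sets, params), params)
  })
  calls <- do.call(rbind, c(top, list(empty_founder_calls())))
  rownames(calls) <- NULL
  if (!nrow(calls)) {
    return(list(
      summary = data.frame(gene = character(), n_samples = integer(),
                           median_vaf = numeric(), min_vaf = numeric(),
                           max_vaf = numeric(), stringsAsFactors = FALSE),
      calls = calls
    ))
  }
  agg <- split(calls$founder_vaf, calls$gene)
  summary <- data.frame(
    gene = names(agg),
    n_samples = vapply(agg, length, integer(1)),
    median_vaf = vapply(agg, stats::median, numeric(1)),
    min_vaf = vapply(agg, min, numeric(1)),
    max_vaf = vapply(agg, max, numeric(1)),
    stringsAsFactors = FALSE
  )
  summary <- summary[order(-summary$n_samples, summary$gene), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, calls = calls)
}
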