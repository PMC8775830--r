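#' @keywords internal
"_PACKAGE"

# Canonical column set for a mutation table. `vaf_percent` is always
# recomputed from depths, never trusted from the input file.
MUTATION_COLUMNS <- c(
  "sample_id", "gene", "chrom", "pos", "ref", "alt",
  "variant_class", "total_depth", "alt_depth", "vaf_percent"
)

VARIANT_CLASSES <- c(
  "missense", "frameshift_ins", "frameshift_del",
  "nonsense", "splice", "silent", "other"
)

# MAF Variant_Classification -> internal categories
MAF_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Frame_Shift_Ins   = "frameshift_ins",
  Frame_Shift_Del   = "frameshift_del",
  Nonsense_Mutation = "nonsense",
  Splice_Site       = "splice",
  Splice_Region     = "splice",
  Silent            = "silent"
)

#' Quality-filter policy for somatic mutation calls
#'
#' Read-support thresholds applied to every call before burden or founder
#' analysis: a minimum total coverage at the locus and a minimum number of
#' reads supporting the mutant allele. Defaults are 50x total coverage with
#' at least 5 mutant reads.
#'
#' @param min_total_depth Minimum total read depth at the mutated locus.
#' @param min_alt_depth Minimum number of reads carrying the mutant allele.
#' @return An object of class `quality_filter_policy`.
#' @examples
#' quality_filter_policy()
#' quality_filter_policy(min_total_depth = 30, min_alt_depth = 3)
#' @export
quality_filter_policy <- function(min_total_depth = 50, min_alt_depth = 5) {
  stopifnot(
    is.numeric(min_total_depth), length(min_total_depth) == 1, min_total_depth >= 0,
    is.numeric(min_alt_depth), length(min_alt_depth) == 1, min_alt_depth >= 0
  )
  structure(
    list(min_total_depth = min_total_depth, min_alt_depth = min_alt_depth),
    class = "quality_filter_policy"
  )
}

#' @export
print.quality_filter_policy <- function(x, ...) {
  cat(sprintf(
    "Quality filter: total depth >= %g, mutant reads >= %g\n",
    x$min_total_depth, x$min_alt_depth
  ))
  invisible(x)
}

validate_mutation_records <- function(df, source = "input") {
  num_cols <- c("pos", "total_depth", "alt_depth")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  chr_cols <- c("sample_id", "gene", "chrom", "ref", "alt", "variant_class")
  for (cl in chr_cols) df[[cl]] <- as.character(df[[cl]])

  bad <- which(!is.finite(df$total_depth) | df$total_depth <= 0)
  if (length(bad)) {
    stop(sprintf(
      "%s: record %d has total_depth %s; loci without coverage have undefined mutation frequency",
      source, bad[1], format(df$total_depth[bad[1]])
    ), call. = FALSE)
  }
  bad <- which(!is.finite(df$alt_depth) | df$alt_depth < 0)
  if (length(bad)) {
    stop(sprintf("%s: record %d has invalid alt_depth", source, bad[1]), call. = FALSE)
  }
  bad <- which(df$alt_depth > df$total_depth)
  if (length(bad)) {
    stop(sprintf(
      "%s: record %d has alt_depth (%g) > total_depth (%g)",
      source, bad[1], df$alt_depth[bad[1]], df$total_depth[bad[1]]
    ), call. = FALSE)
  }
  bad <- which(!is.finite(df$pos) | df$pos < 1)
  if (length(bad)) {
    stop(sprintf("%s: record %d has position < 1", source, bad[1]), call. = FALSE)
  }
  df$variant_class[!df$variant_class %in% VARIANT_CLASSES] <- "other"
  df$vaf_percent <- 100 * df$alt_depth / df$total_depth
  rownames(df) <- NULL
  df[, MUTATION_COLUMNS]
}

empty_mutation_table <- function() {
  df <- data.frame(
    sample_id = character(), gene = character(), chrom = character(),
    pos = numeric(), ref = character(), alt = character(),
    variant_class = character(), total_depth = numeric(),
    alt_depth = numeric(), vaf_percent = numeric(),
    stringsAsFactors = FALSE
  )
  df
}

require_columns <- function(found, required, path) {
  missing <- setdiff(required, found)
  if (length(missing)) {
    stop(sprintf(
      "%s: missing required column: %s",
      basename(path), paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
}

#' Read a somatic mutation table
#'
#' Reads somatic mutation calls into the canonical mutation-record table.
#' Three dialects are supported:
#'
#' * `simple_tsv` - the package's canonical 9-column tab-separated format
#'   (`sample_id`, `gene`, `chrom`, `pos`, `ref`, `alt`, `variant_class`,
#'   `total_depth`, `alt_depth`), also what [write_mutation_table()] and the
#'   simulator emit.
#' * `maf` - TCGA-style Mutation Annotation Format. Standard column names
#'   are accepted but only the fields above are consumed; `t_depth` is taken
#'   if present, otherwise `t_ref_count + t_alt_count`. Lines starting with
#'   `#` are skipped.
#' * `vcf` - read-only VCF with AD-style allele depths in the genotype
#'   field; multi-allelic sites produce one record per alternate allele.
#'   Gene symbols are taken from a `GENE=` INFO key when present.
#'
#' Mutation frequency (VAF, in percent) is computed as
#' `100 * alt_depth / total_depth` for every record. Records with zero total
#' depth are rejected (their frequency is undefined), as are records with
#' more mutant reads than coverage; errors name the offending record.
#' Coordinates are 1-based inclusive; strand is ignored.
#'
#' @param path Path to the mutation file.
#' @param dialect One of `"simple_tsv"`, `"maf"`, `"vcf"`.
#' @return A data frame of mutation records with columns
#'   `sample_id, gene, chrom, pos, ref, alt, variant_class, total_depth,
#'   alt_depth, vaf_percent`.
#' @seealso [apply_quality_filters()], [write_mutation_table()]
#' @export
read_mutation_table <- function(path, dialect = c("simple_tsv", "maf", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  switch(dialect,
    simple_tsv = read_simple_tsv(path),
    maf = read_maf(path),
    vcf = read_vcf(path)
  )
}

read_simple_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  required <- setdiff(MUTATION_COLUMNS, "vaf_percent")
  require_columns(names(df), required, path)
  if (nrow(df) == 0) return(empty_mutation_table())
  validate_mutation_records(df[, required], source = basename(path))
}

read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  required <- c(
    "Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome", "Start_Position",
    "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification",
    "t_alt_count"
  )
  require_columns(names(df), required, path)
  if (!"t_depth" %in% names(df) && !"t_ref_count" %in% names(df)) {
    stop(sprintf("%s: missing required column: t_depth (or t_ref_count)",
                 basename(path)), call. = FALSE)
  }
  if (nrow(df) == 0) return(empty_mutation_table())
  total <- if ("t_depth" %in% names(df)) {
    as.numeric(df$t_depth)
  } else {
    as.numeric(df$t_ref_count) + as.numeric(df$t_alt_count)
  }
  vc <- MAF_CLASS_MAP[df$Variant_Classification]
  vc[is.na(vc)] <- "other"
  out <- data.frame(
    sample_id = df$Tumor_Sample_Barcode,
    gene = df$Hugo_Symbol,
    chrom = as.character(df$Chromosome),
    pos = as.numeric(df$Start_Position),
    ref = df$Reference_Allele,
    alt = df$Tumor_Seq_Allele2,
    variant_class = unname(vc),
    total_depth = total,
    alt_depth = as.numeric(df$t_alt_count),
    stringsAsFactors = FALSE
  )
  validate_mutation_records(out, source = basename(path))
}

read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) return(empty_mutation_table())
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) {
    stop(sprintf("%s: missing required column: AD (allele depths in FORMAT)",
                 basename(path)), call. = FALSE)
  }
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  info <- unname(v@fix[, "INFO"])
  genes <- info_field(info, "GENE")
  classes <- info_field(info, "CLASS")
  genes[is.na(genes)] <- "."
  classes[is.na(classes) | !classes %in% VARIANT_CLASSES] <- "other"

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (s in colnames(ad)) {
      depths <- suppressWarnings(as.numeric(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
      if (all(is.na(depths))) next
      total <- sum(depths, na.rm = TRUE)
      for (k in seq_along(alts)) {
        altd <- depths[k + 1]
        if (is.na(altd) || altd == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = s, gene = genes[i], chrom = fix[i, "CHROM"],
          pos = as.numeric(fix[i, "POS"]), ref = fix[i, "REF"], alt = alts[k],
          variant_class = classes[i], total_depth = total, alt_depth = altd,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(empty_mutation_table())
  validate_mutation_records(do.call(rbind, rows), source = basename(path))
}

#' Write a mutation table in the canonical simple_tsv dialect
#'
#' @param records Mutation-record data frame (see [read_mutation_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  cols <- setdiff(MUTATION_COLUMNS, "vaf_percent")
  stopifnot(all(cols %in% names(records)))
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply read-support quality filters to mutation records
#'
#' Retains exactly the records with `total_depth >= min_total_depth` and
#' `alt_depth >= min_alt_depth`; input order is preserved. The numbers of
#' retained and removed records are attached as attributes `n_retained` and
#' `n_removed`.
#'
#' @param records Mutation-record data frame.
#' @param policy A [quality_filter_policy()].
#' @return The filtered data frame.
#' @examples
#' recs <- data.frame(
#'   sample_id = "S1", gene = "TP53", chrom = "17", pos = 1:2,
#'   ref = "A", alt = "T", variant_class = "missense",
#'   total_depth = c(60, 49), alt_depth = c(30, 10),
#'   vaf_percent = c(50, 100 * 10 / 49)
#' )
#' kept <- apply_quality_filters(recs, quality_filter_policy())
#' attr(kept, "n_removed")
#' @export
apply_quality_filters <- function(records, policy = quality_filter_policy()) {
  stopifnot(inherits(policy, "quality_filter_policy"))
  keep <- records$total_depth >= policy$min_total_depth &
    records$alt_depth >= policy$min_alt_depth
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}
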