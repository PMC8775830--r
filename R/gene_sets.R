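PATHWAY_NAMES <- c("BER", "NER", "MMR", "HR", "NHEJ")

#' Load DNA-repair pathway gene sets
#'
#' Reads a YAML configuration mapping the five DNA-repair pathways to gene
#' symbols: base-excision repair (BER), nucleotide-excision repair (NER),
#' mismatch repair (MMR), homologous recombination (HR), and non-homologous
#' end joining (NHEJ). With `path = NULL` the packaged default is used: a
#' curated, versioned list built from the KEGG repair maps (base-excision
#' repair, nucleotide-excision repair, mismatch repair, and the two
#' double-strand-break maps), extended with recurrent double-strand-break
#' signaling and chromatin-remodeling factors (e.g. ATM, SRCAP) that travel
#' with the HR machinery.
#'
#' The file must define exactly the five pathway names above, each with at
#' least one gene. A gene may belong to several pathways (many replication
#' factors do); duplicates within one pathway raise a warning and are
#' deduplicated.
#'
#' @param path Path to a YAML gene-set file, or `NULL` for the packaged
#'   default.
#' @return An object of class `pathway_gene_sets`: a list with elements
#'   `pathways` (named list of character vectors), `all_repair_genes`
#'   (deduplicated union), and `version`.
#' @examples
#' gs <- load_gene_sets()
#' "PRKDC" %in% gs$pathways$NHEJ
#' @export
load_gene_sets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dna_repair_genesets.yaml",
                        package = "founderscan", mustWork = TRUE)
  }
  if (!file.exists(path)) stop(sprintf("gene-set file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pathways)) {
    stop("gene-set config must contain a 'pathways' mapping", call. = FALSE)
  }
  nm <- names(cfg$pathways)
  unknown <- setdiff(nm, PATHWAY_NAMES)
  if (length(unknown)) {
    stop(sprintf("unknown pathway name: %s (expected %s)",
                 paste(unknown, collapse = ", "),
                 paste(PATHWAY_NAMES, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(PATHWAY_NAMES, nm)
  if (length(missing)) {
    stop(sprintf("missing pathway: %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  pathways <- lapply(cfg$pathways, function(g) as.character(unlist(g)))
  for (p in PATHWAY_NAMES) {
    genes <- pathways[[p]]
    if (!length(genes)) stop(sprintf("pathway %s has no genes", p), call. = FALSE)
    if (anyDuplicated(genes)) {
      warning(sprintf("pathway %s lists duplicated genes; deduplicating", p),
              call. = FALSE)
      pathways[[p]] <- unique(genes)
    }
  }
  pathways <- pathways[PATHWAY_NAMES]
  structure(
    list(
      pathways = pathways,
      all_repair_genes = sort(unique(unlist(pathways, use.names = FALSE))),
      version = if (is.null(cfg$version)) "unversioned" else as.character(cfg$version)
    ),
    class = "pathway_gene_sets"
  )
}

#' @export
print.pathway_gene_sets <- function(x, ...) {
  cat(sprintf("DNA-repair pathway gene sets (%s): %d genes total\n",
              x$version, length(x$all_repair_genes)))
  for (p in names(x$pathways)) {
    cat(sprintf("  %-4s %3d genes\n", p, length(x$pathways[[p]])))
  }
  invisible(x)
}

#' Write pathway gene sets to a YAML file
#'
#' @param gene_sets A `pathway_gene_sets` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  stopifnot(inherits(gene_sets, "pathway_gene_sets"))
  yaml::write_yaml(
    list(version = gene_sets$version, pathways = gene_sets$pathways),
    path
  )
  invisible(path)
}
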