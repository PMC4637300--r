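# Offline effector-candidate ranking and generic gene-set
# over-representation (the self-contained replacements for live literature
# queries and proprietary pathway software).

#' Intersect a module with the most-cited genes
#'
#' Genes are ranked by their citation count (offline table); the cutoff
#' is the count at the ceiling(fraction * N)-th rank and every gene tied
#' at that count is included.  The intersection with the module's targets
#' is returned in deterministic order (count descending, then gene id).
#'
#' @param citations data.frame with columns `gene_id`, `count` (see
#'   [read_citation_counts()]); must cover >= 20 genes.
#' @param module `association_module` or character vector of gene ids.
#' @param fraction top fraction to retain (default 0.05).
#' @return character vector of module genes in the top-cited set.
#' @export
top_cited_intersection <- function(citations, module, fraction = 0.05) {
  if (is.null(citations) || nrow(citations) == 0) stopf("empty citation table")
  if (nrow(citations) < 20) stopf("citation table must cover >= 20 genes")
  genes <- if (inherits(module, "association_module")) module$targets else module
  ord <- citations[order(-citations$count, citations$gene_id), ]
  k <- ceiling(fraction * nrow(ord))
  cutoff <- ord$count[k]
  top <- ord[ord$count >= cutoff, ]
  top$gene_id[top$gene_id %in% genes]
}

#' Gene-set over-representation of module targets
#'
#' Right-tailed hypergeometric (Fisher exact) test of the overlap between
#' the module's targets and each gene set, against the measured-gene
#' background universe; Benjamini-Hochberg adjustment across all tested
#' sets.  A set is `reported` only when the adjusted p is below
#' `alpha` and the overlap exceeds `min_overlap` genes.
#'
#' @param module_targets character vector of target gene ids.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param background character vector: the gene universe (must contain
#'   all module targets).  Sets with no background overlap are skipped.
#' @param alpha reporting threshold on the BH-adjusted p (default 0.01).
#' @param min_overlap minimum overlap strictly required for reporting
#'   (default 4, i.e. reported needs overlap > 4).
#' @return data.frame: set_name, overlap_count, set_size, module_size,
#'   background_size, raw_p, bh_adjusted_p, reported.
#' @export
geneset_enrichment <- function(module_targets, gene_sets, background,
                               alpha = 0.01, min_overlap = 4) {
  background <- unique(background)
  module_targets <- unique(module_targets)
  if (!all(module_targets %in% background)) {
    stopf("background must contain all module targets")
  }
  N <- length(background)
  n <- length(module_targets)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(set, module_targets))
    # right tail: P(overlap >= k) under hypergeometric(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = K,
               module_size = n, background_size = N, raw_p = p)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(set_name = character(), overlap_count = integer(),
                      set_size = integer(), module_size = integer(),
                      background_size = integer(), raw_p = numeric(),
                      bh_adjusted_p = numeric(), reported = logical()))
  }
  rows$bh_adjusted_p <- stats::p.adjust(rows$raw_p, method = "BH")
  rows$reported <- rows$bh_adjusted_p < alpha & rows$overlap_count > min_overlap
  rows[order(rows$raw_p, rows$set_name), ]
}
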