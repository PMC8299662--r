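#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a query gene list relative
#' to a background universe: with `N` universe genes, `K` of them in the set,
#' a query of size `n` and `k` query genes in the set, the p-value is the
#' hypergeometric upper tail `P(X >= k)`. Benjamini-Hochberg adjusted
#' p-values are computed across all tested sets of the collection.
#'
#' Query genes outside the universe are dropped with a warning; gene sets are
#' intersected with the universe and sets with no universe member are
#' skipped. Symbols are uppercased for matching.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param gene_sets A `GeneSetCollection` (see [read_gene_sets_gmt()]) or a
#'   named list of character vectors.
#' @param universe_genes Character vector: the background universe, typically
#'   all genes measured in the expression matrix rather than the whole
#'   genome.
#' @return Data frame sorted by p-value then set name: `set_name`, `n_query`,
#'   `n_set`, `n_overlap`, `n_universe`, `p_value`, `adj_p`,
#'   `overlap_genes` (semicolon-separated).
#' @export
hypergeometric_enrichment <- function(query_genes, gene_sets, universe_genes) {
  universe <- unique(toupper(as.character(universe_genes)))
  if (!length(universe)) stop("empty universe")
  query <- unique(toupper(as.character(query_genes)))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("no query genes left after universe filtering")

  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(toupper(gene_sets[[nm]])), universe)
    if (!length(set)) return(NULL)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set_name = nm, n_query = length(query), n_set = length(set),
               n_overlap = k, n_universe = length(universe), p_value = p,
               overlap_genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(set_name = character(), n_query = integer(),
                      n_set = integer(), n_overlap = integer(),
                      n_universe = integer(), p_value = numeric(),
                      adj_p = numeric(), overlap_genes = character()))
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "n_query", "n_set", "n_overlap", "n_universe",
               "p_value", "adj_p", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Select top enriched terms
#'
#' First `k` results whose p-value is strictly below `p_threshold`, from a
#' result table already sorted by p-value then set name (ties are therefore
#' broken lexicographically, making the selection deterministic).
#'
#' @param results Data frame from [hypergeometric_enrichment()].
#' @param k Maximum number of terms (default 10).
#' @param p_threshold Strict significance cutoff (default 0.05).
#' @return The filtered data frame.
#' @export
top_terms <- function(results, k = 10, p_threshold = 0.05) {
  sig <- results[results$p_value < p_threshold, , drop = FALSE]
  utils::head(sig, k)
}
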