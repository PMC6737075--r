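#' Hypergeometric term enrichment
#'
#' Tests each annotation term for over-representation in a query gene set
#' drawn from a universe (by default the identified proteome, i.e. all
#' genes in the input count table). The p-value is the upper-tail
#' hypergeometric probability `P[X >= k]` of observing at least the seen
#' overlap when `n` query genes are drawn from a universe of `N` genes of
#' which `K` carry the term. Benjamini-Hochberg adjustment is applied
#' across the tested terms; terms with zero query overlap are untestable
#' hypotheses and are excluded from both the output and the adjustment
#' family. Gene matching is case-insensitive.
#'
#' @param query_genes Character vector of query gene symbols; must be a
#'   subset of `universe_genes`.
#' @param annotation Named list of gene sets (see [read_annotation()]).
#' @param universe_genes Character vector of all gene symbols under
#'   consideration.
#' @param adjust Apply Benjamini-Hochberg correction (`TRUE`, default); set
#'   `FALSE` to report raw p-values only (the adjusted column then equals
#'   the raw one).
#' @return Data.frame with one row per term having at least one query
#'   overlap: `term`, `universe_size`, `term_size`, `query_size`,
#'   `overlap`, `p_value`, `adj_p`, sorted by `adj_p` ascending with ties
#'   broken by term name.
#' @export
enrich_terms <- function(query_genes, annotation, universe_genes,
                         adjust = TRUE) {
  if (!length(universe_genes)) stop("empty universe", call. = FALSE)
  uni <- unique(toupper(universe_genes))
  qry <- unique(toupper(query_genes))
  offenders <- unique(query_genes[!toupper(query_genes) %in% uni])
  if (length(offenders))
    stop("query gene(s) absent from universe: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  N <- length(uni)
  n <- length(qry)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(unique(toupper(annotation[[term]])), uni)
    K <- length(genes)
    k <- length(intersect(genes, qry))
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, universe_size = N, term_size = K,
               query_size = n, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(), universe_size = integer(),
                      term_size = integer(), query_size = integer(),
                      overlap = integer(), p_value = numeric(),
                      adj_p = numeric(), stringsAsFactors = FALSE))
  res$adj_p <- if (adjust) bh_adjust(res$p_value) else res$p_value
  res <- res[order(res$adj_p, res$term), ]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, preserving input order
#' and capped at 1. Input values must lie in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Restrict a count table to the proteins annotated to a term
#'
#' Returns the sub-table of proteins whose gene symbol (case-insensitive)
#' is annotated to `term`, preserving input order. This is the selection
#' step that narrows the identified proteome to the structural proteins of
#' a significantly enriched cellular-component category before pattern
#' classification.
#'
#' @param term Term name; must exist in `annotation`.
#' @param annotation Named list of gene sets.
#' @param counts A count table (see [read_count_table()]).
#' @return The sub-table (possibly empty, with a warning).
#' @export
select_term_proteins <- function(term, annotation, counts) {
  if (!term %in% names(annotation))
    stop("unknown term '", term, "'", call. = FALSE)
  counts <- validate_count_table(counts)
  keep <- toupper(counts$gene_symbol) %in% toupper(annotation[[term]])
  if (!any(keep))
    warning("term '", term, "' covers no gene in the table; empty subset")
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
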