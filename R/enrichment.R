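#' Hypergeometric over-representation of gene sets in a query list
#'
#' Upper-tail hypergeometric test per set: with a universe of size N, a set
#' of size K (after intersection with the universe), a query of size n and
#' an overlap of k, the p-value is P(X >= k) for X hypergeometric(N, K, n).
#' Benjamini-Hochberg adjustment is applied across the tested sets.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param universe Character vector of background genes.
#' @param sets A `gene_set_collection` from [load_gene_sets()] (or a named
#'   list of character vectors). Sets with no member in the universe are
#'   dropped.
#' @param alpha FDR significance level for the `significant` flag.
#' @return Data frame of class `enrichment_table`, sorted by p-value:
#'   `set`, `overlap`, `set_size`, `query_size`, `universe_size`,
#'   `p_value`, `fdr`, `significant`.
#' @export
overrepresentation <- function(query, universe, sets, alpha = 0.05) {
  query <- unique(query); universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "))
  restricted <- lapply(sets, intersect, universe)
  restricted <- restricted[lengths(restricted) > 0]
  if (!length(restricted))
    return(structure(data.frame(set = character(), overlap = integer(),
                                set_size = integer(), query_size = integer(),
                                universe_size = integer(),
                                p_value = numeric(), fdr = numeric(),
                                significant = logical()),
                     class = c("enrichment_table", "data.frame")))
  N <- length(universe); n <- length(query)
  K <- lengths(restricted)
  k <- vapply(restricted, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(restricted), overlap = as.integer(k),
                    set_size = as.integer(K), query_size = n,
                    universe_size = N, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < alpha
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
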