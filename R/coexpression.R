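#' Critical Pearson correlation for a two-tailed test
#'
#' The smallest |r| significant at two-tailed level `alpha` with `df`
#' degrees of freedom (df = number of samples - 2), via the Student-t
#' inversion `r = t / sqrt(t^2 + df)` with `t` the two-tailed critical
#' value. Strictly decreasing in df and increasing as alpha decreases.
#'
#' @param df Positive integer degrees of freedom (vectorised).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return Critical |r| in (0, 1).
#' @examples
#' critical_r(10, 0.001) # 0.823
#' @export
critical_r <- function(df, alpha) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  tcrit <- stats::qt(alpha / 2, df, lower.tail = FALSE)
  tcrit / sqrt(tcrit^2 + df)
}

#' Coexpression partners of a key gene above a critical-correlation cut
#'
#' Pearson correlation between the key gene and every candidate partner
#' across the samples of the two requested groups, on the log2(FPKM +
#' pseudocount) scale. Partners at or above the threshold are flagged
#' (the analytic critical r for the realised sample size by default, with
#' an inclusive comparison); ranks order by |r| descending with
#' alphabetical tie-break. The key gene is excluded from its own list.
#'
#' @param key_gene Gene symbol present in the matrix.
#' @param partners Character vector of candidate partner symbols (e.g. the
#'   DEGs of the contrast); must be present in the matrix.
#' @param em An [expression_matrix()].
#' @param groups Character pair of groups whose samples are used.
#' @param alpha Two-tailed level for the default threshold (default 0.001).
#' @param threshold Optional explicit |r| cut; overrides `alpha`.
#' @param top_k Optional; return only the top k rows by |r| (the
#'   `n_passing` attribute still counts all flagged partners).
#' @param pseudocount Offset for the log transform.
#' @return Data frame of class `coexpression_result`: `key_gene`,
#'   `partner`, `r`, `abs_r`, `passes`, `rank`; attributes `threshold`,
#'   `n_samples`, `n_passing`.
#' @export
coexpressed_partners <- function(key_gene, partners, em,
                                 groups = c("C", "AD"), alpha = 0.001,
                                 threshold = NULL, top_k = NULL,
                                 pseudocount = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!key_gene %in% rownames(em$values))
    stop("key gene absent from matrix: ", key_gene)
  absent <- setdiff(partners, rownames(em$values))
  if (length(absent))
    stop("partner gene(s) absent from matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  partners <- setdiff(unique(partners), key_gene)
  samples <- group_samples(em, groups)
  n <- length(samples)
  if (n < 3) stop("need at least 3 samples to correlate")
  if (is.null(threshold)) threshold <- critical_r(n - 2, alpha)
  lx <- log2(em$values[c(key_gene, partners), samples, drop = FALSE] +
               pseudocount)
  r <- drop(stats::cor(lx[key_gene, ], t(lx[partners, , drop = FALSE])))
  out <- data.frame(key_gene = key_gene, partner = partners,
                    r = r, abs_r = abs(r),
                    passes = abs(r) >= threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_r, out$partner), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  n_passing <- sum(out$passes)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  attr(out, "threshold") <- threshold
  attr(out, "n_samples") <- n
  attr(out, "n_passing") <- n_passing
  class(out) <- c("coexpression_result", "data.frame")
  out
}

#' Propagate behavior-term hypotheses from key genes to their partners
#'
#' Every partner flagged against at least one key gene inherits that key
#' gene's behavior terms as hypotheses; terms the partner already carries
#' itself are reported as known instead. Partners correlated with a single
#' key gene inherit only that gene's terms.
#'
#' @param results A `coexpression_result` (possibly the row-bind of results
#'   for several key genes).
#' @param annotation A `gene_annotation` table covering key genes and
#'   partners.
#' @return Data frame: `partner`, `key_genes` (pipe-delimited), `known_terms`
#'   (inherited terms the partner is already annotated with),
#'   `hypothesis_terms` (inherited terms new to the partner), both
#'   pipe-delimited.
#' @export
propagate_terms <- function(results, annotation) {
  stopifnot(inherits(results, "coexpression_result") ||
              is.data.frame(results))
  flagged <- results[results$passes, , drop = FALSE]
  if (!nrow(flagged))
    return(data.frame(partner = character(), key_genes = character(),
                      known_terms = character(),
                      hypothesis_terms = character(),
                      stringsAsFactors = FALSE))
  key_terms <- function(g) {
    i <- match(g, annotation$gene)
    if (is.na(i)) character() else split_terms(annotation$behavior_terms[i])[[1]]
  }
  partners <- sort(unique(flagged$partner))
  rows <- lapply(partners, function(p) {
    keys <- sort(unique(flagged$key_gene[flagged$partner == p]))
    inherited <- sort(unique(unlist(lapply(keys, key_terms))))
    own <- key_terms(p)
    data.frame(partner = p,
               key_genes = paste(keys, collapse = "|"),
               known_terms = paste(intersect(inherited, own), collapse = "|"),
               hypothesis_terms = paste(setdiff(inherited, own),
                                        collapse = "|"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
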