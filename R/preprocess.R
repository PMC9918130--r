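#' Log-transform and row-standardize an FPKM matrix
#'
#' Applies `log2(FPKM + pseudocount)` and then centres and scales every gene
#' row to mean 0 and unit sample SD (n - 1 denominator). Genes with zero
#' variance after the log step carry no contrast information and are dropped
#' with a message.
#'
#' @param em An [expression_matrix()] of non-negative FPKM values.
#' @param pseudocount Positive offset added before the log; default 1.
#' @return An object of class `processed_matrix`: list with `values`
#'   (genes x samples, row-standardized), `design`, `pseudocount` and
#'   `dropped` (IDs of zero-variance genes removed).
#' @export
preprocess <- function(em, pseudocount = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a positive scalar")
  lx <- log2(em$values + pseudocount)
  sds <- apply(lx, 1, stats::sd)
  keep <- sds > 0
  dropped <- rownames(lx)[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " zero-variance gene(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  if (!any(keep)) stop("all genes have zero variance; nothing to process")
  z <- (lx[keep, , drop = FALSE] -
          rowMeans(lx[keep, , drop = FALSE])) / sds[keep]
  structure(list(values = z, design = em$design,
                 pseudocount = pseudocount, dropped = dropped),
            class = "processed_matrix")
}

#' Principal coordinate analysis of samples
#'
#' Classical metric multidimensional scaling of the Euclidean distances
#' between sample columns of a processed matrix (Gower double-centring
#' eigendecomposition, via [stats::cmdscale()]). Each axis is oriented so
#' the first sample's coordinate is non-negative, for reproducibility.
#'
#' @param processed A `processed_matrix` from [preprocess()].
#' @param n_axes Number of axes to retain (capped at samples - 1).
#' @return List of class `pcoa_result`: `points` (samples x axes),
#'   `eig` (all eigenvalues, non-increasing), `prop_var` (share of the
#'   positive eigenvalue total per retained axis).
#' @export
pcoa <- function(processed, n_axes = 2) {
  stopifnot(inherits(processed, "processed_matrix"))
  ns <- ncol(processed$values)
  if (ns < 2) stop("principal coordinate analysis needs at least 2 samples")
  k <- min(n_axes, ns - 1)
  d <- stats::dist(t(processed$values))
  mds <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- mds$points
  if (is.null(pts) || ncol(pts) == 0)
    stop("no positive-eigenvalue axes available")
  for (j in seq_len(ncol(pts)))
    if (pts[1, j] < 0) pts[, j] <- -pts[, j]
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  pos <- sum(mds$eig[mds$eig > 0])
  structure(list(points = pts, eig = mds$eig,
                 prop_var = mds$eig[seq_len(ncol(pts))] / pos),
            class = "pcoa_result")
}
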