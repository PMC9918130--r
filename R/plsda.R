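#' Build a centred two-group dummy block
#'
#' Samples of the two requested groups, in matrix order, coded by a
#' samples x 2 indicator matrix; every row of the raw indicator sums to 1
#' and every column of the centred block sums to 0.
#'
#' @param design Named factor or character vector mapping sample to group.
#' @param groups Character pair `c(reference, experimental)`.
#' @return List of class `dummy_block`: `indicator` (0/1 matrix),
#'   `centered` (column-centred), `groups`, `samples`.
#' @export
make_dummy <- function(design, groups) {
  if (length(groups) != 2 || anyDuplicated(groups))
    stop("exactly two distinct groups are required")
  design <- stats::setNames(as.character(design), names(design))
  absent <- setdiff(groups, unique(design))
  if (length(absent))
    stop("group(s) absent from design: ", paste(absent, collapse = ", "))
  samples <- names(design)[design %in% groups]
  ind <- vapply(groups, function(g) as.numeric(design[samples] == g),
                numeric(length(samples)))
  dimnames(ind) <- list(samples, groups)
  structure(list(indicator = ind, centered = scale(ind, scale = FALSE),
                 groups = groups, samples = samples),
            class = "dummy_block")
}

#' Fit a two-block PLS-DA between expression and group membership
#'
#' Axis 1 is the first singular triple of the cross-covariance between the
#' sample-space expression block and the centred dummy block: the unit-norm
#' gene weight vector maximizing covariance between the expression scores
#' and the group codes. Axis 2 is extracted from the X block deflated by the
#' Axis-1 scores, making successive score vectors exactly orthogonal. Each
#' axis is oriented so the reference (first) group has a positive mean
#' score; genes elevated in the experimental group therefore correlate
#' negatively with Axis 1.
#'
#' @param processed A `processed_matrix` from [preprocess()].
#' @param dummy A `dummy_block` from [make_dummy()] on the same design.
#' @param n_axes Number of latent axes (default 2).
#' @return List of class `plsda_model`: `weights` (genes x axes, unit
#'   columns), `scores` (samples x axes), `cov_axis` (singular value per
#'   axis, the X-Y score covariance scale), `cov_explained` (share of the
#'   total squared cross-covariance on each axis), `groups`, `samples`.
#' @export
fit_plsda <- function(processed, dummy, n_axes = 2) {
  stopifnot(inherits(processed, "processed_matrix"),
            inherits(dummy, "dummy_block"))
  missing_s <- setdiff(dummy$samples, colnames(processed$values))
  if (length(missing_s))
    stop("sample(s) absent from expression block: ",
         paste(missing_s, collapse = ", "))
  S <- t(processed$values[, dummy$samples, drop = FALSE])  # samples x genes
  Y <- dummy$centered
  n_axes <- min(n_axes, nrow(S) - 1, ncol(S))
  p <- ncol(S)
  W <- matrix(0, p, n_axes, dimnames = list(colnames(S), NULL))
  Tt <- matrix(0, nrow(S), n_axes, dimnames = list(rownames(S), NULL))
  cov_axis <- numeric(n_axes)
  total_cov2 <- sum(crossprod(S, Y)^2)
  Sd <- S
  for (a in seq_len(n_axes)) {
    M <- crossprod(Sd, Y)                 # genes x 2 cross-covariance
    sv <- svd(M, nu = 1, nv = 0)
    w <- sv$u[, 1]
    t_sc <- drop(Sd %*% w)
    ref <- dummy$indicator[, 1] == 1
    if (mean(t_sc[ref]) < 0) { w <- -w; t_sc <- -t_sc }
    W[, a] <- w; Tt[, a] <- t_sc; cov_axis[a] <- sv$d[1]
    Sd <- Sd - t_sc %*% t(crossprod(Sd, t_sc)) / sum(t_sc^2)
  }
  degenerate <- cov_axis[1] < sqrt(.Machine$double.eps)
  if (degenerate)
    message("cross-covariance is numerically zero; no stable axis")
  structure(list(weights = W, scores = Tt, cov_axis = cov_axis,
                 cov_explained = if (total_cov2 > 0)
                   cov_axis^2 / total_cov2 else rep(0, n_axes),
                 degenerate = degenerate,
                 groups = dummy$groups, samples = dummy$samples),
            class = "plsda_model")
}

#' Correlate every gene with the PLS-DA Axis-1 scores
#'
#' Pearson correlation of each gene's processed values (over the model's
#' samples) with the Axis-1 score vector, with genes binned on |r| in ten
#' width-0.1 bins and flagged as candidates at the configured threshold.
#' Under the orientation convention a gene elevated in the experimental
#' group receives a negative r.
#'
#' @param processed The `processed_matrix` the model was fitted on.
#' @param model A `plsda_model`.
#' @param candidate_threshold Candidate flag cut-off on |r|; genes with
#'   `|r| >= candidate_threshold` are flagged (default 0.90).
#' @return Data frame of class `correlation_ranking`: `gene`, `r`, `abs_r`,
#'   `bin` (label such as "1.00-0.90"), `candidate`.
#' @export
axis1_correlations <- function(processed, model, candidate_threshold = 0.90) {
  stopifnot(inherits(processed, "processed_matrix"),
            inherits(model, "plsda_model"))
  X <- processed$values[, model$samples, drop = FALSE]
  sc <- model$scores[, 1]
  sds <- apply(X, 1, stats::sd)
  r <- rep(NA_real_, nrow(X))
  ok <- sds > 0
  if (any(!ok))
    message(sum(!ok), " zero-variance gene(s); correlation undefined")
  r[ok] <- drop(stats::cor(t(X[ok, , drop = FALSE]), sc))
  out <- data.frame(gene = rownames(X), r = r, abs_r = abs(r),
                    bin = abs_r_bin(abs(r)),
                    candidate = !is.na(r) & abs(r) >= candidate_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("correlation_ranking", "data.frame")
  out
}

#' Bin labels for |r| values
#'
#' Ten bins of width 0.1. Bins are lower-closed (`[0.50, 0.60)` is printed
#' "0.59-0.50") except the top bin `[0.90, 1.00]`, so a gene at exactly
#' 0.90 lands in the top bin.
#'
#' @param abs_r Numeric vector of |r| values in [0, 1] (NA allowed).
#' @return Character vector of bin labels.
#' @export
abs_r_bin <- function(abs_r) {
  labels <- c("0.09-0.00", "0.19-0.10", "0.29-0.20", "0.39-0.30",
              "0.49-0.40", "0.59-0.50", "0.69-0.60", "0.79-0.70",
              "0.89-0.80", "1.00-0.90")
  idx <- pmin(floor(abs_r * 10), 9) + 1
  out <- rep(NA_character_, length(abs_r))
  out[!is.na(idx)] <- labels[idx[!is.na(idx)]]
  out
}

#' Count genes per |r| bin, optionally cross-tabulated with annotations
#'
#' @param ranking A `correlation_ranking` (restrict its rows beforehand to
#'   the gene universe of interest, e.g. DEGs with a neurogenesis flag).
#' @param annotation Optional annotation table joined via [annotate()]; when
#'   given, columns count transcription-factor genes and genes per behavior
#'   term within each bin.
#' @return Data frame with one row per bin (descending |r|), column `n`,
#'   and optional cross-tab columns; bin counts sum to the number of genes
#'   with defined r.
#' @export
bin_abs_correlations <- function(ranking, annotation = NULL) {
  stopifnot(inherits(ranking, "correlation_ranking"))
  labels <- rev(c("0.09-0.00", "0.19-0.10", "0.29-0.20", "0.39-0.30",
                  "0.49-0.40", "0.59-0.50", "0.69-0.60", "0.79-0.70",
                  "0.89-0.80", "1.00-0.90"))
  bins <- factor(ranking$bin, levels = labels)
  out <- data.frame(bin = labels, n = as.integer(table(bins)),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    ann <- annotate(ranking$gene, annotation)
    out$n_tf <- as.integer(table(bins[ann$is_tf]))
    terms <- split_terms(ann$behavior_terms)
    for (term in behavior_vocabulary()) {
      has <- vapply(terms, function(t) term %in% t, logical(1))
      out[[term]] <- as.integer(table(bins[has]))
    }
  }
  out
}

#' Select candidate genes by Axis-1 correlation and annotation
#'
#' Genes with `|r| >= r_threshold` (the bin-boundary convention treats the
#' printed "r > |0.90|" cut as inclusive at print precision), optionally
#' restricted to neurogenesis-flagged genes and/or to genes carrying at
#' least one requested behavior term; sorted by |r| descending with
#' alphabetical tie-break.
#'
#' @param ranking A `correlation_ranking`.
#' @param annotation Optional `gene_annotation` table; required when
#'   `require_neurogenesis` or `require_terms` is used.
#' @param r_threshold Minimum |r| (default 0.90).
#' @param require_neurogenesis If TRUE, keep only neurogenesis-flagged genes.
#' @param require_terms Optional character vector; keep genes annotated with
#'   at least one of these terms.
#' @return Data frame of class `candidate_table`: `gene`, `r`, `abs_r`, and
#'   (when annotation is given) `is_tf`, `is_neurogenesis`, `behavior_terms`.
#' @export
select_candidates <- function(ranking, annotation = NULL, r_threshold = 0.90,
                              require_neurogenesis = FALSE,
                              require_terms = NULL) {
  stopifnot(inherits(ranking, "correlation_ranking"))
  out <- ranking[!is.na(ranking$abs_r) & ranking$abs_r >= r_threshold,
                 c("gene", "r", "abs_r")]
  if (!is.null(annotation)) {
    ann <- annotate(out$gene, annotation)
    out$is_tf <- ann$is_tf
    out$is_neurogenesis <- ann$is_neurogenesis
    out$behavior_terms <- ann$behavior_terms
    if (require_neurogenesis) out <- out[out$is_neurogenesis, ]
    if (!is.null(require_terms)) {
      terms <- split_terms(out$behavior_terms)
      keep <- vapply(terms, function(t) any(require_terms %in% t), logical(1))
      out <- out[keep, ]
    }
  } else if (require_neurogenesis || !is.null(require_terms)) {
    stop("annotation required to filter by flags or terms")
  }
  out <- out[order(-out$abs_r, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}
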