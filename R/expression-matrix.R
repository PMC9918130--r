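#' Construct an expression matrix with an attached sample design
#'
#' The universal input of the pipeline: a genes x samples matrix of FPKM
#' values together with the mapping from sample to experimental group.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row names (gene symbols) and unique column names (sample IDs).
#'   All values must be non-negative (FPKM scale).
#' @param design Named character vector (or factor) mapping every sample ID
#'   in `values` to its group label, e.g. `c(C1 = "C", A20_1 = "A20", ...)`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `design` (a factor named by sample ID, levels
#'   in first-appearance order).
#' @examples
#' v <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expression_matrix(v, c(s1 = "C", s2 = "C", s3 = "A20"))
#' @export
expression_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have gene row names and sample column names")
  dup <- gid[duplicated(gid)]
  if (length(dup))
    stop("duplicate gene ID(s): ", paste(unique(dup), collapse = ", "))
  dup <- sid[duplicated(sid)]
  if (length(dup))
    stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stop("FPKM values must be non-negative and non-missing")
  design <- stats::setNames(as.character(design), names(design))
  missing_design <- setdiff(sid, names(design))
  if (length(missing_design))
    stop("sample(s) missing from design: ",
         paste(missing_design, collapse = ", "))
  design <- design[sid]
  design <- factor(design, levels = unique(design))
  names(design) <- sid
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)", levels(x$design),
                               tabulate(x$design)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Sample IDs belonging to a set of groups
#'
#' @param em An `expression_matrix`.
#' @param groups Character vector of group labels.
#' @return Character vector of sample IDs, in matrix column order.
#' @keywords internal
group_samples <- function(em, groups) {
  absent <- setdiff(groups, levels(em$design))
  if (length(absent))
    stop("group(s) absent from design: ", paste(absent, collapse = ", "))
  names(em$design)[em$design %in% groups]
}
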