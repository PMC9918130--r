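#' Read an FPKM expression matrix and its sample design from TSV files
#'
#' The matrix file has a header row of sample IDs, gene symbols in the first
#' column, and FPKM values in the remaining columns. The design file has two
#' columns, `sample_id` and `group`.
#'
#' @param matrix_path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @return An [expression_matrix()] with sample order as in the matrix file.
#' @export
read_expression <- function(matrix_path, design_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression file needs a gene column plus samples")
  genes <- as.character(tab[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene row(s) in ", matrix_path, ": ",
         paste(unique(dup), collapse = ", "))
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  des <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(des)))
    stop("design file must have columns sample_id and group")
  expression_matrix(values,
                    stats::setNames(des$group, des$sample_id))
}

#' Write an expression matrix and its design to TSV files
#'
#' Inverse of [read_expression()]; round-trips values and sample order.
#'
#' @param em An `expression_matrix`.
#' @param matrix_path,design_path Output paths.
#' @export
write_expression <- function(em, matrix_path, design_path) {
  tab <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  des <- data.frame(sample_id = names(em$design),
                    group = as.character(em$design))
  utils::write.table(des, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, design_path))
}

#' Load gene sets from a GMT file
#'
#' One set per line: set name, description, then member symbols, all
#' tab-separated.
#'
#' @param gmt_path Path to the GMT file.
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with a `descriptions` attribute (named character vector).
#' @export
load_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descr <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, ": expected name, description and >= 1 member")
    nm[i] <- f[1]; descr[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)])
  }
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate gene-set name(s): ", paste(unique(dup), collapse = ", "))
  names(sets) <- nm
  structure(sets, descriptions = stats::setNames(descr, nm),
            class = "gene_set_collection")
}

#' The behavior / neurological-phenotype term vocabulary
#'
#' The fixed set of term labels an annotation table may use.
#'
#' @return Character vector of allowed term labels.
#' @export
behavior_vocabulary <- function() {
  c("abnormal aggression-related behavior",
    "increased aggression",
    "abnormal anxiety-related response",
    "abnormal fear-related response",
    "abnormal response to social novelty",
    "learning or memory",
    "abnormal learning/memory/conditioning")
}

#' Read a gene annotation table
#'
#' TSV with columns `gene`, `is_neurogenesis`, `is_tf` and `behavior_terms`
#' (pipe-delimited term labels from [behavior_vocabulary()], empty allowed).
#'
#' @param path Path to the annotation TSV.
#' @return A data frame of class `gene_annotation` with one row per gene.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character())
  req <- c("gene", "is_neurogenesis", "is_tf", "behavior_terms")
  if (!all(req %in% names(ann)))
    stop("annotation file must have columns: ", paste(req, collapse = ", "))
  ann$is_neurogenesis <- as.logical(ann$is_neurogenesis)
  ann$is_tf <- as.logical(ann$is_tf)
  ann$behavior_terms <- as.character(ann$behavior_terms)
  terms <- unlist(strsplit(ann$behavior_terms[nzchar(ann$behavior_terms)],
                           "|", fixed = TRUE))
  bad <- setdiff(unique(terms), behavior_vocabulary())
  if (length(bad))
    stop("behavior term(s) outside the vocabulary: ",
         paste(bad, collapse = "; "))
  dup <- ann$gene[duplicated(ann$gene)]
  if (length(dup))
    stop("duplicate annotation row(s): ", paste(unique(dup), collapse = ", "))
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Join gene-level annotations onto a list of genes
#'
#' Genes absent from the annotation table receive all-FALSE flags and an
#' empty term set; the join never drops or duplicates input genes. Matching
#' is by case-sensitive exact symbol.
#'
#' @param genes Character vector of gene symbols.
#' @param annotation A `gene_annotation` table (see [read_annotation()]).
#' @return Data frame with one row per input gene, in input order, with
#'   columns `gene`, `is_neurogenesis`, `is_tf`, `behavior_terms`.
#' @export
annotate <- function(genes, annotation) {
  idx <- match(genes, annotation$gene)
  out <- data.frame(
    gene = genes,
    is_neurogenesis = ifelse(is.na(idx), FALSE,
                             annotation$is_neurogenesis[idx]),
    is_tf = ifelse(is.na(idx), FALSE, annotation$is_tf[idx]),
    behavior_terms = ifelse(is.na(idx), "", annotation$behavior_terms[idx]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Split a pipe-delimited term string into a character vector
#'
#' @param x Character vector of pipe-delimited term strings.
#' @return List of character vectors (empty vector for empty strings).
#' @export
split_terms <- function(x) {
  lapply(as.character(x), function(s)
    if (!nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]])
}
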