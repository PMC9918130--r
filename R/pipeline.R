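#' Configuration for a full pipeline run
#'
#' Either `simulation` (a [synthetic_config()]) or both `matrix_path` and
#' `design_path` must be supplied.
#'
#' @param simulation Optional [synthetic_config()]; when given, input data
#'   are generated rather than read.
#' @param matrix_path,design_path Input TSVs (used when `simulation` is
#'   NULL).
#' @param annotation_path Optional annotation TSV; defaults to the
#'   generator's own annotation when simulating, or no annotation joins.
#' @param gmt_path Optional GMT file for the over-representation stage;
#'   when simulating and absent, the generated neurogenesis flags form one
#'   set.
#' @param groups Ordered triple of group labels
#'   (control, treatment, withdrawal).
#' @param contrasts List of group pairs to run PLS-DA ranking on; defaults
#'   to control-vs-treatment and control-vs-withdrawal.
#' @param alpha DEG significance level (BH-adjusted).
#' @param r_threshold Candidate |r| threshold.
#' @param coexpr_alpha Two-tailed level for the coexpression critical r.
#' @param top_k Partners reported per key gene.
#' @param key_genes Optional key genes for the coexpression stage; default
#'   is the top (up to) 3 candidate genes of the last contrast.
#' @param pseudocount Log-transform offset.
#' @param n_axes Ordination / PLS axes to retain.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest and forwarded to the simulator
#'   when `simulation` carries none.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, matrix_path = NULL,
                            design_path = NULL, annotation_path = NULL,
                            gmt_path = NULL,
                            groups = c("C", "A20", "AD"),
                            contrasts = NULL, alpha = 0.05,
                            r_threshold = 0.90, coexpr_alpha = 0.001,
                            top_k = 10, key_genes = NULL, pseudocount = 1,
                            n_axes = 2, out_dir = "pipeline_out", seed = 1) {
  if (is.null(contrasts))
    contrasts <- list(groups[c(1, 2)], groups[c(1, 3)])
  if (is.null(simulation) && (is.null(matrix_path) || is.null(design_path)))
    stop("supply either a simulation config or matrix and design paths")
  for (ct in contrasts)
    if (!all(ct %in% groups))
      stop("contrast references unknown group(s): ",
           paste(setdiff(ct, groups), collapse = ", "))
  if (alpha <= 0 || alpha > 1 || coexpr_alpha <= 0 || coexpr_alpha > 1)
    stop("significance levels must lie in (0, 1]")
  if (r_threshold <= 0 || r_threshold > 1)
    stop("r_threshold must lie in (0, 1]")
  structure(list(simulation = simulation, matrix_path = matrix_path,
                 design_path = design_path,
                 annotation_path = annotation_path, gmt_path = gmt_path,
                 groups = groups, contrasts = contrasts, alpha = alpha,
                 r_threshold = r_threshold, coexpr_alpha = coexpr_alpha,
                 top_k = top_k, key_genes = key_genes,
                 pseudocount = pseudocount, n_axes = n_axes,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation:` mapping is passed to [synthetic_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(synthetic_config, raw$simulation)
  if (!is.null(raw$contrasts))
    raw$contrasts <- lapply(raw$contrasts, unlist)
  do.call(pipeline_config, raw)
}

contrast_tag <- function(ct) paste(ct, collapse = "_")

#' Run the full candidate-gene prioritization pipeline
#'
#' Simulates or reads the FPKM matrix, preprocesses it, ordinates the
#' samples, calls DEGs for every pairwise contrast of the three groups,
#' runs PLS-DA ranking and candidate selection for the configured
#' contrasts, classifies expression trajectories, screens coexpression
#' partners of the key genes, performs over-representation analysis, and
#' writes every stage output plus a JSON run manifest to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result and `paths` (the
#'   written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  tsv <- function(obj, file) {
    p <- file.path(config$out_dir, file)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[file]] <<- p
    p
  }

  truth <- NULL
  em <- stage("input", {
    if (!is.null(config$simulation)) {
      sim <- generate_experiment(config$simulation)
      truth <- sim$truth
      write_expression(sim$matrix,
                       file.path(config$out_dir, "matrix.tsv"),
                       file.path(config$out_dir, "design.tsv"))
      paths[["matrix.tsv"]] <- file.path(config$out_dir, "matrix.tsv")
      paths[["design.tsv"]] <- file.path(config$out_dir, "design.tsv")
      write_truth(truth, file.path(config$out_dir, "truth.tsv"))
      paths[["truth.tsv"]] <- file.path(config$out_dir, "truth.tsv")
      sim$matrix
    } else {
      read_expression(config$matrix_path, config$design_path)
    }
  })

  annotation <- stage("annotation", {
    if (!is.null(config$annotation_path)) {
      read_annotation(config$annotation_path)
    } else if (!is.null(truth)) {
      ann <- truth[, c("gene", "is_neurogenesis", "is_tf", "behavior_terms")]
      class(ann) <- c("gene_annotation", "data.frame")
      ann
    } else NULL
  })

  processed <- stage("preprocess", preprocess(em, config$pseudocount))
  ord <- stage("ordination", pcoa(processed, config$n_axes))
  tsv(data.frame(sample = rownames(ord$points), ord$points,
                 group = as.character(em$design[rownames(ord$points)])),
      "coords.tsv")

  all_pairs <- list(config$groups[c(1, 2)], config$groups[c(1, 3)],
                    config$groups[c(2, 3)])
  degs <- stage("differential_expression", {
    res <- lapply(all_pairs, function(ct)
      call_degs(em, ct, alpha = config$alpha,
                pseudocount = config$pseudocount))
    names(res) <- vapply(all_pairs, contrast_tag, "")
    for (tag in names(res)) tsv(res[[tag]], paste0("deg_", tag, ".tsv"))
    res
  })

  rankings <- list(); candidates <- list()
  for (ct in config$contrasts) {
    tag <- contrast_tag(ct)
    rk <- stage(paste0("plsda_", tag), {
      dummy <- make_dummy(em$design, ct)
      model <- fit_plsda(processed, dummy, config$n_axes)
      axis1_correlations(processed, model, config$r_threshold)
    })
    rankings[[tag]] <- rk
    tsv(rk, paste0("ranking_", tag, ".tsv"))
    deg_genes <- degs[[tag]]$gene[degs[[tag]]$significant]
    rk_deg <- rk[rk$gene %in% deg_genes, ]
    class(rk_deg) <- class(rk)
    tsv(bin_abs_correlations(rk_deg, annotation), paste0("bins_", tag, ".tsv"))
    cand <- select_candidates(rk, annotation, config$r_threshold)
    candidates[[tag]] <- cand
    tsv(cand, paste0("candidates_", tag, ".tsv"))
  }

  traj <- stage("trajectory", {
    tags <- vapply(all_pairs, contrast_tag, "")
    classify_trajectory(degs[[tags[1]]], degs[[tags[2]]], degs[[tags[3]]])
  })
  tsv(traj, "trajectory.tsv")

  key_genes <- config$key_genes
  if (is.null(key_genes)) {
    last <- candidates[[length(candidates)]]
    key_genes <- utils::head(last$gene, 3)
  }
  coexpr <- stage("coexpression", {
    tagD <- contrast_tag(config$groups[c(1, 3)])
    deg_genes <- degs[[tagD]]$gene[degs[[tagD]]$significant]
    res <- list()
    for (kg in key_genes) {
      partners <- setdiff(deg_genes, kg)
      if (!length(partners)) next
      cx <- coexpressed_partners(kg, partners, em,
                                 groups = config$groups[c(1, 3)],
                                 alpha = config$coexpr_alpha,
                                 top_k = config$top_k,
                                 pseudocount = config$pseudocount)
      res[[kg]] <- cx
      tsv(cx, paste0("coexpr_", kg, ".tsv"))
    }
    res
  })

  enr <- stage("enrichment", {
    tagD <- contrast_tag(config$groups[c(1, 3)])
    query <- degs[[tagD]]$gene[degs[[tagD]]$significant]
    universe <- rownames(em$values)
    sets <- if (!is.null(config$gmt_path)) {
      load_gene_sets(config$gmt_path)
    } else if (!is.null(annotation)) {
      list(neurogenesis = annotation$gene[annotation$is_neurogenesis])
    } else NULL
    if (is.null(sets) || !length(query)) NULL
    else overrepresentation(query, universe, sets, config$alpha)
  })
  if (!is.null(enr)) tsv(enr, "enrichment.tsv")

  manifest <- list(
    package = "plsdaRank",
    version = as.character(utils::packageVersion("plsdaRank")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = config[setdiff(names(config), "simulation")],
    simulation = if (!is.null(config$simulation))
      unclass(config$simulation),
    key_genes = key_genes,
    outputs = names(paths)
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  paths[["manifest.json"]] <- manifest_path

  invisible(list(matrix = em, truth = truth, processed = processed,
                 ordination = ord, degs = degs, rankings = rankings,
                 candidates = candidates, trajectory = traj,
                 coexpression = coexpr, enrichment = enr,
                 annotation = annotation, key_genes = key_genes,
                 paths = paths))
}
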