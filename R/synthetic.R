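#' Trajectory class labels used by the generator and the classifier
#' @return Character vector of the five planted class labels.
#' @export
trajectory_classes <- function() {
  c("persistent", "partial_normalization", "deprivation_emergent",
    "gradual_emergent", "restored")
}

## Per-class mean-shift pattern as multiples of the base effect delta,
## for the (treatment, withdrawal) groups relative to control.
## partial_normalization uses (2, 1) so that every pairwise gap in the
## pattern has magnitude >= delta; gradual_emergent uses (0.5, 1) so that
## its per-phase steps stay below the detection limit while the cumulative
## effect is detectable.
.class_shifts <- rbind(
  persistent            = c(1,   1),
  partial_normalization = c(2,   1),
  deprivation_emergent  = c(0,   1),
  gradual_emergent      = c(0.5, 1),
  restored              = c(1,   0)
)

#' Configuration for the synthetic three-group FPKM experiment
#'
#' Defaults emulate the study design the pipeline targets: 18 samples in
#' three groups of 6 (control, 20-day treatment, treatment followed by
#' withdrawal), ~10^4 genes with log-normal baseline FPKM, planted
#' between-group effects of |log2FC| 0.2-0.6, a mixture of expression
#' trajectory classes for the planted genes, a neurogenesis annotation at
#' roughly the 397-in-10^4 density of the curated adult-neurogenesis list,
#' and one hub-centred coexpression block.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group.
#' @param group_labels Ordered triple of group labels
#'   (control, treatment, withdrawal).
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of per-gene
#'   baseline expression on the log2-FPKM scale.
#' @param noise_sd Within-group SD on the log2 scale.
#' @param deg_fraction Fraction of genes planted with a true effect.
#' @param effect_size_range Interval from which each planted gene's base
#'   |log2FC| delta is drawn uniformly.
#' @param trajectory_mix Named proportions over [trajectory_classes()] for
#'   the planted genes; must sum to 1.
#' @param neurogenesis_fraction Fraction of genes flagged as
#'   neurogenesis-associated.
#' @param tf_fraction Fraction of genes flagged as transcription factors.
#' @param behavior_term_prob Probability that a neurogenesis-flagged gene
#'   carries any given term of [behavior_vocabulary()].
#' @param annotate_planted If TRUE, all planted genes are flagged as
#'   neurogenesis-associated (emulating an analysis restricted to the
#'   annotated DEG subset); annotation of the remaining genes is random.
#' @param coexpr_block_size Number of genes (including the hub) sharing a
#'   latent factor; 0 disables the block.
#' @param coexpr_loading Correlation of each block member with the hub gene;
#'   member-member correlations equal its square.
#' @param seed Integer seed driving one reproducible generator stream
#'   (global RNG state is restored on exit).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 10000,
                             n_per_group = 6,
                             group_labels = c("C", "A20", "AD"),
                             baseline_log2_mean = 4,
                             baseline_log2_sd = 2,
                             noise_sd = 0.1,
                             deg_fraction = 0.1,
                             effect_size_range = c(0.2, 0.6),
                             trajectory_mix = c(
                               persistent = 0.4,
                               partial_normalization = 0.2,
                               deprivation_emergent = 0.1,
                               gradual_emergent = 0.1,
                               restored = 0.2),
                             neurogenesis_fraction = 0.04,
                             tf_fraction = 0.08,
                             behavior_term_prob = 0.25,
                             annotate_planted = FALSE,
                             coexpr_block_size = 0,
                             coexpr_loading = 0.9,
                             seed = 1) {
  cfg <- list(n_genes = n_genes, n_per_group = n_per_group,
              group_labels = group_labels,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              noise_sd = noise_sd, deg_fraction = deg_fraction,
              effect_size_range = effect_size_range,
              trajectory_mix = trajectory_mix,
              neurogenesis_fraction = neurogenesis_fraction,
              tf_fraction = tf_fraction,
              behavior_term_prob = behavior_term_prob,
              annotate_planted = isTRUE(annotate_planted),
              coexpr_block_size = coexpr_block_size,
              coexpr_loading = coexpr_loading, seed = seed)
  stopifnot_config(cfg)
  structure(cfg, class = "synthetic_config")
}

stopifnot_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(length(cfg$n_genes) == 1 && cfg$n_genes >= 1 &&
        cfg$n_genes == round(cfg$n_genes), "n_genes must be a positive integer")
  chk(cfg$n_per_group >= 1 && cfg$n_per_group == round(cfg$n_per_group),
      "n_per_group must be a positive integer")
  chk(length(cfg$group_labels) == 3 && !anyDuplicated(cfg$group_labels),
      "group_labels must be three distinct labels")
  chk(cfg$baseline_log2_sd >= 0, "baseline_log2_sd must be non-negative")
  chk(cfg$noise_sd > 0, "noise_sd must be positive")
  for (f in c("deg_fraction", "neurogenesis_fraction", "tf_fraction",
              "behavior_term_prob", "coexpr_loading"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "must lie in [0, 1]"))
  chk(length(cfg$effect_size_range) == 2 &&
        cfg$effect_size_range[1] > 0 &&
        diff(cfg$effect_size_range) >= 0,
      "effect_size_range must be an increasing positive interval")
  chk(all(cfg$trajectory_mix >= 0) &&
        abs(sum(cfg$trajectory_mix) - 1) < 1e-8,
      "trajectory_mix must be non-negative and sum to 1")
  chk(all(names(cfg$trajectory_mix) %in% trajectory_classes()),
      "trajectory_mix names must be trajectory classes")
  chk(cfg$coexpr_block_size >= 0 &&
        cfg$coexpr_block_size == round(cfg$coexpr_block_size),
      "coexpr_block_size must be a non-negative integer")
  chk(cfg$coexpr_block_size <= cfg$n_genes,
      "coexpr_block_size cannot exceed n_genes")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

## Run expr under a private RNG stream seeded with `seed`, restoring the
## caller's global RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic three-group FPKM experiment with ground truth
#'
#' Expression is log-normal: per-gene baseline log2-FPKM plus within-group
#' Gaussian noise, with planted per-class mean shifts for the treatment and
#' withdrawal groups and an optional hub-centred coexpression block whose
#' members share a latent factor. Identical configurations (including seed)
#' give bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (a `ground_truth` data frame: per-gene planted class, true
#'   log2FC for the three contrasts, coexpression-block and hub flags, and
#'   generated annotation flags).
#' @export
generate_experiment <- function(config) {
  stopifnot_config(config)
  with_seed(config$seed, {
    n <- config$n_genes; k <- config$n_per_group
    genes <- sprintf("gene%05d", seq_len(n))
    grp <- rep(config$group_labels, each = k)
    samples <- paste0(rep(config$group_labels, each = k), "_",
                      rep(seq_len(k), 3))
    baseline <- stats::rnorm(n, config$baseline_log2_mean,
                             config$baseline_log2_sd)

    ## planted classes and effects
    n_deg <- round(config$deg_fraction * n)
    cls <- rep(NA_character_, n)
    delta <- numeric(n)
    shift_trt <- numeric(n); shift_wd <- numeric(n)
    if (n_deg > 0) {
      planted <- sample.int(n, n_deg)
      mix <- config$trajectory_mix[trajectory_classes()]
      mix[is.na(mix)] <- 0
      names(mix) <- trajectory_classes()
      cls[planted] <- sample(names(mix), n_deg, replace = TRUE, prob = mix)
      delta[planted] <- stats::runif(n_deg, config$effect_size_range[1],
                                     config$effect_size_range[2]) *
        sample(c(-1, 1), n_deg, replace = TRUE)
      shift_trt[planted] <- .class_shifts[cls[planted], 1] * delta[planted]
      shift_wd[planted]  <- .class_shifts[cls[planted], 2] * delta[planted]
    }

    log2x <- matrix(stats::rnorm(n * 3 * k, 0, config$noise_sd), n, 3 * k)
    log2x <- log2x + baseline
    idx_trt <- (k + 1):(2 * k); idx_wd <- (2 * k + 1):(3 * k)
    log2x[, idx_trt] <- log2x[, idx_trt] + shift_trt
    log2x[, idx_wd]  <- log2x[, idx_wd]  + shift_wd

    ## coexpression block: hub carries the latent factor, members load on it
    in_block <- rep(FALSE, n); is_hub <- rep(FALSE, n)
    if (config$coexpr_block_size > 0) {
      free <- which(is.na(cls))
      if (length(free) < config$coexpr_block_size)
        stop("not enough unplanted genes for the coexpression block")
      block <- sample(free, config$coexpr_block_size)
      in_block[block] <- TRUE
      hub <- block[1]; is_hub[hub] <- TRUE
      u <- stats::rnorm(3 * k)
      s <- config$noise_sd; lam <- config$coexpr_loading
      log2x[hub, ] <- baseline[hub] + s * u
      members <- block[-1]
      if (length(members)) {
        eps <- matrix(stats::rnorm(length(members) * 3 * k), length(members))
        log2x[members, ] <- baseline[members] +
          s * (lam * rep(1, length(members)) %o% u +
                 sqrt(1 - lam^2) * eps)
      }
    }

    ## annotation flags
    is_ng <- stats::runif(n) < config$neurogenesis_fraction
    if (config$annotate_planted) is_ng[!is.na(cls)] <- TRUE
    is_tf <- stats::runif(n) < config$tf_fraction
    vocab <- behavior_vocabulary()
    terms <- character(n)
    ng_idx <- which(is_ng)
    if (length(ng_idx)) {
      pick <- matrix(stats::runif(length(ng_idx) * length(vocab)) <
                       config$behavior_term_prob, length(ng_idx))
      terms[ng_idx] <- apply(pick, 1, function(p)
        paste(vocab[p], collapse = "|"))
    }

    values <- 2^log2x
    dimnames(values) <- list(genes, samples)
    em <- expression_matrix(values, stats::setNames(grp, samples))

    truth <- data.frame(
      gene = genes,
      class = cls,
      true_lfc_C_A20 = shift_trt,
      true_lfc_C_AD = shift_wd,
      true_lfc_A20_AD = shift_wd - shift_trt,
      in_coexpr_block = in_block,
      is_hub = is_hub,
      is_neurogenesis = is_ng,
      is_tf = is_tf,
      behavior_terms = terms,
      stringsAsFactors = FALSE
    )
    class(truth) <- c("ground_truth", "data.frame")
    list(matrix = em, truth = truth)
  })
}

#' Write or read a ground-truth table
#'
#' TSV serialisation that round-trips losslessly through [read_truth()].
#'
#' @param truth A `ground_truth` data frame from [generate_experiment()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$class[is.na(out$class)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = character(),
                             colClasses = c(gene = "character",
                                            class = "character",
                                            behavior_terms = "character"))
  truth$class[!nzchar(truth$class)] <- NA_character_
  for (f in c("in_coexpr_block", "is_hub", "is_neurogenesis", "is_tf"))
    truth[[f]] <- as.logical(truth[[f]])
  class(truth) <- c("ground_truth", "data.frame")
  truth
}
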