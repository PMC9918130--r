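test_that("dummy blocks satisfy the indicator and centring invariants", {
  design <- setNames(rep(c("C", "A20", "AD"), each = 6),
                     paste0("s", 1:18))
  dummy <- make_dummy(design, c("C", "A20"))
  expect_equal(dim(dummy$indicator), c(12L, 2L))
  expect_true(all(rowSums(dummy$indicator) == 1))
  expect_lt(max(abs(colSums(dummy$centered))), 1e-12)
  expect_error(make_dummy(design, "C"), "two")
  expect_error(make_dummy(design, c("C", "XX")), "XX")
})

test_that("axis-1 weights match the exhaustive direction-search oracle", {
  set.seed(81)
  for (p in c(2, 3)) {
    for (rep in 1:3) {
      n <- 8
      X <- matrix(rnorm(n * p), n, p)
      X[1:4, 1] <- X[1:4, 1] + 1.5       # one separating gene
      X <- scale(X)
      y <- rep(c(0.5, -0.5), each = 4)
      oracle <- grid_search_axis1(X, y)
      pm <- structure(list(values = t(X), design = NULL, pseudocount = 1,
                           dropped = character()),
                      class = "processed_matrix")
      rownames(pm$values) <- paste0("g", seq_len(p))
      colnames(pm$values) <- paste0("s", seq_len(n))
      dummy <- make_dummy(setNames(rep(c("C", "A20"), each = 4),
                                   colnames(pm$values)), c("C", "A20"))
      model <- fit_plsda(pm, dummy, n_axes = 1)
      expect_lt(direction_angle(model$weights[, 1], oracle), 1e-3)
    }
  }
})

test_that("the fit agrees with an independent PLS implementation", {
  sim <- generate_experiment(synthetic_config(n_genes = 120,
                                              deg_fraction = 0.2,
                                              trajectory_mix = c(persistent = 1),
                                              seed = 15))
  pm <- preprocess(sim$matrix)
  dummy <- make_dummy(pm$design, c("C", "A20"))
  model <- fit_plsda(pm, dummy, n_axes = 2)
  X <- t(pm$values[, dummy$samples])
  ref <- mixOmics::pls(X, dummy$centered, ncomp = 2, scale = FALSE,
                       mode = "regression")
  ## axis 1 is convention-free and must coincide exactly; later axes differ
  ## between implementations in how the Y block is deflated
  expect_gt(abs(cor(model$scores[, 1], ref$variates$X[, 1])), 0.9999)
})

test_that("weights are unit norm, scores orthogonal, order irrelevant", {
  sim <- generate_experiment(synthetic_config(n_genes = 80, seed = 16))
  pm <- preprocess(sim$matrix)
  dummy <- make_dummy(pm$design, c("C", "AD"))
  model <- fit_plsda(pm, dummy, n_axes = 2)
  expect_equal(unname(colSums(model$weights^2)), c(1, 1), tolerance = 1e-9)
  expect_lt(abs(sum(model$scores[, 1] * model$scores[, 2])), 1e-8)
  ## permuting samples identically in X and the design leaves the model
  ## unchanged up to that permutation
  perm <- sample(colnames(pm$values))
  pm2 <- pm; pm2$values <- pm$values[, perm]; pm2$design <- pm$design[perm]
  dummy2 <- make_dummy(pm2$design, c("C", "AD"))
  model2 <- fit_plsda(pm2, dummy2, n_axes = 2)
  expect_equal(model2$scores[order(rownames(model2$scores)), 1],
               model$scores[order(rownames(model$scores)), 1],
               tolerance = 1e-9)
})

test_that("destroying the group structure collapses the leading axis", {
  ## the same planted data fitted against scrambled labels: the label
  ## permutation removes the signal, so the cross-covariance on axis 1
  ## must drop markedly
  sim <- generate_experiment(synthetic_config(n_genes = 300,
                                              deg_fraction = 0.5,
                                              effect_size_range = c(0.8, 0.8),
                                              trajectory_mix = c(persistent = 1),
                                              seed = 18))
  pm <- preprocess(sim$matrix)
  cov1 <- function(design) {
    dummy <- make_dummy(design, c("C", "A20"))
    fit_plsda(pm, dummy, 1)$cov_axis[1]
  }
  true_cov <- cov1(pm$design)
  set.seed(18)
  scrambled <- setNames(sample(as.character(pm$design)), names(pm$design))
  expect_gt(true_cov, 1.5 * cov1(scrambled))
})

test_that("axis-1 correlations hit the exact and sign-convention cases", {
  sim <- generate_experiment(synthetic_config(n_genes = 150,
                                              deg_fraction = 0.1,
                                              effect_size_range = c(0.6, 0.6),
                                              trajectory_mix = c(persistent = 1),
                                              seed = 19))
  pm <- preprocess(sim$matrix)
  dummy <- make_dummy(pm$design, c("C", "A20"))
  model <- fit_plsda(pm, dummy, 1)
  ## genes made equal (or opposite) to the score vector correlate at +-1
  pm2 <- pm
  pm2$values[1, dummy$samples] <- model$scores[, 1]
  pm2$values[2, dummy$samples] <- -2 * model$scores[, 1] + 3
  rk2 <- axis1_correlations(pm2, model)
  expect_equal(rk2$r[1], 1, tolerance = 1e-9)
  expect_equal(rk2$r[2], -1, tolerance = 1e-9)
  ## orientation: reference-group scores positive, so a gene UP in the
  ## experimental group correlates negatively
  expect_gt(mean(model$scores[pm$design[dummy$samples] == "C", 1]), 0)
  rk <- axis1_correlations(pm, model)
  up <- sim$truth$true_lfc_C_A20 > 0.5
  down <- sim$truth$true_lfc_C_A20 < -0.5
  expect_true(all(rk$r[up] < 0))
  expect_true(all(rk$r[down] > 0))
  expect_true(all(abs(rk$r) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("absolute-correlation bins use lower-closed width-0.1 intervals", {
  expect_identical(abs_r_bin(c(0.95, 0.91, 0.05)),
                   c("1.00-0.90", "1.00-0.90", "0.09-0.00"))
  expect_identical(abs_r_bin(0.5), "0.59-0.50")
  expect_identical(abs_r_bin(0.90), "1.00-0.90")
  expect_identical(abs_r_bin(0.8999), "0.89-0.80")
  rk <- structure(data.frame(gene = c("a", "b", "c"),
                             r = c(0.95, -0.91, 0.05),
                             abs_r = c(0.95, 0.91, 0.05),
                             bin = abs_r_bin(c(0.95, 0.91, 0.05)),
                             candidate = c(TRUE, TRUE, FALSE)),
                  class = c("correlation_ranking", "data.frame"))
  bins <- bin_abs_correlations(rk)
  expect_equal(bins$n[bins$bin == "1.00-0.90"], 2L)
  expect_equal(bins$n[bins$bin == "0.09-0.00"], 1L)
  expect_equal(sum(bins$n), 3L)
})

test_that("annotation cross-tabs conserve counts", {
  sim <- generate_experiment(synthetic_config(n_genes = 200,
                                              deg_fraction = 0.3,
                                              annotate_planted = TRUE,
                                              seed = 20))
  pm <- preprocess(sim$matrix)
  dummy <- make_dummy(pm$design, c("C", "A20"))
  model <- fit_plsda(pm, dummy, 1)
  rk <- axis1_correlations(pm, model)
  ann <- sim$truth[, c("gene", "is_neurogenesis", "is_tf", "behavior_terms")]
  class(ann) <- c("gene_annotation", "data.frame")
  keep <- rk[rk$gene %in% ann$gene[ann$is_neurogenesis], ]
  class(keep) <- class(rk)
  bins <- bin_abs_correlations(keep, ann)
  expect_equal(sum(bins$n), nrow(keep))
  expect_true(all(bins$n_tf <= bins$n))
  for (term in behavior_vocabulary())
    expect_true(all(bins[[term]] <= bins$n))
})

test_that("candidate selection filters, sorts and tie-breaks", {
  rk <- structure(data.frame(gene = c("b", "a", "c", "d"),
                             r = c(0.95, -0.95, 0.91, 0.2),
                             abs_r = c(0.95, 0.95, 0.91, 0.2),
                             bin = abs_r_bin(c(0.95, 0.95, 0.91, 0.2)),
                             candidate = c(TRUE, TRUE, TRUE, FALSE)),
                  class = c("correlation_ranking", "data.frame"))
  expect_equal(nrow(select_candidates(rk, r_threshold = 1.0)), 0)
  expect_equal(nrow(select_candidates(rk, r_threshold = 0)), 4)
  got <- select_candidates(rk, r_threshold = 0.90)
  expect_identical(got$gene, c("a", "b", "c"))   # tie a/b broken by name
  ann <- fixture_annotation()
  rk$gene <- c("Nr1d1", "Fmr1", "Sacm1l", "Pten")
  got2 <- select_candidates(rk, ann, 0.90, require_neurogenesis = TRUE)
  expect_identical(sort(got2$gene), c("Fmr1", "Nr1d1"))
  got3 <- select_candidates(rk, ann, 0.90,
                            require_terms = "abnormal anxiety-related response")
  expect_identical(sort(got3$gene), c("Fmr1", "Nr1d1"))
})

test_that("gene-wise rescaling of raw FPKM leaves the ranking unchanged", {
  sim <- generate_experiment(synthetic_config(n_genes = 100,
                                              deg_fraction = 0.1,
                                              seed = 22))
  em <- sim$matrix
  run <- function(em) {
    pm <- preprocess(em, pseudocount = 1e-6)
    dummy <- make_dummy(pm$design, c("C", "A20"))
    axis1_correlations(pm, fit_plsda(pm, dummy, 1))
  }
  rk1 <- run(em)
  em2 <- em
  em2$values[5, ] <- em2$values[5, ] * 37.5
  rk2 <- run(em2)
  expect_equal(rk1$r, rk2$r, tolerance = 1e-6)
})

test_that("swapping the dummy reference only flips correlation signs", {
  sim <- generate_experiment(synthetic_config(n_genes = 90,
                                              deg_fraction = 0.2,
                                              seed = 23))
  pm <- preprocess(sim$matrix)
  m1 <- fit_plsda(pm, make_dummy(pm$design, c("C", "A20")), 1)
  m2 <- fit_plsda(pm, make_dummy(pm$design, c("A20", "C")), 1)
  r1 <- axis1_correlations(pm, m1)$r
  r2 <- axis1_correlations(pm, m2)$r
  expect_equal(r1, -r2, tolerance = 1e-9)
})
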