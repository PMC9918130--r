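test_that("generator is deterministic and matches the configured design", {
  cfg <- synthetic_config(n_genes = 300, coexpr_block_size = 10, seed = 5)
  sim1 <- generate_experiment(cfg)
  sim2 <- generate_experiment(cfg)
  expect_identical(sim1$matrix$values, sim2$matrix$values)
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(dim(sim1$matrix$values), c(300L, 18L))
  expect_equal(unname(tabulate(sim1$matrix$design)), c(6L, 6L, 6L))
  expect_identical(levels(sim1$matrix$design), c("C", "A20", "AD"))
  expect_true(all(sim1$matrix$values > 0))
  ## a different seed changes the data
  sim3 <- generate_experiment(synthetic_config(n_genes = 300,
                                               coexpr_block_size = 10,
                                               seed = 6))
  expect_false(identical(sim1$matrix$values, sim3$matrix$values))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99); before <- .Random.seed
  generate_experiment(synthetic_config(n_genes = 50, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("no-effect configuration plants nothing", {
  sim <- generate_experiment(synthetic_config(n_genes = 1000,
                                              deg_fraction = 0, seed = 3))
  expect_true(all(is.na(sim$truth$class)))
  expect_true(all(sim$truth$true_lfc_C_A20 == 0))
  expect_true(all(sim$truth$true_lfc_C_AD == 0))
  expect_true(all(sim$truth$true_lfc_A20_AD == 0))
})

test_that("null-class genes always carry zero true effects", {
  sim <- generate_experiment(synthetic_config(n_genes = 500,
                                              deg_fraction = 0.3, seed = 8))
  nulls <- is.na(sim$truth$class)
  lfc <- as.matrix(sim$truth[nulls, c("true_lfc_C_A20", "true_lfc_C_AD",
                                      "true_lfc_A20_AD")])
  expect_true(all(lfc == 0))
  ## every planted gene has a non-zero effect in at least one contrast
  planted <- sim$truth[!nulls, ]
  expect_true(all(pmax(abs(planted$true_lfc_C_A20),
                       abs(planted$true_lfc_C_AD),
                       abs(planted$true_lfc_A20_AD)) > 0))
})

test_that("estimated fold changes recover a planted effect", {
  ## Monte-Carlo oracle: repeated small experiments with one fixed planted
  ## effect of 0.38; the mean truth-aligned estimate from raw group means
  ## must sit within 3 standard errors of 0.38.
  reps <- 200
  est <- vapply(seq_len(reps), function(i) {
    cfg <- synthetic_config(n_genes = 10, deg_fraction = 0.1,
                            effect_size_range = c(0.38, 0.38),
                            trajectory_mix = c(persistent = 1),
                            noise_sd = 0.1, seed = 1000 + i)
    sim <- generate_experiment(cfg)
    planted <- which(!is.na(sim$truth$class))
    gm <- group_means(sim$matrix)
    lfc <- log2_fold_change(gm[planted, "A20"], gm[planted, "C"])
    mean(lfc * sign(sim$truth$true_lfc_C_A20[planted]))
  }, numeric(1))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.38), 3 * se)
})

test_that("coexpression block members correlate as configured", {
  cfg <- synthetic_config(n_genes = 400, deg_fraction = 0,
                          coexpr_block_size = 25, coexpr_loading = 0.9,
                          seed = 17)
  sim <- generate_experiment(cfg)
  expect_equal(sum(sim$truth$in_coexpr_block), 25)
  expect_equal(sum(sim$truth$is_hub), 1)
  block <- sim$truth$gene[sim$truth$in_coexpr_block]
  hub <- sim$truth$gene[sim$truth$is_hub]
  lx <- log2(sim$matrix$values[block, ])
  cc <- cor(t(lx))
  hub_member <- cc[hub, setdiff(block, hub)]
  member_member <- cc[setdiff(block, hub), setdiff(block, hub)]
  mm <- member_member[upper.tri(member_member)]
  ## hub-member correlation targets the loading, member-member its square
  expect_gt(mean(hub_member), 0.85)
  expect_gt(mean(mm), 0.9^2 - 0.05)
  ## genes outside the block stay uncorrelated on average
  out_genes <- sample(sim$truth$gene[!sim$truth$in_coexpr_block], 25)
  cc_out <- cor(t(log2(sim$matrix$values[out_genes, ])))
  expect_lt(mean(abs(cc_out[upper.tri(cc_out)])), 0.3)
})

test_that("truth tables round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  sim <- generate_experiment(synthetic_config(n_genes = 200,
                                              deg_fraction = 0.2,
                                              coexpr_block_size = 5,
                                              seed = 21))
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back, sim$truth, tolerance = 1e-12)
  expect_identical(table(back$class, useNA = "ifany"),
                   table(sim$truth$class, useNA = "ifany"))
  ## no-effect truth round-trips with every class empty
  sim0 <- generate_experiment(synthetic_config(n_genes = 20,
                                               deg_fraction = 0, seed = 1))
  write_truth(sim0$truth, path)
  expect_true(all(is.na(read_truth(path)$class)))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_genes = 0), "n_genes")
  expect_error(synthetic_config(deg_fraction = 1.2), "deg_fraction")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(trajectory_mix = c(persistent = 0.5)),
               "trajectory_mix")
  expect_error(synthetic_config(coexpr_block_size = -1), "coexpr_block_size")
  expect_error(synthetic_config(n_genes = 10, coexpr_block_size = 20),
               "coexpr_block_size")
})
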