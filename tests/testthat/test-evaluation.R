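test_that("fold schemes partition the observations reproducibly", {
  sch <- split_scheme("kfold", k = 5, repeats = 3, seed = 99)
  folds <- make_folds(sch, 23)
  expect_length(folds, 3L)
  for (r in folds) {
    expect_equal(sort(unlist(r)), 1:23)
    expect_length(r, 5L)
  }
  expect_identical(folds, make_folds(sch, 23))
  loo <- make_folds(split_scheme("loocv"), 7)
  expect_equal(sort(unlist(loo[[1]])), 1:7)
  expect_true(all(lengths(loo[[1]]) == 1L))
  frac <- make_folds(split_scheme("fraction", fraction = 2 / 3), 30)
  expect_length(frac[[1]][[1]], 10L)
})

test_that("repeated cross-validation returns one evaluated row per fold", {
  d <- generate_powerlaw_dataset(60, 4, noise_sd = 0.1, seed = 15)
  sch <- split_scheme("kfold", k = 5, repeats = 4, seed = 2)
  res <- run_crossval(d$table, "apoptosis", "powerlaw", sch,
                      epsilon = d$truth$epsilon)
  expect_s3_class(res, "crossval_results")
  expect_equal(nrow(res), 20L)
  expect_identical(res,
                   run_crossval(d$table, "apoptosis", "powerlaw", sch,
                                epsilon = d$truth$epsilon))
  # a noise-free generative table is predicted perfectly in every fold
  d0 <- generate_powerlaw_dataset(50, 3, noise_sd = 0, seed = 16)
  r0 <- run_crossval(d0$table, "apoptosis", "powerlaw",
                     split_scheme("kfold", k = 5, repeats = 2, seed = 3),
                     epsilon = d0$truth$epsilon, n_components = 3)
  expect_true(all(r0$spearman > 1 - 1e-9))
  expect_true(all(abs(r0$pearson - 1) < 1e-9))
})

test_that("joint-threshold counting follows its definition and monotonicity", {
  res <- data.frame(spearman = c(0.9, 0.6, NA, 0.75),
                    pearson = c(0.9, 0.95, 0.9, 0.71))
  expect_equal(count_joint_threshold(res, 0.7), 2L)
  expect_equal(count_joint_threshold(data.frame(spearman = numeric(0),
                                                pearson = numeric(0)), 0.7), 0L)
  taus <- seq(0, 1, by = 0.1)
  counts <- vapply(taus, function(t) count_joint_threshold(res, t), integer(1))
  expect_false(is.unsorted(rev(counts)))
})

test_that("the nonlinear model dominates the linear on power-law generated folds", {
  wins <- logical(0)
  for (s in 1:10) {
    d <- generate_powerlaw_dataset(80, 5, noise_sd = 0.15, seed = 100 + s)
    sch <- split_scheme("kfold", k = 5, repeats = 4, seed = s)
    nl <- run_crossval(d$table, "apoptosis", "powerlaw", sch,
                       epsilon = d$truth$epsilon)
    li <- run_crossval(d$table, "apoptosis", "linear", sch)
    wins <- c(wins, count_joint_threshold(nl, 0.8) >=
                count_joint_threshold(li, 0.8))
  }
  expect_true(all(wins))
})

test_that("cross-cell-line transfer is a single fit/eval and detects asymmetry", {
  # bounded fates (probabilities) so the Kullback-Leibler loss is defined
  d0 <- generate_powerlaw_dataset(50, 3, beta0 = -3,
                                  beta = c(0.2, 0.1, -0.15),
                                  noise_sd = 0, seed = 22)
  expect_true(all(d0$table$apoptosis < 1))
  self <- cross_cellline(d0$table, d0$table, "apoptosis", "powerlaw",
                         epsilon = d0$truth$epsilon, n_components = 3)
  expect_equal(self$spearman, 1)
  expect_lt(self$kl, 1e-6)

  # two cell lines with different generative exponents
  dA <- generate_powerlaw_dataset(60, 3, beta = c(0.8, 0.2, -0.4),
                                  noise_sd = 0.05, seed = 23,
                                  cell_line = "A")
  dB <- generate_powerlaw_dataset(60, 3, beta = c(-0.5, 0.9, 0.3),
                                  noise_sd = 0.05, seed = 24,
                                  cell_line = "B")
  ab <- cross_cellline(dA$table, dB$table, "apoptosis", "powerlaw")
  ba <- cross_cellline(dB$table, dA$table, "apoptosis", "powerlaw")
  expect_false(isTRUE(all.equal(ab$rmse, ba$rmse)))
  expect_error(cross_cellline(dA$table, tiny_table(), "apoptosis"),
               "protein set")
})

test_that("the per-protein split protocol predicts deterministic systems exactly", {
  lam <- cascade_lambda(4, 0.8)
  d <- generate_influence_dataset(30, lam, seed = 31, noise_sd = 0,
                                  epsilon = 0, fate_epsilon = 0.001)
  tab <- filter_valid(d$control)
  res <- dream8_protein_cv(tab, "powerlaw", seed = 5, n_repeats = 2,
                           epsilon = 0)
  expect_lt(res$mean_rmse, 1e-6)
  expect_equal(dim(res$per_repeat), c(2L, 4L))
  # determinism
  res2 <- dream8_protein_cv(tab, "powerlaw", seed = 5, n_repeats = 2,
                            epsilon = 0)
  expect_equal(res$mean_rmse, res2$mean_rmse)
  # nonlinear beats linear on the multiplicative system
  lamn <- generate_influence_dataset(60, lam, seed = 32, noise_sd = 0.05,
                                     epsilon = 1e-4)
  tn <- filter_valid(lamn$control)
  r_nl <- dream8_protein_cv(tn, "powerlaw", seed = 6, n_repeats = 3)
  r_li <- dream8_protein_cv(tn, "linear", seed = 6, n_repeats = 3)
  expect_lt(r_nl$mean_rmse, r_li$mean_rmse)
})

test_that("cell-line discrimination separates distinct regimes and is deterministic", {
  dA <- generate_powerlaw_dataset(40, 4, signal_meanlog = -2,
                                  signal_sdlog = 0.5,
                                  beta = c(0.7, 0.3, -0.2, 0.5),
                                  noise_sd = 0.05, seed = 41, cell_line = "A")
  dB <- generate_powerlaw_dataset(40, 4, signal_meanlog = 2,
                                  signal_sdlog = 0.5,
                                  beta = c(-0.3, 0.8, 0.4, -0.6),
                                  noise_sd = 0.05, seed = 42, cell_line = "B")
  combined <- observation_table(rbind(as.data.frame(dA$table),
                                      as.data.frame(dB$table)),
                                signals = signal_names(dA$table),
                                fates = "apoptosis")
  sc <- cellline_scores(combined, "apoptosis", "powerlaw")
  expect_equal(sc$n_misclassified, 0L)
  expect_equal(ncol(sc$centroids), 2L)
  sc2 <- cellline_scores(combined, "apoptosis", "powerlaw")
  expect_identical(sc$scores, sc2$scores)
  # a single cell line trivially has no misclassification
  one <- cellline_scores(dA$table, "apoptosis", "powerlaw")
  expect_equal(one$n_misclassified, 0L)
})
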